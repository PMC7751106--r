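#' Normalize a protein sequence to the 20-letter alphabet
#'
#' Uppercases the sequence and resolves non-standard residue codes according
#' to a policy. Under `"strict"` (the default) any character outside the
#' 20-letter alphabet is an error; under `"map"` the common ambiguity codes
#' are resolved to their nearest standard residue (B to D, Z to E, J to L,
#' U to C, O to K) while `X` and anything else remains an error, because the
#' downstream encodings are defined only on the 20 standard residues.
#'
#' @param sequence character scalar, the residue string.
#' @param id protein identifier used in error messages.
#' @param policy `"strict"` or `"map"`.
#' @return The normalized residue string.
#' @export
normalize_sequence <- function(sequence, id = "?", policy = c("strict", "map")) {
  policy <- match.arg(policy)
  s <- toupper(gsub("[[:space:]*]", "", sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (policy == "map") {
    hit <- chars %in% names(AMBIGUITY_MAP)
    chars[hit] <- AMBIGUITY_MAP[chars[hit]]
  }
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("sequence '%s' contains non-standard residue(s): %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  paste(chars, collapse = "")
}

#' Construct a protein record
#'
#' @param id unique identifier.
#' @param sequence residue string; normalized via [normalize_sequence()].
#' @param policy alphabet policy passed to [normalize_sequence()].
#' @return An object of class `protein_record` with fields `id`, `sequence`
#'   and `length`.
#' @export
protein_record <- function(id, sequence, policy = "strict") {
  seq <- normalize_sequence(sequence, id = id, policy = policy)
  if (nchar(seq) < 1L) stop(sprintf("sequence '%s' is empty", id), call. = FALSE)
  structure(list(id = id, sequence = seq, length = nchar(seq)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, x$length))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param policy alphabet policy, see [normalize_sequence()].
#' @return A list of [protein_record()] objects, in file order. The record id
#'   is the first whitespace-delimited token of the header.
#' @export
read_fasta <- function(path, policy = "strict") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop(sprintf("no FASTA records in %s", path), call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  recs <- Map(protein_record, ids, as.character(set),
              MoreArgs = list(policy = policy))
  unname(recs)
}

#' Write protein records to a FASTA file
#'
#' @param records list of [protein_record()].
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "sequence"))
  names(set) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Construct a profile matrix
#'
#' An L x 20 matrix of per-position substitution scores, columns in the
#' canonical alphabetical amino-acid order.
#'
#' @param protein_id identifier of the protein the profile belongs to.
#' @param scores numeric L x 20 matrix; column names, when present, are used
#'   to permute into canonical order.
#' @return An object of class `profile_matrix`.
#' @export
profile_matrix <- function(protein_id, scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20L) {
    stop("a profile matrix must have exactly 20 columns", call. = FALSE)
  }
  if (nrow(scores) < 1L) stop("a profile matrix must have at least one row", call. = FALSE)
  if (!is.null(colnames(scores))) {
    if (!setequal(colnames(scores), AA_ALPHABET)) {
      stop("profile column names must be the 20 standard amino acids", call. = FALSE)
    }
    scores <- scores[, AA_ALPHABET, drop = FALSE]
  } else {
    colnames(scores) <- AA_ALPHABET
  }
  structure(list(protein_id = protein_id, scores = scores, length = nrow(scores)),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %s (%d x 20)\n", x$protein_id, x$length))
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM export
#'
#' Parses the `-out_ascii_pssm` dialect: header lines, then one row per
#' residue carrying the position, the residue, 20 log-odds columns, 20
#' weighted-percentage columns and two trailing statistics. Only the first
#' block (log-odds) is retained, and columns are permuted from the PSI-BLAST
#' order into the canonical alphabetical order.
#'
#' @param path ASCII PSSM file.
#' @param protein_id identifier to attach; defaults to the file name sans
#'   extension.
#' @return A [profile_matrix()].
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(protein_id)) protein_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!grepl("^[0-9]+\\s+[A-Za-z]\\s", ln)) next
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    nums <- suppressWarnings(as.numeric(fields[-(1:2)]))
    ## data rows carry 40 score fields (+ up to 2 trailing statistics)
    scores <- nums[seq_len(min(40L, length(nums)))]
    if (length(scores) < 40L || anyNA(scores)) {
      stop(sprintf("malformed PSSM row at line %d of %s: expected 40 numeric score fields",
                   i, path), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- scores[1:20]
  }
  if (length(rows) == 0L) {
    stop(sprintf("no PSSM data rows found in %s", path), call. = FALSE)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- PSIBLAST_ORDER
  profile_matrix(protein_id, m[, AA_ALPHABET, drop = FALSE])
}

#' Write a profile matrix as a PSI-BLAST-style ASCII PSSM
#'
#' Emits the `-out_ascii_pssm` dialect that [read_pssm()] parses: two header
#' lines, then per-residue rows with the log-odds block (in PSI-BLAST column
#' order), a mirrored second block, and two trailing columns.
#'
#' @param profile a [profile_matrix()].
#' @param path output file.
#' @param sequence optional residue string of matching length for the residue
#'   column; defaults to "A" everywhere.
#' @export
write_pssm <- function(profile, path, sequence = NULL) {
  m <- profile$scores[, PSIBLAST_ORDER, drop = FALSE]
  L <- nrow(m)
  res <- if (is.null(sequence)) rep("A", L) else strsplit(sequence, "")[[1]]
  if (length(res) != L) stop("sequence length does not match profile rows", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste(" ", paste(sprintf("%3s", c(PSIBLAST_ORDER, PSIBLAST_ORDER)), collapse = " "))),
             con)
  for (i in seq_len(L)) {
    writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                      paste(sprintf("%3d", round(m[i, ])), collapse = " "), " ",
                      paste(sprintf("%3d", pmax(0L, round(m[i, ]))), collapse = " "), " ",
                      " 0.00 0.00"), con)
  }
  invisible(path)
}

#' Construct a topology call
#'
#' A membrane call from an external transmembrane-topology predictor. A
#' protein is regarded as a membrane protein if at least one transmembrane
#' segment (TMS) is predicted.
#'
#' @param protein_id identifier.
#' @param tms_count non-negative integer count of predicted TMSs.
#' @return An object of class `topology_call` with the derived `is_membrane`
#'   flag.
#' @export
topology_call <- function(protein_id, tms_count) {
  tms_count <- as.integer(tms_count)
  if (is.na(tms_count) || tms_count < 0L) {
    stop(sprintf("tms_count for '%s' must be a non-negative integer", protein_id),
         call. = FALSE)
  }
  structure(list(protein_id = protein_id, tms_count = tms_count,
                 is_membrane = tms_count >= 1L),
            class = "topology_call")
}

#' Read topology calls from a TSV table
#'
#' @param path tab-separated file with header columns `id` and `tms_count`.
#' @return A named list of [topology_call()] objects keyed by protein id.
#' @export
read_topology_calls <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "tms_count") %in% names(tab))) {
    stop("topology table must have columns 'id' and 'tms_count'", call. = FALSE)
  }
  if (anyDuplicated(tab$id)) {
    dup <- tab$id[duplicated(tab$id)][1]
    stop(sprintf("duplicate id in topology table: '%s'", dup), call. = FALSE)
  }
  calls <- Map(topology_call, tab$id, tab$tms_count)
  names(calls) <- tab$id
  calls
}

#' Write topology calls to a TSV table
#'
#' @param calls named list of [topology_call()].
#' @param path output file.
#' @export
write_topology_calls <- function(calls, path) {
  tab <- data.frame(id = vapply(calls, `[[`, character(1), "protein_id"),
                    tms_count = vapply(calls, `[[`, integer(1), "tms_count"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read class labels from a TSV table
#'
#' @param path tab-separated file with header columns `id` and `label`;
#'   labels are `membrane` (positive) or `nonmembrane` (negative).
#' @return Named integer vector (1 = membrane, 0 = nonmembrane) keyed by id.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "label") %in% names(tab))) {
    stop("label table must have columns 'id' and 'label'", call. = FALSE)
  }
  bad <- setdiff(unique(tab$label), c("membrane", "nonmembrane"))
  if (length(bad) > 0) {
    stop(sprintf("unknown label value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  y <- as.integer(tab$label == "membrane")
  names(y) <- tab$id
  y
}

#' Write class labels to a TSV table
#'
#' @param labels named 0/1 vector keyed by protein id.
#' @param path output file.
#' @export
write_labels <- function(labels, path) {
  tab <- data.frame(id = names(labels),
                    label = ifelse(labels == 1, "membrane", "nonmembrane"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a labeled dataset
#'
#' @param records list of [protein_record()].
#' @param labels named 0/1 vector; every name must resolve to a record id.
#' @param profiles optional named list of [profile_matrix()]; when present,
#'   each profile must length-match its sequence.
#' @param topology optional named list of [topology_call()].
#' @return An object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(records, labels, profiles = NULL, topology = NULL) {
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate record ids in dataset", call. = FALSE)
  missing <- setdiff(names(labels), ids)
  if (length(missing) > 0) {
    stop(sprintf("label id(s) with no record: %s",
                 paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(profiles)) {
    for (id in names(profiles)) {
      rec <- records[[match(id, ids)]]
      if (is.null(rec)) stop(sprintf("profile id '%s' has no record", id), call. = FALSE)
      if (profiles[[id]]$length != rec$length) {
        stop(sprintf("profile for '%s' has %d rows but sequence length is %d",
                     id, profiles[[id]]$length, rec$length), call. = FALSE)
      }
    }
  }
  structure(list(records = records, ids = ids,
                 labels = labels[ids], profiles = profiles,
                 topology = topology),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d proteins (%d membrane / %d nonmembrane)%s\n",
              length(x$records), sum(x$labels == 1), sum(x$labels == 0),
              if (!is.null(x$profiles)) ", with profiles" else ""))
  invisible(x)
}

#' Partition records by a minimum-length floor
#'
#' Sequences shorter than `min_len` residues are set aside (short chains are
#' likely fragments). Order is preserved in both partitions.
#'
#' @param records list of [protein_record()].
#' @param min_len integer length floor, default 50.
#' @return List with elements `kept` and `removed`.
#' @export
validate_min_length <- function(records, min_len = 50L) {
  lens <- vapply(records, `[[`, integer(1), "length")
  list(kept = records[lens >= min_len], removed = records[lens < min_len])
}

#' Read a flat key-value config file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#'
#' @param path config file.
#' @return Named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop(sprintf("malformed config line: '%s'", lines[bad][1]), call. = FALSE)
  stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, character(1), 1L))
}
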