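## Deterministic synthetic fixtures: sequences with a controllable
## hydrophobic-segment class signal, substitution-matrix-derived profile
## matrices, and a simulated topology predictor. Everything is seeded so the
## full pipeline is testable without any external search.

## stable sub-seed per component, kept within 32-bit integer range
derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the study conditions: sequences of at least 50 residues
#' (the fragment floor), transmembrane positives carrying 1-5 hydrophobic
#' segments of 18-25 residues, and a 20% surface-bound fraction of positives
#' that carries only a compositional shift (no TMS), mirroring the roughly
#' 75/25 transmembrane/surface-bound split of annotated membrane proteins.
#'
#' @param n_per_class proteins per class, default 60.
#' @param length_range sequence length range, min >= 50; default 100-250.
#' @param tms_count_range TMS count range for transmembrane positives.
#' @param tms_length_range TMS segment length range (residues).
#' @param hydrophobic_set residues a TMS is drawn from.
#' @param surface_fraction fraction of positives that are surface-bound.
#' @param profile_noise half-width of the integer noise added to profile
#'   rows.
#' @param seed master seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_per_class = 60L,
                         length_range = c(100L, 250L),
                         tms_count_range = c(1L, 5L),
                         tms_length_range = c(18L, 25L),
                         hydrophobic_set = c("A", "I", "L", "M", "F", "V", "W"),
                         surface_fraction = 0.2,
                         profile_noise = 1L,
                         seed = 1L) {
  stopifnot(n_per_class >= 1L,
            length_range[1] >= 50L, length_range[2] >= length_range[1],
            tms_count_range[1] >= 1L, tms_count_range[2] >= tms_count_range[1],
            tms_length_range[1] >= 1L, tms_length_range[2] >= tms_length_range[1],
            surface_fraction >= 0, surface_fraction <= 1,
            all(hydrophobic_set %in% AA_ALPHABET))
  if (length_range[1] < tms_length_range[2] + 5L) {
    stop("minimum length cannot accommodate a single TMS", call. = FALSE)
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range),
                 tms_count_range = as.integer(tms_count_range),
                 tms_length_range = as.integer(tms_length_range),
                 hydrophobic_set = hydrophobic_set,
                 surface_fraction = surface_fraction,
                 profile_noise = as.integer(profile_noise),
                 seed = as.integer(seed)),
            class = "synth_config")
}

sample_background <- function(n, freq = BACKGROUND_FREQ) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = freq[AA_ALPHABET])
}

#' Generate a labeled synthetic dataset
#'
#' Positives are background sequences with `tms_count` non-overlapping
#' hydrophobic stretches inserted (one per equal-width block, so segments
#' never collide); a configurable fraction of positives is surface-bound:
#' no stretch, but a compositional shift towards the hydrophobic set.
#' Negatives are background-only. Deterministic given the config seed.
#'
#' @param cfg a [synth_config()].
#' @return A [labeled_dataset()] with a `meta` data.frame (id, class,
#'   n_tms, surface).
#' @export
gen_dataset <- function(cfg) {
  set.seed(derive_seed(cfg$seed, "dataset"))
  n <- cfg$n_per_class
  ids <- c(sprintf("pos_%03d", seq_len(n)), sprintf("neg_%03d", seq_len(n)))
  labels <- stats::setNames(rep(c(1L, 0L), each = n), ids)
  surface <- c(stats::runif(n) < cfg$surface_fraction, rep(FALSE, n))
  ## surface-bound composition: background mildly enriched in the
  ## hydrophobic set (membrane-associating residues)
  surf_freq <- BACKGROUND_FREQ
  surf_freq[cfg$hydrophobic_set] <- 2 * surf_freq[cfg$hydrophobic_set]
  records <- vector("list", 2L * n)
  n_tms <- integer(2L * n)
  for (i in seq_len(2L * n)) {
    L <- sample(seq(cfg$length_range[1], cfg$length_range[2]), 1L)
    if (labels[i] == 1L && !surface[i]) {
      block <- cfg$tms_length_range[2] + 5L
      max_fit <- L %/% block
      k <- min(sample(seq(cfg$tms_count_range[1], cfg$tms_count_range[2]), 1L),
               max_fit)
      chars <- sample_background(L)
      width <- L %/% k
      for (s in seq_len(k)) {
        tlen <- sample(seq(cfg$tms_length_range[1], cfg$tms_length_range[2]), 1L)
        lo <- (s - 1L) * width + 1L
        start <- lo + sample.int(width - tlen + 1L, 1L) - 1L
        chars[start:(start + tlen - 1L)] <-
          sample(cfg$hydrophobic_set, tlen, replace = TRUE)
      }
      n_tms[i] <- k
    } else if (labels[i] == 1L) {
      chars <- sample(AA_ALPHABET, L, replace = TRUE, prob = surf_freq[AA_ALPHABET])
    } else {
      chars <- sample_background(L)
    }
    records[[i]] <- protein_record(ids[i], paste(chars, collapse = ""))
  }
  ds <- labeled_dataset(records, labels)
  ds$meta <- data.frame(id = ids, class = labels, n_tms = n_tms,
                        surface = surface)
  ds
}

#' Generate synthetic profile matrices for a dataset
#'
#' Row i of a protein's profile is the substitution-score row of residue i
#' (BLOSUM62 log-odds) plus seeded integer noise, giving integer-valued
#' matrices that round-trip exactly through the ASCII PSSM writer/reader and
#' inherit the class-dependent composition of the sequences.
#'
#' @param dataset a [gen_dataset()] result.
#' @param cfg the same [synth_config()].
#' @return Named list of [profile_matrix()] keyed by protein id.
#' @export
gen_profiles <- function(dataset, cfg) {
  set.seed(derive_seed(cfg$seed, "profiles"))
  profiles <- lapply(dataset$records, function(rec) {
    chars <- strsplit(rec$sequence, "")[[1]]
    m <- BLOSUM62_20[chars, , drop = FALSE]
    if (cfg$profile_noise > 0L) {
      m <- m + sample(seq(-cfg$profile_noise, cfg$profile_noise),
                      length(m), replace = TRUE)
    }
    rownames(m) <- NULL
    profile_matrix(rec$id, m)
  })
  stats::setNames(profiles, dataset$ids)
}

#' Simulate an external transmembrane-topology predictor
#'
#' TMS-bearing positives are detected (call = true TMS count) with the given
#' sensitivity; surface-bound positives are never detected, emulating
#' topology tools' blindness to proteins without membrane-spanning segments;
#' negatives receive a spurious single-TMS call at rate 1 - specificity.
#' Defaults mirror the printed tool evaluation (best observed sensitivity
#' 0.72, consensus-predictor specificity 0.997).
#'
#' @param dataset a [gen_dataset()] result (its `meta` field is required).
#' @param cfg the same [synth_config()].
#' @param sensitivity detection rate on TMS-bearing positives.
#' @param specificity true-negative rate on nonmembrane proteins.
#' @return Named list of [topology_call()] keyed by protein id.
#' @export
gen_topology_calls <- function(dataset, cfg, sensitivity = 0.72,
                               specificity = 0.997) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  if (is.null(dataset$meta)) {
    stop("dataset lacks generator metadata; use gen_dataset()", call. = FALSE)
  }
  set.seed(derive_seed(cfg$seed, "topology"))
  meta <- dataset$meta
  u <- stats::runif(nrow(meta))
  tms <- integer(nrow(meta))
  tm_pos <- meta$class == 1L & !meta$surface
  tms[tm_pos] <- ifelse(u[tm_pos] < sensitivity, meta$n_tms[tm_pos], 0L)
  neg <- meta$class == 0L
  tms[neg] <- ifelse(u[neg] < 1 - specificity, 1L, 0L)
  calls <- Map(topology_call, meta$id, tms)
  stats::setNames(calls, meta$id)
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits FASTA sequences, a directory of ASCII PSSM files, a topology-call
#' TSV and a label TSV, all regenerable from the config seed.
#'
#' @param cfg a [synth_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_synth_fixtures <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- gen_dataset(cfg)
  profiles <- gen_profiles(ds, cfg)
  calls <- gen_topology_calls(ds, cfg)
  fasta <- file.path(out_dir, "proteins.fasta")
  write_fasta(ds$records, fasta)
  pssm_dir <- file.path(out_dir, "pssm")
  dir.create(pssm_dir, showWarnings = FALSE)
  for (id in ds$ids) {
    write_pssm(profiles[[id]], file.path(pssm_dir, paste0(id, ".pssm")),
               sequence = ds$records[[match(id, ds$ids)]]$sequence)
  }
  topo <- file.path(out_dir, "topology.tsv")
  write_topology_calls(calls, topo)
  labels <- file.path(out_dir, "labels.tsv")
  write_labels(ds$labels, labels)
  invisible(list(fasta = fasta, pssm_dir = pssm_dir, topology = topo,
                 labels = labels))
}
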