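#' Standardized amino-acid property scales
#'
#' Builds the scale set behind the sequence-order correlation factors of the
#' pseudo amino acid composition: hydrophobicity (Tanford), hydrophilicity
#' (Hopp-Woods) and side-chain mass, each standardized over the 20 amino
#' acids to mean 0 and population standard deviation 1 (divide-by-20
#' variance, since the 20 residues are the full population).
#'
#' @param raw optional replacement list with numeric vectors
#'   `hydrophobicity`, `hydrophilicity`, `mass`, each named by the 20
#'   one-letter codes; defaults to the shipped constants table.
#' @return An object of class `aa_scales` with elements `H1`, `H2`, `M`
#'   (standardized) and `raw`.
#' @export
aa_scales <- function(raw = RAW_SCALES) {
  stopifnot(all(c("hydrophobicity", "hydrophilicity", "mass") %in% names(raw)))
  std <- function(x) {
    x <- x[AA_ALPHABET]
    if (anyNA(x)) stop("scale table must cover all 20 amino acids", call. = FALSE)
    (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  }
  structure(list(H1 = std(raw$hydrophobicity),
                 H2 = std(raw$hydrophilicity),
                 M  = std(raw$mass),
                 raw = raw),
            class = "aa_scales")
}

new_feature_vector <- function(protein_id, encoding, lambda, values) {
  structure(list(protein_id = protein_id, encoding = encoding,
                 lambda = lambda, values = values),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> %s %s (lambda=%d, dim=%d)\n",
              x$protein_id, x$encoding, x$lambda, length(x$values)))
  invisible(x)
}

seq_chars <- function(rec) strsplit(rec$sequence, "", fixed = TRUE)[[1]]

aac_of_chars <- function(chars) {
  if (length(chars) == 0L) {
    return(stats::setNames(rep(0, 20), AA_ALPHABET))
  }
  tab <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.numeric(tab) / length(chars), AA_ALPHABET)
}

#' Amino acid composition (AAC)
#'
#' The normalized occurrence frequency of each of the 20 amino acids:
#' component i is F_i / L. Components are non-negative and sum to 1.
#'
#' @param rec a [protein_record()].
#' @return A 20-component `feature_vector` in alphabetical residue order.
#' @export
encode_aac <- function(rec) {
  chars <- seq_chars(rec)
  if (length(chars) < 1L) stop("empty sequence", call. = FALSE)
  v <- aac_of_chars(chars)
  names(v) <- paste0("aac_", AA_ALPHABET)
  new_feature_vector(rec$id, "AAC", 0L, v)
}

#' Pair amino acid composition (PAAC)
#'
#' Dipeptide composition: component (i, j) is the count of the ordered
#' dipeptide ij divided by L - 1; the 400 components sum to 1.
#'
#' @param rec a [protein_record()] with at least 2 residues.
#' @return A 400-component `feature_vector`.
#' @export
encode_paac <- function(rec) {
  chars <- seq_chars(rec)
  L <- length(chars)
  if (L < 2L) stop("dipeptide composition requires length >= 2", call. = FALSE)
  di <- paste0(chars[-L], chars[-1])
  lv <- as.vector(outer(AA_ALPHABET, AA_ALPHABET, paste0))
  tab <- table(factor(di, levels = lv))
  v <- stats::setNames(as.numeric(tab) / (L - 1), paste0("paac_", lv))
  new_feature_vector(rec$id, "PAAC", 0L, v)
}

#' Sequence-order correlation factors for the pseudo composition
#'
#' theta_k is the average, over all residue pairs k positions apart, of the
#' correlation function Theta(R_i, R_j) = mean of the squared differences of
#' the standardized hydrophobicity, hydrophilicity and side-chain mass of the
#' two residues.
#'
#' @param rec a [protein_record()].
#' @param lambda number of factors, 0 <= lambda < L.
#' @param scales an [aa_scales()] set.
#' @return Numeric vector theta_1..theta_lambda (empty for lambda = 0).
#' @export
theta_factors <- function(rec, lambda, scales = aa_scales()) {
  L <- rec$length
  if (lambda < 0L || lambda >= L) {
    stop(sprintf("lambda must satisfy 0 <= lambda < L (= %d)", L), call. = FALSE)
  }
  if (lambda == 0L) return(numeric(0))
  chars <- seq_chars(rec)
  h1 <- scales$H1[chars]; h2 <- scales$H2[chars]; m <- scales$M[chars]
  vapply(seq_len(lambda), function(k) {
    i <- seq_len(L - k)
    mean(((h1[i + k] - h1[i])^2 + (h2[i + k] - h2[i])^2 + (m[i + k] - m[i])^2) / 3)
  }, numeric(1))
}

#' Pseudo amino acid composition (PseAAC)
#'
#' AAC augmented with lambda sequence-order correlation factors. The first 20
#' components are f_i / (sum f_r + omega * sum theta_j); the last lambda are
#' omega * theta_j over the same denominator, so the vector sums to 1. With
#' lambda = 0 it reduces exactly to the AAC.
#'
#' @param rec a [protein_record()].
#' @param lambda number of correlation factors, 0 <= lambda < L.
#' @param omega weight of the sequence-order components; conventional range
#'   0.05 to 0.7, default 0.05.
#' @param scales an [aa_scales()] set.
#' @return A (20 + lambda)-component `feature_vector`.
#' @export
encode_pseaac <- function(rec, lambda, omega = 0.05, scales = aa_scales()) {
  if (!is.numeric(omega) || omega <= 0) stop("omega must be positive", call. = FALSE)
  theta <- theta_factors(rec, lambda, scales)
  f <- aac_of_chars(seq_chars(rec))
  den <- sum(f) + omega * sum(theta)
  v <- c(f / den, if (lambda > 0L) omega * theta / den)
  names(v) <- c(paste0("pseaac_", AA_ALPHABET),
                if (lambda > 0L) paste0("pseaac_theta", seq_len(lambda)))
  new_feature_vector(rec$id, "PseAAC", as.integer(lambda), v)
}

#' Split amino acid composition (SAAC)
#'
#' The AAC computed separately on the first `n_term` residues, the interior,
#' and the last `c_term` residues, concatenated in that order (60 components
#' with the 25/25 default split). When L equals `n_term + c_term` the interior
#' segment is empty and its block is all zeros.
#'
#' @param rec a [protein_record()] with L >= n_term + c_term.
#' @param n_term,c_term terminal segment lengths, default 25 each.
#' @return A 60-component `feature_vector`.
#' @export
encode_saac <- function(rec, n_term = 25L, c_term = 25L) {
  chars <- seq_chars(rec)
  L <- length(chars)
  if (L < n_term + c_term) {
    stop(sprintf("SAAC requires L >= %d (got %d)", n_term + c_term, L), call. = FALSE)
  }
  nb <- aac_of_chars(chars[seq_len(n_term)])
  mb <- aac_of_chars(chars[setdiff(seq_len(L - c_term), seq_len(n_term))])
  cb <- aac_of_chars(chars[(L - c_term + 1L):L])
  v <- c(nb, mb, cb)
  names(v) <- c(paste0("saac_N_", AA_ALPHABET), paste0("saac_M_", AA_ALPHABET),
                paste0("saac_C_", AA_ALPHABET))
  new_feature_vector(rec$id, "SAAC", 0L, v)
}

#' Standardize a profile matrix row-wise
#'
#' Each row is centred to mean 0 over the 20 amino acids and divided by the
#' row's population standard deviation, making the downstream descriptor
#' scale-free. A zero-variance row becomes all zeros. Set `center_only = TRUE`
#' to skip the division (pure mean-centring).
#'
#' @param p a [profile_matrix()].
#' @param center_only logical; skip division by the row SD.
#' @return A standardized [profile_matrix()].
#' @export
standardize_profile <- function(p, center_only = FALSE) {
  m <- p$scores
  mu <- rowMeans(m)
  cent <- m - mu
  if (!center_only) {
    sd <- sqrt(rowMeans(cent^2))
    cent <- ifelse(sd > 0, 1 / sd, 0) * cent
  }
  profile_matrix(p$protein_id, cent)
}

#' Pseudo-PSSM descriptor of a profile matrix
#'
#' A fixed 40-component summary of an L x 20 standardized profile: the 20
#' column means, then the 20 mean squared lambda-lag differences
#' G_j = mean_i (E_{i,j} - E_{i+lambda,j})^2. For lambda = 0 the G block is
#' identically zero.
#'
#' @param p a standardized [profile_matrix()] (see [standardize_profile()]).
#' @param lambda lag, 0 <= lambda < L.
#' @return A 40-component `feature_vector`.
#' @export
encode_psepssm <- function(p, lambda) {
  L <- p$length
  if (lambda < 0L || lambda >= L) {
    stop(sprintf("lambda must satisfy 0 <= lambda < L (= %d)", L), call. = FALSE)
  }
  m <- p$scores
  ebar <- colMeans(m)
  if (lambda == 0L) {
    g <- rep(0, 20)
  } else {
    i <- seq_len(L - lambda)
    d <- m[i, , drop = FALSE] - m[i + lambda, , drop = FALSE]
    g <- colMeans(d^2)
  }
  v <- c(ebar, g)
  names(v) <- c(paste0("psepssm_mean_", AA_ALPHABET), paste0("psepssm_g_", AA_ALPHABET))
  new_feature_vector(p$protein_id, "PsePSSM", as.integer(lambda), v)
}

#' Encode a whole dataset into a feature matrix
#'
#' @param dataset a [labeled_dataset()].
#' @param encoding one of `"aac"`, `"paac"`, `"pseaac"`, `"saac"`,
#'   `"psepssm"`.
#' @param lambda lambda for the pseudo encodings (ignored otherwise).
#' @param omega PseAAC weight factor.
#' @param center_only profile standardization switch, see
#'   [standardize_profile()].
#' @param scales an [aa_scales()] set.
#' @return Numeric matrix, one row per protein (rownames = ids), with named
#'   feature columns.
#' @export
encode_dataset <- function(dataset,
                           encoding = c("aac", "paac", "pseaac", "saac", "psepssm"),
                           lambda = 0L, omega = 0.05, center_only = FALSE,
                           scales = aa_scales()) {
  encoding <- match.arg(encoding)
  fvs <- switch(encoding,
    aac     = lapply(dataset$records, encode_aac),
    paac    = lapply(dataset$records, encode_paac),
    pseaac  = lapply(dataset$records, encode_pseaac, lambda = lambda,
                     omega = omega, scales = scales),
    saac    = lapply(dataset$records, encode_saac),
    psepssm = {
      if (is.null(dataset$profiles)) {
        stop("psepssm encoding requires profiles in the dataset", call. = FALSE)
      }
      lapply(dataset$ids, function(id) {
        p <- dataset$profiles[[id]]
        if (is.null(p)) stop(sprintf("no profile for '%s'", id), call. = FALSE)
        encode_psepssm(standardize_profile(p, center_only = center_only), lambda)
      })
    })
  X <- do.call(rbind, lapply(fvs, `[[`, "values"))
  rownames(X) <- vapply(fvs, `[[`, character(1), "protein_id")
  X
}
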