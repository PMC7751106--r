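## Independent brute-force oracles used to cross-check the implementation.
## These deliberately re-derive each quantity from first principles rather
## than calling the code paths they verify.

## Dempster combination by explicit enumeration of focal-set products over
## the two-class frame. Each neighbor's mass function has focal sets
## {own class} (mass a_i) and the frame (mass 1 - a_i).
bf_dempster_pignistic <- function(labels, d2, alpha0, gamma) {
  K <- length(labels)
  a <- alpha0 * exp(-gamma[labels + 1L] * d2)
  m <- c(pos = 0, neg = 0, theta = 0)
  conflict <- 0
  for (bits in 0:(2^K - 1)) {
    pick_class <- as.logical(bitwAnd(bits, 2^(seq_len(K) - 1L)))
    w <- prod(ifelse(pick_class, a, 1 - a))
    sets <- unique(labels[pick_class])
    if (length(sets) == 2L) {
      conflict <- conflict + w
    } else if (length(sets) == 0L) {
      m["theta"] <- m["theta"] + w
    } else if (sets == 1L) {
      m["pos"] <- m["pos"] + w
    } else {
      m["neg"] <- m["neg"] + w
    }
  }
  m <- m / (1 - conflict)
  unname(m["pos"] + m["theta"] / 2)
}

## per-class kernel scale heuristic, re-derived: inverse mean squared
## pairwise distance within each class, all-pairs fallback
bf_gamma <- function(X, y) {
  D2 <- as.matrix(dist(X))^2
  g <- c(NA_real_, NA_real_)
  for (cl in 0:1) {
    idx <- which(y == cl)
    if (length(idx) >= 2L) {
      v <- D2[idx, idx][upper.tri(D2[idx, idx])]
      if (sum(v) > 0) g[cl + 1L] <- 1 / mean(rep(v, 2L))
    }
  }
  v <- D2[upper.tri(D2)]
  g[is.na(g)] <- if (length(v) > 0 && sum(v) > 0) 1 / mean(rep(v, 2L)) else 1
  g
}

## greedy max-relevance / min-redundancy (MID) ranking recomputed from
## scratch at every step
bf_mrmr_order <- function(vm, y) {
  mi <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    r2 <- min(cor(a, b)^2, 1 - 1e-12)
    -0.5 * log(1 - r2)
  }
  n <- ncol(vm)
  rel <- vapply(seq_len(n), function(j) mi(vm[, j], y), numeric(1))
  sel <- integer(0)
  while (length(sel) < n) {
    rest <- setdiff(seq_len(n), sel)
    crit <- vapply(rest, function(j) {
      red <- if (length(sel) == 0L) 0 else {
        mean(vapply(sel, function(i) mi(vm[, j], vm[, i]), numeric(1)))
      }
      rel[j] - red
    }, numeric(1))
    sel <- c(sel, rest[which.max(crit)])
  }
  sel
}

## AUC as P(score_pos > score_neg) + 0.5 P(equal) by exhaustive pair counting
bf_auc <- function(scores, truth) {
  sp <- scores[truth == 1L]
  sn <- scores[truth == 0L]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}

## small deterministic synthetic dataset with profiles (and optional calls)
make_synth <- function(n_per_class = 15L, seed = 42L, ...) {
  cfg <- synth_config(n_per_class = n_per_class, seed = seed, ...)
  ds <- gen_dataset(cfg)
  ds$profiles <- gen_profiles(ds, cfg)
  attr(ds, "cfg") <- cfg
  ds
}

random_record <- function(id, L, seed) {
  set.seed(seed)
  protein_record(id, paste(sample(memvote:::AA_ALPHABET, L, replace = TRUE),
                           collapse = ""))
}
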