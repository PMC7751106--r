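#' Train a lambda-parameterized bank of base classifiers
#'
#' Builds one classifier per lambda over the profile descriptor features
#' (the 40-component pseudo-PSSM encoding), or one per (lambda, K) pair when
#' `per_K = TRUE` (neighbour-based algorithms only). With the full
#' lambda range 0..49 this yields the 50-member and 500-member banks.
#' Neighbour-based members are lazy (they store the training features);
#' adapter members are fitted immediately.
#'
#' @param dataset a [labeled_dataset()] with profiles for every record.
#' @param algorithm `"oetknn"`, `"knn"`, `"svm"`, `"gbm"` or `"rf"`.
#' @param lambda_range integer vector of lambda values, default `0:49`.
#' @param per_K enumerate members per (lambda, K), K = 1..`k_max`; only valid
#'   for `"oetknn"` and `"knn"`.
#' @param k_max largest neighbourhood size, default 10.
#' @param alpha0 evidence strength for OET-KNN members.
#' @param center_only profile standardization switch.
#' @param seed seed for adapter fitting.
#' @return An object of class `classifier_bank`; its `members` data.frame
#'   records the bank order.
#' @export
train_classifier_bank <- function(dataset,
                                  algorithm = c("oetknn", "knn", "svm", "gbm", "rf"),
                                  lambda_range = 0:49, per_K = FALSE,
                                  k_max = 10L, alpha0 = 0.95,
                                  center_only = FALSE, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (length(dataset$records) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(dataset$profiles)) {
    stop("profile matrices are required to train a bank", call. = FALSE)
  }
  if (per_K && !algorithm %in% c("oetknn", "knn")) {
    stop("per-K banks are defined only for neighbour-based algorithms", call. = FALSE)
  }
  lens <- vapply(dataset$records, `[[`, integer(1), "length")
  too_short <- lens <= max(lambda_range)
  if (any(too_short)) {
    stop(sprintf("lambda = %d requires L > lambda; offending record(s): %s",
                 max(lambda_range),
                 paste(utils::head(dataset$ids[too_short], 5), collapse = ", ")),
         call. = FALSE)
  }
  y <- as.integer(dataset$labels)
  features <- lapply(lambda_range, function(lam) {
    encode_dataset(dataset, "psepssm", lambda = lam, center_only = center_only)
  })
  names(features) <- as.character(lambda_range)

  if (per_K) {
    members <- expand.grid(K = seq_len(k_max), lambda = lambda_range,
                           KEEP.OUT.ATTRS = FALSE)[, c("lambda", "K")]
  } else {
    members <- data.frame(lambda = lambda_range, K = NA_integer_)
  }
  members$id <- ifelse(is.na(members$K),
                       sprintf("l%d", members$lambda),
                       sprintf("l%d_k%d", members$lambda, members$K))
  fitted <- NULL
  if (algorithm %in% c("svm", "gbm", "rf")) {
    fitted <- lapply(lambda_range, function(lam) {
      fit_adapter(algorithm, features[[as.character(lam)]], y, seed = seed)
    })
    names(fitted) <- as.character(lambda_range)
  }
  structure(list(algorithm = algorithm, members = members, features = features,
                 y = y, ids = dataset$ids, k_max = k_max, alpha0 = alpha0,
                 center_only = center_only, fitted = fitted, seed = seed),
            class = "classifier_bank")
}

#' @export
print.classifier_bank <- function(x, ...) {
  cat(sprintf("<classifier_bank> %s, %d members (lambda %d..%d%s)\n",
              toupper(x$algorithm), nrow(x$members),
              min(x$members$lambda), max(x$members$lambda),
              if (any(!is.na(x$members$K))) sprintf(", K 1..%d", x$k_max) else ""))
  invisible(x)
}

## Held-out neighbour votes for one lambda: for each sample, every other
## sample forms the reference set; returns the per-K vote matrix (n x k_max)
## and the fused (majority over K) vote and score.
loocv_neighbor_votes <- function(X, y, k_max = 10L,
                                 method = c("knn", "oetknn"), alpha0 = 0.95) {
  method <- match.arg(method)
  n <- nrow(X)
  if (n < 2L) stop("leave-one-out requires n >= 2", call. = FALSE)
  D2 <- as.matrix(stats::dist(X))^2
  kk <- min(k_max, n - 1L)
  per_k <- matrix(NA_integer_, n, k_max)
  fused <- integer(n)
  fused_score <- numeric(n)
  for (i in seq_len(n)) {
    others <- which(seq_len(n) != i)
    ord <- others[order(D2[i, others], others)]
    labs <- y[ord]
    if (method == "knn") {
      votes <- vapply(seq_len(kk), function(K) majority01(labs[seq_len(K)], labs[1L]),
                      integer(1))
    } else {
      g <- gamma_heuristic(D2[others, others, drop = FALSE], y[others])
      d2s <- D2[i, ord]
      votes <- vapply(seq_len(kk), function(K) {
        betp <- dempster_pignistic(labs[seq_len(K)], d2s[seq_len(K)], alpha0, g)
        if (betp > 0.5) 1L else if (betp < 0.5) 0L else labs[1L]
      }, integer(1))
    }
    per_k[i, seq_len(kk)] <- votes
    fused[i] <- majority01(votes, votes[1L])
    fused_score[i] <- mean(votes == 1L)
  }
  list(per_k = per_k[, seq_len(kk), drop = FALSE], fused = fused,
       fused_score = fused_score)
}

#' Leave-one-out vote matrix of a classifier bank
#'
#' Produces the binary vote matrix feeding the voting ensembles: one row per
#' protein, one column per bank member, each entry the member's held-out
#' (leave-one-out) prediction for that protein. Neighbour-based members use a
#' masked-distance fast path; adapter members are naively refitted per fold.
#'
#' @param bank a [train_classifier_bank()] result.
#' @return 0/1 matrix with the true labels attached as attribute `y` and
#'   `score` (mean member score per protein) as attribute `score`.
#' @export
loocv_vote_matrix <- function(bank) {
  n <- length(bank$y)
  members <- bank$members
  if (any(!is.na(members$K)) && n - 1L < bank$k_max) {
    stop(sprintf("a per-K bank with K up to %d needs at least %d samples for leave-one-out",
                 bank$k_max, bank$k_max + 1L), call. = FALSE)
  }
  votes <- matrix(NA_integer_, n, nrow(members),
                  dimnames = list(bank$ids, members$id))
  scores <- matrix(NA_real_, n, length(bank$features))
  for (j in seq_along(bank$features)) {
    lam <- names(bank$features)[j]
    X <- bank$features[[j]]
    if (bank$algorithm %in% c("knn", "oetknn")) {
      lv <- loocv_neighbor_votes(X, bank$y, bank$k_max, bank$algorithm, bank$alpha0)
      rows <- which(members$lambda == as.integer(lam))
      if (any(is.na(members$K))) {
        votes[, rows] <- lv$fused
        scores[, j] <- lv$fused_score
      } else {
        votes[, rows] <- lv$per_k
        scores[, j] <- lv$fused_score
      }
    } else {
      pred <- integer(n)
      sc <- numeric(n)
      for (i in seq_len(n)) {
        clf <- fit_adapter(bank$algorithm, X[-i, , drop = FALSE], bank$y[-i],
                           seed = bank$seed)
        p <- predict_classifier(clf, X[i, , drop = FALSE])
        pred[i] <- p$label
        sc[i] <- p$score
      }
      votes[, which(members$lambda == as.integer(lam))] <- pred
      scores[, j] <- sc
    }
  }
  structure(votes, y = bank$y, score = rowMeans(scores))
}

#' Predict bank member votes for new proteins
#'
#' @param bank a [train_classifier_bank()] result.
#' @param dataset a [labeled_dataset()] with profiles for the query proteins
#'   (labels may be placeholders).
#' @return 0/1 vote matrix, one row per query protein, columns in bank order.
#' @export
predict_bank <- function(bank, dataset) {
  members <- bank$members
  votes <- matrix(NA_integer_, length(dataset$ids), nrow(members),
                  dimnames = list(dataset$ids, members$id))
  for (j in seq_along(bank$features)) {
    lam <- as.integer(names(bank$features)[j])
    Xtr <- bank$features[[j]]
    Xq <- encode_dataset(dataset, "psepssm", lambda = lam,
                         center_only = bank$center_only)
    rows <- which(members$lambda == lam)
    if (bank$algorithm %in% c("knn", "oetknn")) {
      D2tr <- as.matrix(stats::dist(Xtr))^2
      g <- gamma_heuristic(D2tr, bank$y)
      for (i in seq_len(nrow(Xq))) {
        if (any(is.na(members$K))) {
          votes[i, rows] <- if (bank$algorithm == "knn") {
            knn_vote_predict(Xtr, bank$y, Xq[i, ], bank$k_max)$label
          } else {
            oetknn_fused_predict(Xtr, bank$y, Xq[i, ], bank$k_max,
                                 bank$alpha0, g)$label
          }
        } else {
          votes[i, rows] <- vapply(members$K[rows], function(K) {
            if (bank$algorithm == "knn") {
              ord <- neighbor_order(Xtr, Xq[i, ])
              labs <- bank$y[ord]
              majority01(labs[seq_len(K)], labs[1L])
            } else {
              oetknn_predict(Xtr, bank$y, Xq[i, ], K, bank$alpha0, g)$label
            }
          }, integer(1))
        }
      }
    } else {
      votes[, rows] <- predict_classifier(bank$fitted[[as.character(lam)]], Xq)$label
    }
  }
  votes
}

#' The seven all-voting ensemble variants
#'
#' Enumerates the standard all-voting ensemble definitions over the profile
#' descriptor banks: one 50-member bank per adapter algorithm (SVM, GBM, RF),
#' 50-member fused banks for KNN and OET-KNN, and the 500-member per-(lambda,
#' K) banks for KNN and OET-KNN.
#'
#' @return `data.frame` with columns `name`, `algorithm`, `per_K` and
#'   `members` (the member count with the full lambda range 0..49).
#' @export
all_voting_variants <- function() {
  data.frame(
    name = c("SVM", "GBM", "RF", "KNN V50", "KNN V500",
             "OET-KNN V50", "OET-KNN V500"),
    algorithm = c("svm", "gbm", "rf", "knn", "knn", "oetknn", "oetknn"),
    per_K = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE),
    members = c(50L, 50L, 50L, 50L, 500L, 50L, 500L))
}
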