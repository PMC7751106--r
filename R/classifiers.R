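## Base learners. Labels are integer 0/1 with 1 = membrane (positive).
## Distances are Euclidean on the encoding vectors; neighbor ties are broken
## by training-set index, and all vote ties resolve to the K=1 decision.

## majority vote over 0/1 labels; tie -> tie_label
majority01 <- function(labels, tie_label) {
  pos <- sum(labels == 1L)
  n <- length(labels)
  if (2L * pos > n) 1L else if (2L * pos < n) 0L else as.integer(tie_label)
}

## ordered neighbor indices of a query against rows of X (ties by row index)
neighbor_order <- function(X, q) {
  d2 <- colSums((t(X) - q)^2)
  order(d2, seq_along(d2))
}

#' Fused majority-vote k-nearest-neighbour prediction
#'
#' Runs plain KNN for every K in 1..`k_max` (capped at the training size) and
#' fuses the sub-votes by majority. Within a single K, an even split is
#' resolved by the nearest neighbour's label; a tied fusion (e.g. 5-5) is
#' resolved by the K=1 label. The score is the fraction of positive
#' sub-votes.
#'
#' @param train numeric matrix of training feature vectors (rows).
#' @param y integer 0/1 labels for the training rows.
#' @param q numeric query feature vector.
#' @param k_max largest neighbourhood size, default 10.
#' @return List with `label` (0/1) and `score` in `[0, 1]`.
#' @export
knn_vote_predict <- function(train, y, q, k_max = 10L) {
  train <- as.matrix(train)
  if (nrow(train) < 1L) stop("empty training set", call. = FALSE)
  ord <- neighbor_order(train, q)
  labs <- as.integer(y)[ord]
  kk <- min(k_max, nrow(train))
  votes <- vapply(seq_len(kk), function(K) majority01(labs[seq_len(K)], labs[1L]),
                  integer(1))
  list(label = majority01(votes, votes[1L]), score = mean(votes == 1L))
}

## gamma heuristic: per-class inverse mean squared pairwise distance, with an
## all-pairs fallback for degenerate classes
gamma_heuristic <- function(D2, y) {
  g <- c(NA_real_, NA_real_)
  for (cl in 0:1) {
    idx <- which(y == cl)
    m <- length(idx)
    if (m >= 2L) {
      tot <- sum(D2[idx, idx])
      if (tot > 0) g[cl + 1L] <- m * (m - 1L) / tot
    }
  }
  n <- nrow(D2)
  tot_all <- sum(D2)
  fallback <- if (n >= 2L && tot_all > 0) n * (n - 1L) / tot_all else 1
  g[is.na(g)] <- fallback
  g
}

## Dempster combination over the two-class frame for K neighbors.
## labels: 0/1 per neighbor (nearest first); d2: squared distances;
## mass on the neighbor's class is alpha0 * exp(-gamma_class * d2).
## Returns the pignistic probability of the positive class.
dempster_pignistic <- function(labels, d2, alpha0, gamma) {
  m_pos <- 0; m_neg <- 0; m_theta <- 1
  for (i in seq_along(labels)) {
    a <- alpha0 * exp(-gamma[labels[i] + 1L] * d2[i])
    if (labels[i] == 1L) {
      conflict <- m_neg * a
      pos <- m_pos + m_theta * a
      neg <- m_neg * (1 - a)
    } else {
      conflict <- m_pos * a
      pos <- m_pos * (1 - a)
      neg <- m_neg + m_theta * a
    }
    theta <- m_theta * (1 - a)
    z <- 1 - conflict
    m_pos <- pos / z; m_neg <- neg / z; m_theta <- theta / z
  }
  m_pos + m_theta / 2
}

#' Evidence-theoretic k-nearest-neighbour prediction
#'
#' Each of the K nearest neighbours contributes a Dempster-Shafer mass
#' function: mass `alpha0 * exp(-gamma_c * d^2)` on its own class and the
#' remainder on the whole frame. Masses are combined by Dempster's rule and
#' the class with the larger pignistic probability wins; an exact tie is
#' resolved by the nearest neighbour's label. The score is the pignistic
#' probability of the positive class.
#'
#' @param train numeric matrix of training feature vectors.
#' @param y integer 0/1 training labels.
#' @param q numeric query vector.
#' @param K neighbourhood size, 1 <= K <= nrow(train).
#' @param alpha0 evidence strength in (0, 1), default 0.95.
#' @param gamma length-2 positive kernel scales for classes 0 and 1; when
#'   `NULL`, the per-class inverse mean squared pairwise distance heuristic
#'   is used.
#' @return List with `label` (0/1) and `score` in `[0, 1]`.
#' @export
oetknn_predict <- function(train, y, q, K, alpha0 = 0.95, gamma = NULL) {
  train <- as.matrix(train)
  n <- nrow(train)
  if (K < 1L || K > n) stop("K must satisfy 1 <= K <= n", call. = FALSE)
  if (alpha0 <= 0 || alpha0 >= 1) stop("alpha0 must be in (0, 1)", call. = FALSE)
  if (is.null(gamma)) {
    D2 <- as.matrix(stats::dist(train))^2
    gamma <- gamma_heuristic(D2, as.integer(y))
  }
  if (any(gamma <= 0)) stop("gamma must be positive", call. = FALSE)
  d2 <- colSums((t(train) - q)^2)
  ord <- order(d2, seq_along(d2))[seq_len(K)]
  labs <- as.integer(y)[ord]
  betp <- dempster_pignistic(labs, d2[ord], alpha0, gamma)
  label <- if (betp > 0.5) 1L else if (betp < 0.5) 0L else labs[1L]
  list(label = label, score = betp)
}

#' Fused evidential KNN over K = 1..k_max
#'
#' Majority vote over the [oetknn_predict()] sub-votes for every K in
#' 1..`k_max` (capped at the training size); a tied fusion resolves to the
#' K=1 evidential label. Score is the fraction of positive sub-votes.
#'
#' @inheritParams oetknn_predict
#' @param k_max largest neighbourhood size, default 10.
#' @export
oetknn_fused_predict <- function(train, y, q, k_max = 10L, alpha0 = 0.95,
                                 gamma = NULL) {
  train <- as.matrix(train)
  n <- nrow(train)
  if (n < 1L) stop("empty training set", call. = FALSE)
  if (is.null(gamma)) {
    D2 <- as.matrix(stats::dist(train))^2
    gamma <- gamma_heuristic(D2, as.integer(y))
  }
  d2 <- colSums((t(train) - q)^2)
  ord <- order(d2, seq_along(d2))
  labs <- as.integer(y)[ord]
  d2s <- d2[ord]
  kk <- min(k_max, n)
  votes <- vapply(seq_len(kk), function(K) {
    betp <- dempster_pignistic(labs[seq_len(K)], d2s[seq_len(K)], alpha0, gamma)
    if (betp > 0.5) 1L else if (betp < 0.5) 0L else labs[1L]
  }, integer(1))
  list(label = majority01(votes, votes[1L]), score = mean(votes == 1L))
}

#' Fit an off-the-shelf adapter classifier (SVM, GBM or RF)
#'
#' Thin wrappers around `e1071::svm` (RBF kernel), `xgboost` and
#' `randomForest`. When `hyper_grid` is supplied, the parameter combination
#' maximising internal stratified cross-validation accuracy is selected, with
#' ties going to the smallest parameter values.
#'
#' @param algorithm `"svm"`, `"gbm"` or `"rf"`.
#' @param train numeric feature matrix.
#' @param y integer 0/1 labels; both classes must be present.
#' @param hyper_grid optional named list of parameter vectors: `cost`/`gamma`
#'   for SVM, `mtry` for RF, `eta`/`max_depth` for GBM.
#' @param cv_folds folds for the internal grid-search CV, default 3.
#' @param seed seed for the internal CV partition.
#' @return An object of class `trained_classifier` with a deterministic
#'   `predict_classifier()` contract.
#' @export
fit_adapter <- function(algorithm = c("svm", "gbm", "rf"), train, y,
                        hyper_grid = NULL, cv_folds = 3L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  train <- as.matrix(train)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  params <- default_adapter_params(algorithm, train)
  if (!is.null(hyper_grid)) {
    grid <- expand.grid(hyper_grid, KEEP.OUT.ATTRS = FALSE)
    grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
    if (nrow(grid) > 1L) {
      folds <- make_folds(y, min(cv_folds, min(table(y))), seed = seed)
      accs <- vapply(seq_len(nrow(grid)), function(g) {
        p <- utils::modifyList(params, as.list(grid[g, , drop = FALSE]))
        mean(vapply(seq_len(max(folds)), function(f) {
          tr <- folds != f
          m <- fit_adapter_raw(algorithm, train[tr, , drop = FALSE], y[tr], p, seed)
          mean(adapter_labels(algorithm, m, train[!tr, , drop = FALSE]) == y[!tr])
        }, numeric(1)))
      }, numeric(1))
      params <- utils::modifyList(params, as.list(grid[which.max(accs), , drop = FALSE]))
    } else {
      params <- utils::modifyList(params, as.list(grid[1L, , drop = FALSE]))
    }
  }
  model <- fit_adapter_raw(algorithm, train, y, params, seed)
  structure(list(algorithm = algorithm, model = model, params = params),
            class = "trained_classifier")
}

default_adapter_params <- function(algorithm, train) {
  switch(algorithm,
         svm = list(cost = 1, gamma = 1 / ncol(train)),
         rf  = list(mtry = max(1L, floor(sqrt(ncol(train)))), ntree = 200L),
         gbm = list(eta = 0.3, max_depth = 3L, nrounds = 50L))
}

fit_adapter_raw <- function(algorithm, X, y, params, seed) {
  set.seed(seed)
  switch(algorithm,
    svm = e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
                     cost = params$cost, gamma = params$gamma, scale = FALSE),
    rf  = randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                     mtry = min(params$mtry, ncol(X)),
                                     ntree = params$ntree),
    gbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = params$eta,
                    max_depth = params$max_depth, nthread = 1L),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = params$nrounds, verbose = 0))
}

adapter_labels <- function(algorithm, model, X) {
  switch(algorithm,
    svm = as.integer(as.character(stats::predict(model, X))),
    rf  = as.integer(as.character(stats::predict(model, X))),
    gbm = as.integer(stats::predict(model, xgboost::xgb.DMatrix(X)) > 0.5))
}

adapter_scores <- function(algorithm, model, X) {
  switch(algorithm,
    svm = {
      dv <- attr(stats::predict(model, X, decision.values = TRUE),
                 "decision.values")
      ## orient the decision value so larger means more positive-class
      pos_first <- grepl("^1", colnames(dv)[1])
      stats::plogis(if (pos_first) dv[, 1] else -dv[, 1])
    },
    rf  = stats::predict(model, X, type = "prob")[, "1"],
    gbm = stats::predict(model, xgboost::xgb.DMatrix(X)))
}

#' Predict with a trained adapter classifier
#'
#' @param clf a `trained_classifier` from [fit_adapter()].
#' @param X numeric feature matrix of query rows.
#' @return `data.frame` with columns `label` (0/1) and `score` (positive-class
#'   score in `[0, 1]`).
#' @export
predict_classifier <- function(clf, X) {
  X <- as.matrix(X)
  data.frame(label = adapter_labels(clf$algorithm, clf$model, X),
             score = as.numeric(adapter_scores(clf$algorithm, clf$model, X)))
}
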