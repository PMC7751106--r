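#' Confusion counts for binary membrane predictions
#'
#' @param pred 0/1 predicted labels (1 = membrane, the positive class).
#' @param truth 0/1 true labels of equal length.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("prediction and truth lengths differ", call. = FALSE)
  }
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  structure(list(tp = sum(pred == 1L & truth == 1L),
                 fp = sum(pred == 1L & truth == 0L),
                 tn = sum(pred == 0L & truth == 0L),
                 fn = sum(pred == 0L & truth == 1L)),
            class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy (TP+TN)/n, and
#' the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). When any factor
#' under the MCC square root is zero the MCC is defined as 0 (the
#' "no better than random" convention). An undefined sensitivity or
#' specificity (empty class) is reported as `NA`.
#'
#' @param cc a [confusion()] result, or a list with tp/fp/tn/fn.
#' @return An object of class `metrics_report` with proportions in `[0, 1]`;
#'   the print method shows percentages rounded to two decimals.
#' @export
metrics <- function(cc) {
  tp <- cc$tp; fp <- cc$fp; tn <- cc$tn; fn <- cc$fn
  n <- tp + fp + tn + fn
  if (n == 0L) stop("all confusion counts are zero", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den) else 0
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / n, mcc = mcc,
                 auc = NA_real_, counts = cc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%  MCC %.4f%s\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy, x$mcc,
              if (!is.na(x$auc)) sprintf("  AUC %.4f", x$auc) else ""))
  invisible(x)
}

#' Leave-one-out cross-validation of a generic learner
#'
#' Each sample is predicted by a model fitted on all other samples. The
#' learner is a list with `fit(X, y) -> model` and
#' `predict(model, X) -> data.frame(label, score)`.
#'
#' @param X numeric feature matrix.
#' @param y 0/1 labels.
#' @param learner list with `fit` and `predict` functions.
#' @return List with `pred` (0/1), `score`, and a [metrics()] report with AUC
#'   when scores are available.
#' @export
loocv <- function(X, y, learner) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("leave-one-out requires n >= 2", call. = FALSE)
  pred <- integer(n)
  score <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    model <- learner$fit(X[-i, , drop = FALSE], y[-i])
    p <- learner$predict(model, X[i, , drop = FALSE])
    pred[i] <- as.integer(p$label)
    if (!is.null(p$score)) score[i] <- p$score
  }
  rep_out <- metrics(confusion(pred, y))
  if (!anyNA(score) && length(unique(y)) == 2L) {
    rep_out$auc <- roc_auc(score, y)$auc
  }
  list(pred = pred, score = score, metrics = rep_out)
}

## stratified fold assignment; a global round-robin cursor keeps overall fold
## sizes within one of each other
make_folds <- function(y, k, seed = 1L) {
  n <- length(y)
  if (k < 2L || k > n) stop("k must satisfy 2 <= k <= n", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  cursor <- 0L
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    idx <- if (length(idx) > 1L) sample(idx) else idx
    fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
    cursor <- cursor + length(idx)
  }
  fold
}

#' Stratified k-fold cross-validation of a generic learner
#'
#' @inheritParams loocv
#' @param k number of folds, 2 <= k <= n; `k = n` reduces to leave-one-out.
#' @param seed seed for the stratified partition.
#' @param stratified stratify folds by class, default `TRUE`.
#' @return List with `pred`, `score`, `fold` and a [metrics()] report.
#' @export
kfold <- function(X, y, learner, k = 5L, seed = 1L, stratified = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  fold <- if (stratified) {
    make_folds(y, k, seed)
  } else {
    set.seed(seed)
    sample(rep_len(seq_len(k), n))
  }
  pred <- integer(n)
  score <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) {
      stop(sprintf("fold %d leaves a single-class training set", f), call. = FALSE)
    }
    model <- learner$fit(X[tr, , drop = FALSE], y[tr])
    p <- learner$predict(model, X[!tr, , drop = FALSE])
    pred[!tr] <- as.integer(p$label)
    if (!is.null(p$score)) score[!tr] <- p$score
  }
  rep_out <- metrics(confusion(pred, y))
  if (!anyNA(score) && length(unique(y)) == 2L) {
    rep_out$auc <- roc_auc(score, y)$auc
  }
  list(pred = pred, score = score, fold = fold, metrics = rep_out)
}

#' ROC curve and AUC
#'
#' AUC by the midrank (Mann-Whitney) method: the probability that a random
#' positive scores above a random negative, with ties counted half. Curve
#' points are computed at every distinct score threshold.
#'
#' @param scores numeric positive-class scores.
#' @param truth 0/1 labels; both classes must be present.
#' @return List with `points` (`data.frame` of threshold, fpr, tpr) and
#'   `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  if (length(scores) != length(truth)) {
    stop("scores and truth lengths differ", call. = FALSE)
  }
  np <- sum(truth == 1L)
  nn <- sum(truth == 0L)
  if (np == 0L || nn == 0L) {
    stop("ROC analysis needs both classes present", call. = FALSE)
  }
  r <- rank(scores)
  auc <- (sum(r[truth == 1L]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, vapply(thr, function(t) sum(scores >= t & truth == 0L) / nn,
                                      numeric(1))),
                    tpr = c(0, vapply(thr, function(t) sum(scores >= t & truth == 1L) / np,
                                      numeric(1))))
  list(points = pts, auc = auc)
}
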