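## Voting ensembles over a binary vote matrix: rows = proteins, columns =
## constituent classifiers in bank order, entries in {0, 1}.

MI_RHO_GUARD <- 1e-12

#' Majority vote over all constituent classifiers
#'
#' Per protein, the class with the most votes wins; an exact tie resolves to
#' the first column's vote (bank-order position one).
#'
#' @param vm 0/1 vote matrix with at least one column and no missing entries.
#' @return Integer 0/1 label vector, one per row.
#' @export
all_vote <- function(vm) {
  vm <- as.matrix(vm)
  if (ncol(vm) < 1L) stop("empty vote matrix", call. = FALSE)
  if (anyNA(vm)) stop("vote matrix contains missing entries", call. = FALSE)
  pos <- rowSums(vm == 1L)
  nc <- ncol(vm)
  ifelse(2 * pos > nc, 1L, ifelse(2 * pos < nc, 0L, as.integer(vm[, 1L])))
}

#' Correlation-based mutual information between two binary columns
#'
#' The linear (Gaussian) approximation MI = -1/2 ln(1 - rho^2) with rho the
#' Pearson correlation (the phi coefficient on 0/1 columns). A zero-variance
#' column yields 0; |rho| = 1 is capped at -1/2 ln(1e-12) so that perfectly
#' redundant columns keep a finite, order-preserving penalty.
#'
#' @param a,b equal-length numeric/binary vectors (length >= 2).
#' @return Non-negative scalar MI estimate.
#' @export
mi_correlation <- function(a, b) {
  if (length(a) != length(b)) stop("columns must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("columns must have length >= 2", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  rho <- stats::cor(a, b)
  if (rho^2 >= 1 - MI_RHO_GUARD) return(-0.5 * log(MI_RHO_GUARD))
  -0.5 * log(1 - rho^2)
}

#' Greedy mRMR ranking of vote-matrix columns
#'
#' Ranks the constituent classifiers by maximum relevance (MI with the target
#' class) and minimum redundancy, using the mutual information difference
#' (MID) criterion: at each step the unranked column maximising
#' `MI(c, y) - mean(MI(c, selected))` is appended; ties go to the lower
#' column index. The first column maximises plain relevance.
#'
#' @param vm 0/1 vote matrix with >= 2 columns.
#' @param y 0/1 target labels, one per row.
#' @return An object of class `ranked_list`: `order` (a permutation of column
#'   indices) and `scores` (the MID value at each selection step).
#' @export
mrmr_rank <- function(vm, y) {
  vm <- as.matrix(vm)
  n <- ncol(vm)
  if (n < 2L) stop("mRMR ranking needs at least two columns", call. = FALSE)
  rel <- vapply(seq_len(n), function(j) mi_correlation(vm[, j], y), numeric(1))
  order_out <- integer(n)
  scores <- numeric(n)
  selected <- logical(n)
  red_sum <- numeric(n)
  first <- which.max(rel)
  order_out[1L] <- first
  scores[1L] <- rel[first]
  selected[first] <- TRUE
  for (step in seq_len(n - 1L)) {
    last <- order_out[step]
    rest <- which(!selected)
    red_sum[rest] <- red_sum[rest] + vapply(rest, function(j) {
      mi_correlation(vm[, j], vm[, last])
    }, numeric(1))
    mid <- rel[rest] - red_sum[rest] / step
    pick <- rest[which.max(mid)]
    order_out[step + 1L] <- pick
    scores[step + 1L] <- max(mid)
    selected[pick] <- TRUE
  }
  structure(list(order = order_out, scores = scores), class = "ranked_list")
}

#' Incremental selection of the optimal classifier subset
#'
#' Evaluates the prefix sets s_1..s_n of the mRMR ranking (adding one
#' component at a time in ascending rank order) and returns the prefix whose
#' majority vote best matches the target labels; ties go to the smallest
#' prefix. Because the vote matrix already holds held-out (leave-one-out)
#' votes, the criterion is a LOOCV accuracy.
#'
#' @param vm 0/1 vote matrix.
#' @param y 0/1 target labels.
#' @param ranked a [mrmr_rank()] result covering all columns.
#' @return An object of class `selection_result`: `subset_size`,
#'   `member_indices`, `criterion_accuracy`, and the full `prefix_accuracies`.
#' @export
incremental_select <- function(vm, y, ranked) {
  vm <- as.matrix(vm)
  if (length(ranked$order) != ncol(vm)) {
    stop("ranking must cover all vote-matrix columns", call. = FALSE)
  }
  accs <- vapply(seq_along(ranked$order), function(i) {
    mean(all_vote(vm[, ranked$order[seq_len(i)], drop = FALSE]) == y)
  }, numeric(1))
  best <- which.max(accs)
  structure(list(subset_size = best,
                 member_indices = ranked$order[seq_len(best)],
                 criterion_accuracy = accs[best],
                 prefix_accuracies = accs),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d member(s), criterion accuracy %.4f\n",
              x$subset_size, x$criterion_accuracy))
  invisible(x)
}

#' Majority vote restricted to the selected subset
#'
#' @param vm 0/1 vote matrix.
#' @param sel a [incremental_select()] result (or any list with
#'   `member_indices`).
#' @return Integer 0/1 label vector.
#' @export
selective_vote <- function(vm, sel) {
  all_vote(as.matrix(vm)[, sel$member_indices, drop = FALSE])
}
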