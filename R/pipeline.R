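#' Run the full membrane-detection pipeline on a labeled dataset
#'
#' Trains a lambda-parameterized bank of profile-descriptor classifiers,
#' builds the leave-one-out vote matrix, evaluates the all-voting ensemble,
#' ranks the constituent classifiers by mRMR and selects the optimal prefix
#' (selective voting), and finally integrates the selected votes with
#' external topology calls through the weighted-voting rule.
#'
#' @param dataset a [labeled_dataset()] with profiles.
#' @param calls optional named list of [topology_call()]; when `NULL` the
#'   integration step is skipped.
#' @param algorithm base learner for the bank, default `"oetknn"`.
#' @param lambda_range lambda values for the bank, default 0:9.
#' @param per_K build the per-(lambda, K) bank, default `TRUE`.
#' @param k_max largest neighbourhood size.
#' @param alpha0 evidence strength for OET-KNN members.
#' @return List with the bank, vote matrix, all-voting and selective-voting
#'   labels and metrics, the ranking and selection, and (when calls are
#'   given) the integrated labels and metrics.
#' @export
run_pipeline <- function(dataset, calls = NULL, algorithm = "oetknn",
                         lambda_range = 0:9, per_K = TRUE, k_max = 10L,
                         alpha0 = 0.95) {
  bank <- train_classifier_bank(dataset, algorithm, lambda_range,
                                per_K = per_K, k_max = k_max, alpha0 = alpha0)
  vm <- loocv_vote_matrix(bank)
  y <- attr(vm, "y")
  all_labels <- all_vote(vm)
  ranked <- mrmr_rank(vm, y)
  sel <- incremental_select(vm, y, ranked)
  sel_labels <- selective_vote(vm, sel)
  out <- list(bank = bank, vote_matrix = vm, y = y,
              ranked = ranked, selection = sel,
              all_vote = list(labels = all_labels,
                              metrics = metrics(confusion(all_labels, y))),
              selective = list(labels = sel_labels,
                               metrics = metrics(confusion(sel_labels, y))))
  if (!is.null(calls)) {
    sv <- vm[, sel$member_indices, drop = FALSE]
    out$integrated <- batch_integrate(dataset$ids, sv, sel_labels, calls,
                                      truth = y)
  }
  out
}
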