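## Integration of the selective-voting ensemble with an external
## transmembrane-topology predictor's calls, via weighted voting. A positive
## topology call carries weight equal to the number of selected constituent
## classifiers minus one, so the ensemble decision flips to positive if and
## only if at least one constituent classifier agrees with the positive
## topology call. Negative topology calls carry weight zero and never demote.

#' Integrate one protein's ensemble decision with a topology call
#'
#' @param constituent_votes 0/1 votes of the selected constituent classifiers
#'   for this protein (the votes that produced `ensemble_label`).
#' @param ensemble_label the selective-voting ensemble's 0/1 decision.
#' @param topo a [topology_call()] for this protein, or `NULL` when absent.
#' @return Integer 0/1 final label.
#' @export
decide_with_topology <- function(constituent_votes, ensemble_label, topo = NULL) {
  if (length(constituent_votes) == 0L) {
    stop("constituent vote list must be non-empty", call. = FALSE)
  }
  if (!is.null(topo) && topo$is_membrane && any(constituent_votes == 1L)) {
    return(1L)
  }
  as.integer(ensemble_label)
}

#' Integrate ensemble outputs with topology calls over a dataset
#'
#' Applies [decide_with_topology()] per protein. A protein without a topology
#' call is treated as call-absent (the ensemble label stands).
#'
#' @param ids protein identifiers, one per vote-matrix row.
#' @param selected_votes 0/1 matrix of the selected constituent classifiers'
#'   votes (rows align with `ids`).
#' @param ensemble_labels 0/1 selective-voting labels, one per id.
#' @param calls named list of [topology_call()] keyed by protein id (may cover
#'   a subset of `ids`).
#' @param truth optional 0/1 true labels; when given, a [metrics()] report is
#'   attached.
#' @return List with `table` (id, ensemble_label, topology_tms, final_label,
#'   positive_votes) and, when truth is supplied, `metrics`.
#' @export
batch_integrate <- function(ids, selected_votes, ensemble_labels, calls,
                            truth = NULL) {
  selected_votes <- as.matrix(selected_votes)
  stopifnot(length(ids) == nrow(selected_votes),
            length(ids) == length(ensemble_labels))
  final <- integer(length(ids))
  tms <- rep(NA_integer_, length(ids))
  for (i in seq_along(ids)) {
    topo <- calls[[ids[i]]]
    if (!is.null(topo)) tms[i] <- topo$tms_count
    final[i] <- decide_with_topology(selected_votes[i, ], ensemble_labels[i], topo)
  }
  out <- list(table = data.frame(id = ids,
                                 ensemble_label = as.integer(ensemble_labels),
                                 topology_tms = tms,
                                 final_label = final,
                                 positive_votes = rowSums(selected_votes == 1L)))
  if (!is.null(truth)) out$metrics <- metrics(confusion(final, truth))
  out
}
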