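# End-to-end assembly: train the three classifiers on one training bundle
# (compounds + scores + peaks + descriptors), apply them to an evaluation
# bundle, combine the votes, and audit the potent counts against the
# training prior.

#' Train the three-classifier consensus on a data bundle
#'
#' Trains the docking-score logistic model (manual selection), the
#' spectral discriminant model and the descriptor decision forest on one
#' training bundle, as produced by [gen_study()] or assembled from files.
#'
#' @param train list with `compounds` (id, mw, category), `scores`,
#'   `peaks`, `descriptors`.
#' @param f_enter F-to-enter for the spectral model.
#' @param min_bin_compounds spectral bin population filter.
#' @param min_entropy descriptor entropy filter threshold.
#' @return list of class `"consensus_model"` with the three fitted models
#'   and the preprocessing state needed to apply them.
#' @export
train_consensus <- function(train, f_enter = 4.0, min_bin_compounds = 3,
                            min_entropy = 0.5) {
  reconcile_compounds(compounds = train$compounds, scores = train$scores,
                      descriptors = train$descriptors)
  labels <- train$compounds$category
  z <- standardize_scores(train$scores)
  dlr <- select_manual(z, labels)
  bins <- filter_bins(bin_spectra(train$peaks, ids = train$compounds$id),
                      min_compounds = min_bin_compounds)
  sdar <- train_discriminant(bins, labels, f_enter = f_enter)
  descriptors <- filter_descriptors(train$descriptors,
                                    min_entropy = min_entropy)
  forest <- train_forest(descriptors, labels)
  structure(list(dlr = dlr,
                 standardization = attr(z, "standardization"),
                 sdar = sdar,
                 forest = forest,
                 descriptor_columns = colnames(descriptors)),
            class = "consensus_model")
}

#' Apply a trained consensus model to an evaluation bundle
#'
#' Scores every compound with the three classifiers, combines the votes
#' under the requested strategy, and audits the potent-call counts against
#' the training prior (overall and per MW band).
#'
#' @param model `"consensus_model"` from [train_consensus()].
#' @param ev list with `compounds`, `scores`, `peaks`, `descriptors`.
#' @param strategy consensus strategy, see [combine_votes()].
#' @param cutoff DLR probability cutoff.
#' @param ... passed to [audit_counts()] (priors, confidence).
#' @return list with `votes`, `calls` (consensus data.frame) and `audit`.
#' @export
apply_consensus <- function(model, ev, strategy = "MAJORITY",
                            cutoff = 0.5, ...) {
  z_ev <- standardize_scores(ev$scores, stats = model$standardization)
  p_dlr <- score_probability(model$dlr, z_ev, cutoff = cutoff)$call
  bins_ev <- bin_spectra(ev$peaks, ids = ev$compounds$id)
  p_sdar <- classify_sdar(model$sdar, bins_ev)$call
  p_sar <- classify_forest(model$forest,
                           ev$descriptors[, model$descriptor_columns,
                                          drop = FALSE])$call
  votes <- data.frame(id = ev$compounds$id, dlr = p_dlr, sdar = p_sdar,
                      sar = p_sar, stringsAsFactors = FALSE)
  calls <- combine_votes(votes, strategy = strategy)
  audit <- audit_counts(calls, bands = ev$compounds$band, ...)
  list(votes = votes, calls = calls, audit = audit)
}
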