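# Spectral data-activity relationship (SDAR) classifier: predicted 13C/15N
# chemical shifts are binned (1 ppm carbon, 5 ppm nitrogen), sparsely
# populated bins are dropped, and a linear discriminant model with equal
# class priors is grown by forward selection with an F-to-enter threshold.

#' Bin NMR peak lists into a compound-by-bin matrix
#'
#' Each peak falls in bin `floor(shift / width)` for its nucleus; the cell
#' value is the number of peaks the compound has in the bin. Carbon and
#' nitrogen bins are namespaced separately (`C<i>`, `N<i>`).
#'
#' @param peaks data.frame with columns `id`, `nucleus` (`"13C"`/`"15N"`),
#'   `shift` (ppm), as from [read_peak_lists()].
#' @param ids compound identifiers to include (rows of the output);
#'   defaults to the compounds present in `peaks`. Compounds with no peaks
#'   get a zero row with a warning.
#' @param c_width,n_width bin widths in ppm.
#' @param binary count each bin as present/absent instead of peak counts.
#' @return integer matrix, compounds in rows, populated bins in columns.
#' @export
bin_spectra <- function(peaks, ids = NULL, c_width = 1, n_width = 5,
                        binary = FALSE) {
  stopifnot(c_width > 0, n_width > 0)
  if (is.null(ids)) ids <- unique(peaks$id)
  width <- ifelse(peaks$nucleus == "13C", c_width, n_width)
  prefix <- ifelse(peaks$nucleus == "13C", "C", "N")
  bin <- paste0(prefix, floor(peaks$shift / width))
  bins <- sort(unique(bin))
  m <- matrix(0L, nrow = length(ids), ncol = length(bins),
              dimnames = list(ids, bins))
  keep <- peaks$id %in% ids
  if (any(keep)) {
    tab <- table(factor(peaks$id[keep], levels = ids),
                 factor(bin[keep], levels = bins))
    m[] <- as.integer(tab)
  }
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("compound(s) with no peaks: ",
            paste(ids[empty], collapse = ", "))
  }
  if (binary) m <- (m > 0) + 0L
  m
}

#' Drop sparsely populated spectral bins
#'
#' Retains bins hit by at least `min_compounds` distinct compounds
#' (nonzero count), the population filter applied before discriminant
#' training.
#'
#' @param m bin matrix from [bin_spectra()].
#' @param min_compounds minimum number of distinct compounds per bin.
#' @return filtered bin matrix (possibly zero columns).
#' @export
filter_bins <- function(m, min_compounds = 3) {
  keep <- colSums(m > 0) >= min_compounds
  m[, keep, drop = FALSE]
}

# Partial F-to-enter for adding column `cand` to the bins in `selected`,
# computed on the regression of the class indicator (equivalent to the
# two-group stepwise discriminant F).
.f_to_enter <- function(x, y, selected, cand) {
  n <- length(y)
  x_old <- cbind(1, x[, selected, drop = FALSE])
  x_new <- cbind(x_old, x[, cand])
  q_new <- qr(x_new)
  if (q_new$rank < ncol(x_new)) return(NA_real_)  # collinear candidate
  rss_old <- sum(qr.resid(qr(x_old), y)^2)
  rss_new <- sum(qr.resid(q_new, y)^2)
  df2 <- n - ncol(x_new)
  if (df2 <= 0 || rss_new <= 0) return(NA_real_)
  (rss_old - rss_new) / (rss_new / df2)
}

#' Train a forward-stepwise linear discriminant model on spectral bins
#'
#' At each step the bin with the largest partial F among those exceeding
#' `f_enter` joins the model (ties break toward the lower bin index in
#' column order); selection stops when no candidate qualifies. The final
#' linear discriminant uses equal class priors regardless of training
#' imbalance. Collinear candidates are skipped.
#'
#' @param m filtered bin matrix.
#' @param labels `"P"`/`"W"` per row.
#' @param f_enter F-to-enter threshold.
#' @param max_bins optional cap on selected bins (default rows - 2).
#' @return object of class `"sdar_model"`: `bins` (in entry order),
#'   `f_values`, and the fitted `MASS::lda` object with equal priors.
#' @export
train_discriminant <- function(m, labels, f_enter = 4.0, max_bins = NULL) {
  labels <- .check_labels(labels)
  if (min(table(labels)) < 2) stop("need >= 2 compounds per class")
  if (is.null(max_bins)) max_bins <- nrow(m) - 2
  y <- as.numeric(labels == "P")
  x <- m * 1.0
  # bins with zero pooled within-class variance make the discriminant
  # singular; they are skipped with a warning
  within_var <- vapply(colnames(x), function(b) {
    sum(stats::ave(x[, b], labels, FUN = function(v) v - mean(v))^2)
  }, 0.0)
  if (any(within_var == 0)) {
    warning("skipping bin(s) with singular within-class variance: ",
            paste(colnames(x)[within_var == 0], collapse = ", "))
  }
  usable <- colnames(x)[within_var > 0]
  selected <- character()
  f_values <- numeric()
  repeat {
    candidates <- setdiff(usable, selected)
    if (!length(candidates) || length(selected) >= max_bins) break
    fs <- vapply(candidates, function(cand)
      .f_to_enter(x, y, selected, cand), 0.0)
    fs[is.na(fs)] <- -Inf
    best <- which.max(fs)  # first max = lowest column index on ties
    if (fs[best] > f_enter) {
      selected <- c(selected, candidates[best])
      f_values <- c(f_values, fs[best])
    } else break
  }
  lda_fit <- NULL
  if (length(selected)) {
    lda_fit <- MASS::lda(x[, selected, drop = FALSE], grouping = labels,
                         prior = c(0.5, 0.5))
  }
  structure(list(bins = selected,
                 f_values = stats::setNames(f_values, selected),
                 lda = lda_fit,
                 class_counts = table(labels)),
            class = "sdar_model")
}

#' Classify compounds with a trained SDAR model
#'
#' Posterior class probabilities from the linear discriminant under equal
#' priors; the call is the class with the larger posterior. Rows carrying
#' none of the selected bins are classified from the class centroids alone
#' and flagged low-information. A model with no selected bins returns the
#' uninformative posterior 0.5.
#'
#' @param model `"sdar_model"`.
#' @param m bin matrix covering (at least) the model's bins; absent bins
#'   are treated as zero counts.
#' @return data.frame with `id`, `posterior_p`, `call`, `low_information`.
#' @export
classify_sdar <- function(model, m) {
  ids <- rownames(m) %||% seq_len(nrow(m))
  if (!length(model$bins)) {
    return(data.frame(id = ids, posterior_p = 0.5,
                      call = "W", low_information = TRUE,
                      stringsAsFactors = FALSE))
  }
  x <- matrix(0, nrow = nrow(m), ncol = length(model$bins),
              dimnames = list(ids, model$bins))
  have <- intersect(colnames(m), model$bins)
  x[, have] <- m[, have]
  pred <- stats::predict(model$lda, newdata = x)
  post_p <- pred$posterior[, "P"]
  data.frame(id = ids, posterior_p = unname(post_p),
             call = ifelse(post_p > 0.5, "P", "W"),
             low_information = rowSums(x != 0) == 0,
             stringsAsFactors = FALSE)
}
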