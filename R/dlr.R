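# Docking-score logistic-regression classifier (DLR): column
# standardization with stored training statistics, maximum-likelihood
# logistic fits with Wald statistics, forward/backward/manual variable
# selection, ROC and cutoff analysis with the named operating points, fixed
# published coefficients for scoring, and the MW-truncated applicability
# domain.

#' Standardize a docking-score matrix
#'
#' Converts raw docking scores to z-scores per column. At training time the
#' per-column mean and SD are computed and stored; at apply time the stored
#' training statistics are reused so new compounds are placed on the
#' training scale.
#'
#' @param m numeric matrix, compounds in rows.
#' @param stats optional training statistics (a `score_standardization`
#'   object) to reuse.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return standardized matrix with the statistics in
#'   `attr(, "standardization")`.
#' @export
standardize_scores <- function(m, stats = NULL, sd_type = c("sample",
                                                            "population")) {
  sd_type <- match.arg(sd_type)
  if (is.null(stats)) {
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    if (sd_type == "population") {
      n <- nrow(m)
      sdv <- sdv * sqrt((n - 1) / n)
    }
    if (any(sdv == 0)) {
      stop("constant column(s): ",
           paste(colnames(m)[sdv == 0], collapse = ", "))
    }
    stats <- structure(list(mean = mu, sd = sdv, sd_type = sd_type),
                       class = "score_standardization")
  } else {
    if (!all(colnames(m) %in% names(stats$mean))) {
      stop("matrix columns do not match the stored standardization")
    }
  }
  z <- sweep(sweep(m, 2, stats$mean[colnames(m)], "-"),
             2, stats$sd[colnames(m)], "/")
  attr(z, "standardization") <- stats
  z
}

.check_labels <- function(labels) {
  labels <- factor(as.character(labels), levels = c("W", "P"))
  if (anyNA(labels)) stop("labels must be 'P' or 'W'")
  if (nlevels(droplevels(labels)) < 2) stop("both classes must be present")
  labels
}

#' Fit a logistic-regression model on standardized scores
#'
#' Maximum-likelihood logistic regression of the potent/weak label on the
#' given columns (iteratively reweighted least squares), with per-term
#' standard errors from the observed information and Wald chi-square tests.
#' Potent is the modelled (positive) class.
#'
#' @param z standardized score matrix.
#' @param labels `"P"`/`"W"` per row.
#' @param columns columns to use (default all).
#' @param selection tag recorded on the model.
#' @return object of class `"dlr_model"`: `intercept`, `coefficients`,
#'   `table` (coefficient, SE, Wald chi-square, p), `converged`,
#'   `selection`, `standardization` (if carried by `z`).
#' @export
fit_logistic <- function(z, labels, columns = colnames(z),
                         selection = "FIXED") {
  labels <- .check_labels(labels)
  if (length(columns) > nrow(z) / 2) {
    warning("more than n/2 candidate columns; the 1:20 events-per-variable ",
            "guideline is badly violated")
  }
  df <- data.frame(.y = as.integer(labels == "P"),
                   z[, columns, drop = FALSE], check.names = FALSE)
  fml <- if (length(columns)) {
    stats::reformulate(sprintf("`%s`", columns), response = ".y")
  } else {
    .y ~ 1
  }
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df))
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  wald <- (est / se)^2
  p <- stats::pchisq(wald, df = 1, lower.tail = FALSE)
  tab <- data.frame(term = rownames(sm), coefficient = est, se = se,
                    wald_chisq = wald, p_value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  sep <- any(abs(est) > 15) || !fit$converged
  structure(list(
    intercept = unname(est["(Intercept)"]),
    coefficients = est[setdiff(names(est), "(Intercept)")],
    table = tab,
    converged = fit$converged,
    separation_suspected = sep,
    iterations = fit$iter,
    selection = selection,
    standardization = attr(z, "standardization")
  ), class = "dlr_model")
}

#' Construct a DLR model from fixed coefficients
#'
#' Builds a scoring-only model from published (or otherwise externally
#' estimated) coefficients on the z-score scale.
#'
#' @param intercept model intercept.
#' @param coefficients named numeric vector of per-column coefficients.
#' @param se optional named standard errors (same names plus
#'   `"(Intercept)"` allowed); enables Wald statistics.
#' @return `"dlr_model"` object with `selection = "FIXED"`.
#' @export
dlr_fixed_model <- function(intercept, coefficients, se = NULL) {
  tab <- NULL
  if (!is.null(se)) {
    est <- c("(Intercept)" = intercept, coefficients)
    se <- se[names(est)]
    wald <- (est / se)^2
    tab <- data.frame(term = names(est), coefficient = unname(est),
                      se = unname(se), wald_chisq = unname(wald),
                      p_value = stats::pchisq(unname(wald), 1,
                                              lower.tail = FALSE),
                      stringsAsFactors = FALSE)
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 table = tab, converged = TRUE,
                 separation_suspected = FALSE, iterations = 0L,
                 selection = "FIXED", standardization = NULL),
            class = "dlr_model")
}

#' The published seven-score DLR model
#'
#' The final manually selected logistic model combining seven standardized
#' docking scores (six catalytic-site scores and one entrance-site score)
#' with their reported standard errors, shipped as a fixed-coefficient
#' fixture so probability scoring is testable without running any docking
#' program.
#'
#' @return `"dlr_model"` object.
#' @export
dlr_published_model <- function() {
  coefs <- c(
    "surflex.1W0F.catalytic" = 5.5653,
    "fred.2V0M.catalytic"    = -2.2601,
    "surflex.2J0D.catalytic" = -1.7176,
    "glide.2V0M.catalytic"   = 1.5078,
    "fred.2V0M.full"         = 1.4618,
    "glide.1W0F.catalytic"   = -1.2597,
    "fred.1W0F.entrance"     = -1.0350
  )
  ses <- c(
    "(Intercept)"            = 0.3556,
    "surflex.1W0F.catalytic" = 1.5783,
    "fred.2V0M.catalytic"    = 0.8146,
    "surflex.2J0D.catalytic" = 0.6328,
    "glide.2V0M.catalytic"   = 0.5545,
    "fred.2V0M.full"         = 0.5385,
    "glide.1W0F.catalytic"   = 0.5007,
    "fred.1W0F.entrance"     = 0.6189
  )
  dlr_fixed_model(intercept = -1.8088, coefficients = coefs, se = ses)
}

#' Potent-class probability from a DLR model
#'
#' `logistic(intercept + sum(coef * z))` per row; classification is potent
#' when the probability reaches the cutoff.
#'
#' @param model `"dlr_model"`.
#' @param z standardized score matrix (or single named row).
#' @param cutoff classification cutoff (default 0.5).
#' @return data.frame with `probability` and `call` per row.
#' @export
score_probability <- function(model, z, cutoff = 0.5) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list(NULL,
                                                                names(z)))
  missing_cols <- setdiff(names(model$coefficients), colnames(z))
  if (length(missing_cols)) {
    stop("missing model column(s): ", paste(missing_cols, collapse = ", "))
  }
  eta <- model$intercept + if (length(model$coefficients)) {
    as.vector(z[, names(model$coefficients), drop = FALSE] %*%
                model$coefficients)
  } else {
    rep(0, nrow(z))
  }
  p <- stats::plogis(eta)
  data.frame(id = rownames(z) %||% seq_along(p), probability = p,
             call = ifelse(p >= cutoff, "P", "W"),
             stringsAsFactors = FALSE)
}

# refit helper used by the selection procedures
.wald_p <- function(model) {
  tab <- model$table
  stats::setNames(tab$p_value, tab$term)[names(model$coefficients)]
}

#' Stepwise variable selection by Wald significance
#'
#' Forward selection adds, while any candidate refits with Wald
#' `p <= alpha`, the candidate with the smallest p-value; backward
#' selection starts from the full model and drops the least significant
#' column while its `p > alpha`. Each step refits the model. Ties on
#' p-value break toward the larger absolute coefficient, then column-name
#' order.
#'
#' @param z standardized score matrix.
#' @param labels `"P"`/`"W"` per row.
#' @param direction `"forward"` or `"backward"`.
#' @param alpha entry/stay threshold on the Wald p-value.
#' @return `"dlr_model"` on the selected columns.
#' @export
select_stepwise <- function(z, labels, direction = c("forward", "backward"),
                            alpha = 0.05) {
  direction <- match.arg(direction)
  labels <- .check_labels(labels)
  cols <- colnames(z)
  if (direction == "forward") {
    selected <- character()
    repeat {
      candidates <- setdiff(cols, selected)
      if (!length(candidates)) break
      best <- NULL
      for (cand in candidates) {
        fit <- fit_logistic(z, labels, c(selected, cand),
                            selection = "FORWARD")
        p <- .wald_p(fit)[cand]
        coef_abs <- abs(fit$coefficients[cand])
        if (is.null(best) || p < best$p - 1e-12 ||
            (abs(p - best$p) <= 1e-12 && coef_abs > best$coef_abs)) {
          best <- list(col = cand, p = unname(p),
                       coef_abs = unname(coef_abs), fit = fit)
        }
      }
      if (best$p <= alpha) selected <- c(selected, best$col) else break
    }
    fit_logistic(z, labels, selected, selection = "FORWARD")
  } else {
    selected <- cols
    fit <- fit_logistic(z, labels, selected, selection = "BACKWARD")
    repeat {
      if (!length(selected)) break
      p <- .wald_p(fit)
      worst <- which.max(p)
      if (p[worst] > alpha) {
        selected <- setdiff(selected, names(p)[worst])
        fit <- fit_logistic(z, labels, selected, selection = "BACKWARD")
      } else break
    }
    fit
  }
}

#' Manual ("full model") variable selection
#'
#' Keeps the columns whose coefficients are Wald-significant at `alpha` in
#' the full model; if the training ROC AUC of that reduced model does not
#' exceed `auc_floor`, the fewest additional columns significant at
#' `relaxed_alpha` in the full model are added best-first until it does.
#' When the floor cannot be reached the best model found is returned with a
#' flag.
#'
#' @param z standardized score matrix.
#' @param labels `"P"`/`"W"` per row.
#' @param alpha full-model significance threshold.
#' @param relaxed_alpha threshold for supplementary columns.
#' @param auc_floor training ROC AUC that the model must exceed.
#' @return `"dlr_model"`; `$auc_floor_reached` records the outcome.
#' @export
select_manual <- function(z, labels, alpha = 0.05, relaxed_alpha = 0.10,
                          auc_floor = 0.8) {
  labels <- .check_labels(labels)
  full <- fit_logistic(z, labels, colnames(z), selection = "MANUAL")
  p_full <- .wald_p(full)
  keep <- names(p_full)[p_full <= alpha]
  spare <- names(sort(p_full[p_full > alpha & p_full < relaxed_alpha]))
  model <- fit_logistic(z, labels, keep, selection = "MANUAL")
  auc_of <- function(m) {
    if (!length(m$coefficients)) return(0.5)
    roc_curve(m, z, labels)$auc
  }
  auc <- auc_of(model)
  while (auc <= auc_floor && length(spare)) {
    keep <- c(keep, spare[1])
    spare <- spare[-1]
    model <- fit_logistic(z, labels, keep, selection = "MANUAL")
    auc <- auc_of(model)
  }
  if (!length(model$coefficients)) {
    # nothing significant even at the relaxed level: fall back to the
    # intercept plus the single best full-model column, flagged
    best <- names(p_full)[which.min(p_full)]
    model <- fit_logistic(z, labels, best, selection = "MANUAL")
    auc <- auc_of(model)
  }
  model$auc_floor_reached <- auc > auc_floor
  model$training_auc <- auc
  model
}

#' ROC curve over a probability-cutoff grid
#'
#' Sensitivity and specificity of the potent-class probability at each
#' cutoff on a grid, the trapezoidal AUC over (1-specificity, sensitivity),
#' and the four named operating points: `A` the highest cutoff maximizing
#' specificity with nonzero sensitivity, `B` the cutoff maximizing correct
#' classification (ties toward the larger cutoff), `C` the cutoff
#' minimizing |sensitivity - specificity|, `D` the lowest cutoff maximizing
#' sensitivity.
#'
#' @param model `"dlr_model"` (or NULL when `probabilities` are supplied).
#' @param z standardized score matrix.
#' @param labels `"P"`/`"W"` per row.
#' @param cutoff_step cutoff grid step.
#' @param probabilities optional pre-computed potent-class probabilities.
#' @return list of class `"roc_curve"`: `grid` (cutoff, sensitivity,
#'   specificity, accuracy), `auc`, `points` (named operating points).
#' @export
roc_curve <- function(model, z, labels, cutoff_step = 0.01,
                      probabilities = NULL) {
  labels <- .check_labels(labels)
  if (is.null(probabilities)) {
    probabilities <- score_probability(model, z)$probability
  }
  pos <- labels == "P"
  if (!any(pos) || all(pos)) stop("both classes needed for a ROC curve")
  cutoffs <- seq(0, 1, by = cutoff_step)
  sens <- vapply(cutoffs, function(ct) mean(probabilities[pos] >= ct), 0)
  spec <- vapply(cutoffs, function(ct) mean(probabilities[!pos] < ct), 0)
  acc <- vapply(cutoffs, function(ct) {
    mean((probabilities >= ct) == pos)
  }, 0)
  # exact trapezoidal AUC over the empirical staircase (all distinct
  # probability thresholds), so ties get half credit as in the rank statistic
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(probabilities[pos] >= t), 0)
  fp <- vapply(thr, function(t) sum(probabilities[!pos] >= t), 0)
  tpr <- c(0, tp / sum(pos))
  fprv <- c(0, fp / sum(!pos))
  auc <- sum(diff(fprv) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  max_spec <- max(spec[sens > 0])
  a_idx <- max(which(spec == max_spec & sens > 0))
  b_idx <- max(which(acc == max(acc)))
  c_idx <- which.min(abs(sens - spec))
  d_idx <- min(which(sens == max(sens)))
  pts <- data.frame(
    point = c("A", "B", "C", "D"),
    cutoff = cutoffs[c(a_idx, b_idx, c_idx, d_idx)],
    sensitivity = sens[c(a_idx, b_idx, c_idx, d_idx)],
    specificity = spec[c(a_idx, b_idx, c_idx, d_idx)],
    accuracy = acc[c(a_idx, b_idx, c_idx, d_idx)],
    stringsAsFactors = FALSE)
  structure(list(grid = data.frame(cutoff = cutoffs, sensitivity = sens,
                                   specificity = spec, accuracy = acc),
                 auc = auc, points = pts),
            class = "roc_curve")
}

#' Restrict inputs to the truncated (high-MW) applicability domain
#'
#' The truncated-domain DLR model (TD-DLR) trains and predicts only on
#' compounds above the MW band threshold; compounds at or below it are
#' outside the applicability domain.
#'
#' @param compounds data.frame with `id` and `mw`.
#' @param band_threshold Da.
#' @return list with `inside` (ids retained), `outside` (ids excluded,
#'   reported as outside the MW domain).
#' @export
truncate_domain <- function(compounds, band_threshold = 450) {
  inside <- compounds$id[compounds$mw > band_threshold]
  outside <- compounds$id[compounds$mw <= band_threshold]
  if (!length(inside)) stop("empty applicability domain: no compound above ",
                            band_threshold, " Da")
  list(inside = inside, outside = outside)
}
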