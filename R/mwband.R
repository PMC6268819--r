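# Molecular-weight-band enrichment statistics: Wilson score intervals,
# one-tailed two-proportion z-tests with a normal-approximation power
# calculation, normalized activity histograms over MW, curve fits locating
# the band threshold, and expected-count intervals for auditing classifier
# output against a binomial prior.

#' Wilson score interval for a binomial proportion
#'
#' The score interval without continuity correction. The critical value is
#' the exact normal quantile by default (1.959964... at 95%), not 1.96.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, > 0.
#' @param confidence confidence level.
#' @param z critical value; overrides `confidence` when supplied.
#' @return named numeric vector `c(lower, upper)`.
#' @export
wilson_interval <- function(k, n, confidence = 0.95, z = NULL) {
  stopifnot(n > 0, k >= 0, k <= n)
  if (is.null(z)) z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  c(lower = (centre - half) / denom, upper = (centre + half) / denom)
}

#' One-tailed two-proportion z-test
#'
#' Pooled-variance z statistic without continuity correction; the one-tailed
#' p-value is for the alternative that the first proportion is smaller than
#' the second. Wilson intervals for both proportions are attached.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @param confidence confidence level for the attached Wilson intervals.
#' @return list with `nu1`, `nu2`, `z`, `p_one_tailed`, `ci1`, `ci2`,
#'   and `degenerate` (TRUE when the pooled variance is zero).
#' @export
two_proportion_z <- function(k1, n1, k2, n2, confidence = 0.95) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  degenerate <- se == 0
  z <- if (degenerate) 0 else (p1 - p2) / se
  list(nu1 = p1, nu2 = p2, z = z,
       p_one_tailed = stats::pnorm(z),
       ci1 = wilson_interval(k1, n1, confidence),
       ci2 = wilson_interval(k2, n2, confidence),
       degenerate = degenerate)
}

#' Power of the two-proportion z-test (normal approximation)
#'
#' Power against the fixed alternative (p1, p2):
#' `z_power = (|p1 - p2| - z_alpha * SE0) / SE1`, where SE0 is the pooled
#' standard error under the null and SE1 the unpooled standard error under
#' the alternative; power = Phi(z_power), beta = 1 - power.
#'
#' @param p1,p2 the two proportions, in (0, 1).
#' @param n1,n2 group sizes.
#' @param alpha test size.
#' @param one_tailed logical; one- (default) or two-tailed critical value.
#' @return named numeric vector `c(power, beta)`.
#' @export
two_proportion_power <- function(p1, p2, n1, n2, alpha = 0.05,
                                 one_tailed = TRUE) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, n1 > 0, n2 > 0)
  z_alpha <- stats::qnorm(1 - if (one_tailed) alpha else alpha / 2)
  pbar <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n2))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  power <- stats::pnorm((abs(p1 - p2) - z_alpha * se0) / se1)
  c(power = power, beta = 1 - power)
}

#' Normalized activity histogram over molecular weight
#'
#' Bins active and inactive compounds by MW and computes, per bin, the
#' fraction of active compounds among all compounds in the bin. Bins are
#' anchored at 0 Da; empty bins have an undefined (NA) fraction and are
#' excluded from curve fitting.
#'
#' @param mws_active,mws_inactive molecular weights (Da) of active and
#'   inactive compounds.
#' @param bin_width bin width in Da (> 0).
#' @return data.frame with columns `mid` (bin midpoint, Da), `n_active`,
#'   `n_inactive`, `fraction_active`; class `"band_histogram"`.
#' @export
normalized_histogram <- function(mws_active, mws_inactive, bin_width = 50) {
  if (bin_width <= 0) stop("bin width must be positive")
  all_mw <- c(mws_active, mws_inactive)
  if (!length(all_mw)) stop("no compounds")
  idx_max <- floor(max(all_mw) / bin_width)
  breaks <- seq(0, (idx_max + 1) * bin_width, by = bin_width)
  cnt <- function(x) {
    if (!length(x)) return(integer(length(breaks) - 1))
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
             nbins = length(breaks) - 1)
  }
  n_act <- cnt(mws_active)
  n_ina <- cnt(mws_inactive)
  total <- n_act + n_ina
  frac <- ifelse(total > 0, n_act / total, NA_real_)
  out <- data.frame(mid = breaks[-length(breaks)] + bin_width / 2,
                    n_active = n_act, n_inactive = n_ina,
                    fraction_active = frac)
  class(out) <- c("band_histogram", "data.frame")
  out
}

# three-parameter log-logistic enrichment curve a / (1 + (x0/x)^b)
.logistic_mw <- function(x, a, x0, b) a / (1 + (x0 / x)^b)

.weibull4 <- function(x, a, b, c, x0) {
  # SigmaPlot-style 4-parameter Weibull peak:
  # a * ((c-1)/c)^((1-c)/c) * |z|^(c-1) * exp(-|z|^c + (c-1)/c),
  # z = (x - x0)/b + ((c-1)/c)^(1/c)
  k <- (c - 1) / c
  z <- (x - x0) / b + k^(1 / c)
  az <- abs(z)
  a * k^((1 - c) / c) * az^(c - 1) * exp(-az^c + k)
}

#' Fit enrichment curves and locate the MW band threshold
#'
#' Fits the normalized activity histogram with a log-logistic sigmoid
#' `a / (1 + (x0/x)^b)` on `mw <= logistic_range[2]`, a straight line on
#' `linear_range`, and (optionally) a four-parameter Weibull peak over the
#' full domain, then locates the band threshold as the intersection of the
#' sigmoid and the line nearest the upper end of the linear range.
#'
#' @param hist a `band_histogram` from [normalized_histogram()].
#' @param logistic_range MW range (Da) for the sigmoid fit.
#' @param linear_range MW range (Da) for the linear fit.
#' @param fit_weibull also fit the Weibull peak (full domain)?
#' @param weighted weight residuals by bin totals? Default FALSE, matching
#'   a plain least-squares fit of the normalized fractions.
#' @param start optional start values for the sigmoid, `c(a, x0, b)`.
#' @return list of class `"band_fit"`: `logistic` (a, x0, b), `line`
#'   (slope, intercept), `weibull` (a, b, c, x0) or NULL, per-fit `r2`,
#'   `intersection_mw`, and `flags`.
#' @export
fit_band_threshold <- function(hist, logistic_range = c(0, 950),
                               linear_range = c(150, 550),
                               fit_weibull = FALSE, weighted = FALSE,
                               start = NULL) {
  ok <- !is.na(hist$fraction_active)
  h <- hist[ok, ]
  w <- if (weighted) h$n_active + h$n_inactive else rep(1, nrow(h))

  r2_of <- function(y, fit, wt) {
    1 - sum(wt * (y - fit)^2) / sum(wt * (y - stats::weighted.mean(y, wt))^2)
  }

  in_log <- h$mid >= logistic_range[1] & h$mid <= logistic_range[2]
  if (sum(in_log) < 4) stop("too few populated bins for the sigmoid fit")
  dl <- data.frame(x = h$mid[in_log], y = h$fraction_active[in_log])
  if (is.null(start)) {
    start <- c(a = max(dl$y), x0 = stats::median(dl$x), b = 4)
  }
  lf <- tryCatch(
    minpack.lm::nlsLM(y ~ a / (1 + (x0 / x)^b), data = dl,
                      start = as.list(start), weights = w[in_log],
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(lf)) {
    # degenerate (e.g. flat) fractions leave the sigmoid unidentifiable;
    # report the failure and carry on with the linear fit
    lp <- c(a = NA_real_, x0 = NA_real_, b = NA_real_)
    r2_log <- NA_real_
  } else {
    lp <- stats::coef(lf)
    r2_log <- r2_of(dl$y, stats::predict(lf), w[in_log])
  }

  in_lin <- h$mid >= linear_range[1] & h$mid <= linear_range[2]
  if (sum(in_lin) < 3) stop("too few populated bins for the linear fit")
  ln <- stats::lm(fraction_active ~ mid, data = h[in_lin, ],
                  weights = w[in_lin])
  slope <- stats::coef(ln)[["mid"]]
  intercept <- stats::coef(ln)[["(Intercept)"]]
  r2_lin <- r2_of(h$fraction_active[in_lin], stats::fitted(ln), w[in_lin])

  wb <- NULL
  r2_wb <- NA_real_
  if (fit_weibull) {
    dw <- data.frame(x = h$mid, y = h$fraction_active)
    wf <- tryCatch(
      minpack.lm::nlsLM(
        y ~ .weibull4(x, a, b, c, x0), data = dw,
        start = list(a = max(dw$y), b = diff(range(dw$x)) / 2, c = 2,
                     x0 = dw$x[which.max(dw$y)]),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(wf)) {
      wb <- stats::coef(wf)
      r2_wb <- r2_of(dw$y, stats::predict(wf), w)
    }
  }

  flags <- character()
  if (abs(slope) < 1e-6) flags <- c(flags, "flat_linear_fit")
  if (is.null(lf)) flags <- c(flags, "logistic_fit_failed")
  inter <- if (is.null(lf)) NA_real_ else
    intersect_logistic_line(lp[["a"]], lp[["x0"]], lp[["b"]],
                            slope, intercept,
                            lower = linear_range[1],
                            upper = logistic_range[2])
  if (is.na(inter)) {
    flags <- c(flags, "no_intersection")
  } else if (inter < linear_range[1] || inter > linear_range[2]) {
    flags <- c(flags, "intersection_outside_linear_range")
  }
  structure(list(logistic = lp, line = c(slope = slope,
                                         intercept = intercept),
                 weibull = wb,
                 r2 = c(logistic = r2_log, line = r2_lin, weibull = r2_wb),
                 intersection_mw = inter, flags = flags),
            class = "band_fit")
}

#' Intersection of the sigmoid and linear enrichment fits
#'
#' Root of `a/(1 + (x0/x)^b) - (slope*x + intercept)` nearest `upper`,
#' located by bisection on a sign-change bracket scanned downward from
#' `upper`.
#'
#' @param a,x0,b sigmoid parameters.
#' @param slope,intercept line parameters.
#' @param lower,upper search interval, Da.
#' @return intersection MW in Da, or NA when no sign change exists.
#' @export
intersect_logistic_line <- function(a, x0, b, slope, intercept,
                                    lower = 150, upper = 950) {
  f <- function(x) .logistic_mw(x, a, x0, b) - (slope * x + intercept)
  grid <- seq(lower, upper, length.out = 1000)
  fg <- f(grid)
  sign_change <- which(fg[-length(fg)] * fg[-1] <= 0)
  if (!length(sign_change)) return(NA_real_)
  j <- sign_change[length(sign_change)]  # root nearest the upper end
  stats::uniroot(f, c(grid[j], grid[j + 1]), tol = 1e-8)$root
}

#' Expected-count interval from a binomial prior
#'
#' Scales the Wilson interval of a prior proportion k/n to a new set of m
#' compounds and rounds to whole counts. Used to check whether the number
#' of machine-classified potent inhibitors is statistically compatible with
#' the training-set prior.
#'
#' @param k,n prior successes and trials.
#' @param m size of the evaluation set.
#' @param confidence confidence level.
#' @return integer vector `c(low, high)`.
#' @export
expected_count_interval <- function(k, n, m, confidence = 0.95) {
  stopifnot(m > 0)
  ci <- wilson_interval(k, n, confidence)
  c(low = round(ci[["lower"]] * m), high = round(ci[["upper"]] * m))
}
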