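# In vitro -> in vivo extrapolation of CYP3A4 inhibition data under
# competitive Michaelis-Menten inhibition: apparent Km scaling, the
# Cheng-Prusoff relation, the AUC fold change R = 1 + [I]/IC50 at low
# substrate, interval propagation from the IC50 CI, and categorization of R
# against the regulatory potency thresholds.

#' Apparent Michaelis constant under competitive inhibition
#'
#' The substrate Michaelis constant is scaled by (1 + \[I\]/Ki) when a
#' competitive inhibitor at concentration \[I\] with inhibition constant Ki
#' is present.
#'
#' @param km substrate Michaelis constant, uM (> 0).
#' @param i inhibitor concentration, uM (>= 0).
#' @param ki inhibition constant, uM (> 0).
#' @return apparent Km, uM.
#' @export
apparent_km <- function(km, i, ki) {
  stopifnot(km > 0, ki > 0, i >= 0)
  km * (1 + i / ki)
}

#' Cheng-Prusoff inhibition constant from IC50
#'
#' For competitive inhibition, Ki = IC50 / (1 + \[S\]/Km). As the substrate
#' concentration goes to zero, Ki approaches IC50.
#'
#' @param ic50 half-inhibitory concentration, uM (> 0).
#' @param s substrate concentration, uM (>= 0).
#' @param km substrate Michaelis constant, uM (> 0).
#' @return Ki, uM.
#' @export
cheng_prusoff_ki <- function(ic50, s, km) {
  stopifnot(ic50 > 0, km > 0, s >= 0)
  ic50 / (1 + s / km)
}

#' Physiological inhibitor concentration for an extrapolation variant
#'
#' Converts exposure data to an inhibitor concentration in uM:
#' \describe{
#'   \item{R1}{`mrdd * bioavailability / mw * 1000`, i.e. the absorbed
#'     daily dose in umol per kg of body mass, read as umol/L (1 kg of body
#'     mass ~ 1 L of distribution volume).}
#'   \item{R2}{the same rule with a user-supplied alternative
#'     bioavailability (`ba_override`).}
#'   \item{R3}{the same rule with bioavailability forced to 1.}
#'   \item{R4}{the reported peak plasma concentration Cmax, unchanged.}
#' }
#'
#' @param mrdd maximum recommended daily dose, mg/kg/day.
#' @param bioavailability oral bioavailability as a fraction in (0, 1].
#' @param cmax peak plasma concentration, uM.
#' @param mw molecular weight, g/mol.
#' @param variant one of `"R1"`, `"R2"`, `"R3"`, `"R4"`.
#' @param ba_override bioavailability used for the `"R2"` variant.
#' @return inhibitor concentration, uM.
#' @export
intake_concentration <- function(mrdd = NA, bioavailability = NA, cmax = NA,
                                 mw = NA, variant = c("R1", "R2", "R3", "R4"),
                                 ba_override = NA) {
  variant <- match.arg(variant)
  if (variant == "R4") {
    if (is.na(cmax)) stop("variant R4 requires cmax")
    return(cmax)
  }
  ba <- switch(variant,
               R1 = bioavailability,
               R2 = ba_override,
               R3 = 1)
  if (is.na(mrdd) || is.na(mw)) stop("variant ", variant,
                                     " requires mrdd and mw")
  if (is.na(ba)) stop("variant ", variant, " requires a bioavailability")
  stopifnot(mrdd > 0, mw > 0, ba > 0, ba <= 1)
  mrdd * ba / mw * 1000
}

#' AUC fold change under competitive inhibition
#'
#' The ratio of inhibited to uninhibited pharmacokinetic AUC at low
#' substrate concentration, R = 1 + \[I\]/IC50 (using Ki ~ IC50).
#'
#' @param i inhibitor concentration, uM (>= 0).
#' @param ic50 half-inhibitory concentration, uM (> 0).
#' @return dimensionless fold change, >= 1.
#' @export
compute_r <- function(i, ic50) {
  stopifnot(all(ic50 > 0), all(i >= 0))
  1 + i / ic50
}

#' Propagate the IC50 confidence interval to R
#'
#' R decreases in IC50, so the interval is inverted: the lower bound of R
#' comes from the upper IC50 bound and vice versa. A zero lower IC50 bound
#' maps to an infinite upper bound on R.
#'
#' @param i inhibitor concentration, uM.
#' @param ic50_lo,ic50_hi IC50 interval bounds, uM, `0 <= lo <= hi`.
#' @return named numeric vector `c(lower, upper)`.
#' @export
propagate_r_ci <- function(i, ic50_lo, ic50_hi) {
  stopifnot(ic50_lo >= 0, i >= 0)
  if (ic50_lo > ic50_hi) stop("inverted IC50 interval")
  lower <- 1 + i / ic50_hi
  upper <- if (ic50_lo == 0) Inf else 1 + i / ic50_lo
  c(lower = lower, upper = upper)
}

#' Categorize an AUC fold change
#'
#' Regulatory-style potency call from R and its CI: `"P"` (potent) when
#' R > 2 with the whole CI above 2; `"W"` (weak) when R and its CI lie in
#' \[1.25, 2\]; otherwise `"ND"` (not determined: the CI crosses a
#' threshold, or R is below the clinical-relevance floor).
#'
#' @param r AUC fold change.
#' @param ci_lo,ci_hi confidence bounds on R.
#' @param thresholds c(weak floor, potent floor), default `c(1.25, 2)`.
#' @return `"P"`, `"W"` or `"ND"`.
#' @export
categorize_r <- function(r, ci_lo, ci_hi, thresholds = c(1.25, 2)) {
  lo <- thresholds[1]
  hi <- thresholds[2]
  if (r > hi && ci_lo > hi) return("P")
  if (r >= lo && r <= hi && ci_lo >= lo && ci_hi <= hi) return("W")
  "ND"
}

#' Round half-up to a number of decimals
#'
#' Display rounding used for printed R values (half-up, unlike base R's
#' banker's rounding).
#'
#' @param x numeric.
#' @param digits decimals.
#' @return numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Extrapolate a table of assay and exposure records
#'
#' Runs the full in-vitro-to-in-vivo extrapolation for each row of a table
#' shaped like [cyp3a4_table1()]: inhibitor concentration for the requested
#' variant, R, its CI by interval inversion, and the potency call. Rows
#' lacking a field required by the variant yield `NA` results rather than
#' an error.
#'
#' @param tbl data.frame with columns `id`, `ic50`, `ic50_lo`, `ic50_hi`,
#'   `mrdd`, `bioavailability`, `cmax`, `mw` (subset as required by the
#'   variant).
#' @param variant extrapolation variant, see [intake_concentration()].
#' @param thresholds potency thresholds passed to [categorize_r()].
#' @param ba_override per-row bioavailability for variant `"R2"`.
#' @return data.frame with columns `id`, `i`, `r`, `r_lo`, `r_hi`, `call`.
#' @export
ivive_table <- function(tbl, variant = "R1", thresholds = c(1.25, 2),
                        ba_override = NULL) {
  n <- nrow(tbl)
  out <- data.frame(id = tbl$id, i = NA_real_, r = NA_real_,
                    r_lo = NA_real_, r_hi = NA_real_,
                    call = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    i_k <- tryCatch(
      intake_concentration(
        mrdd = tbl$mrdd[k], bioavailability = tbl$bioavailability[k],
        cmax = tbl$cmax[k], mw = tbl$mw[k], variant = variant,
        ba_override = if (is.null(ba_override)) NA else ba_override[k]),
      error = function(e) NA_real_)
    if (is.na(i_k)) next
    ci <- propagate_r_ci(i_k, tbl$ic50_lo[k], tbl$ic50_hi[k])
    out$i[k] <- i_k
    out$r[k] <- compute_r(i_k, tbl$ic50[k])
    out$r_lo[k] <- ci[["lower"]]
    out$r_hi[k] <- ci[["upper"]]
    out$call[k] <- categorize_r(out$r[k], ci[["lower"]], ci[["upper"]],
                                thresholds)
  }
  out
}

#' Audit recomputed R values against the published table
#'
#' Recomputes R-1, R-3 and R-4 for the bundled extrapolation fixture and
#' compares them, after half-up rounding to two decimals, with the values
#' and calls printed in the source table. Rows whose printed IC50 is too
#' coarsely rounded to reproduce the printed R exactly are reported with
#' their relative deviation, and call disagreements under the stated
#' categorization rule are listed as divergences rather than forced.
#'
#' @param tbl fixture table, by default [cyp3a4_table1()].
#' @return list with elements `values` (long data.frame of recomputed vs
#'   printed R and calls per variant) and `divergent_calls`.
#' @export
table1_report <- function(tbl = cyp3a4_table1()) {
  variants <- c(R1 = "r1p", R3 = "r3p", R4 = "r4p")
  calls <- c(R1 = "c1p", R3 = "c3p", R4 = "c4p")
  rows <- list()
  for (v in names(variants)) {
    comp <- ivive_table(tbl, variant = v)
    printed <- tbl[[variants[[v]]]]
    printed_call <- tbl[[calls[[v]]]]
    keep <- !is.na(printed) & !is.na(comp$r)
    rel <- abs(comp$r - printed) / printed
    rows[[v]] <- data.frame(
      id = tbl$id, variant = v,
      r = comp$r, r_rounded = round_half_up(comp$r, 2),
      r_printed = printed, rel_dev = rel,
      call = comp$call, call_printed = printed_call,
      comparable = keep, stringsAsFactors = FALSE)
  }
  values <- do.call(rbind, rows)
  rownames(values) <- NULL
  cmp <- values[values$comparable, ]
  divergent <- cmp[!is.na(cmp$call_printed) & cmp$call != cmp$call_printed,
                   c("id", "variant", "r", "call", "call_printed")]
  rounding_flagged <- cmp[cmp$rel_dev > 0.005,
                          c("id", "variant", "r", "r_printed", "rel_dev")]
  list(values = values, divergent_calls = divergent,
       rounding_flagged = rounding_flagged)
}
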