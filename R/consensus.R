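# Consensus of the three classifiers' potent/weak votes: conjunction,
# disjunction and majority rules, percent-agreement confidence tiers, and
# an audit of predicted potent counts against binomial expectation
# intervals derived from the training prior.

#' Combine classifier votes into a consensus call
#'
#' Each compound carries one vote per method (`"P"`, `"W"`, or
#' `"OUTSIDE_DOMAIN"` when the method cannot vote, e.g. the
#' truncated-domain docking model below its MW threshold). Out-of-domain
#' votes are excluded from the agreement denominator.
#'
#' Strategies: `"MAJORITY"` calls potent when strictly more than half of
#' the in-domain votes are potent; `"CONJUNCTION"` when all are;
#' `"DISJUNCTION"` when any is.
#'
#' Confidence tiers (percent agreement on the winning potency call):
#' `"PROBABLE"` requires full agreement of all methods, `"PLAUSIBLE"`
#' agreement above 50% but below 100%, `"UNCERTAIN"` otherwise. By default
#' full agreement of a reduced (two-voter) panel is not promoted to
#' `"PROBABLE"`; set `allow_two_voter_probable = TRUE` to relax that.
#'
#' @param votes data.frame with column `id` and one column per method
#'   (e.g. `dlr`, `sdar`, `sar`) holding `"P"`, `"W"` or
#'   `"OUTSIDE_DOMAIN"`.
#' @param strategy consensus strategy.
#' @param allow_two_voter_probable treat 2/2 agreement as `"PROBABLE"`.
#' @return data.frame with `id`, per-method votes, `n_votes` (in-domain),
#'   `n_potent`, `category`, `confidence`.
#' @export
combine_votes <- function(votes,
                          strategy = c("MAJORITY", "CONJUNCTION",
                                       "DISJUNCTION"),
                          allow_two_voter_probable = FALSE) {
  strategy <- match.arg(strategy)
  methods <- setdiff(names(votes), "id")
  if (length(methods) < 2) stop("need at least two voting methods")
  v <- as.matrix(votes[methods])
  bad <- !v %in% c("P", "W", "OUTSIDE_DOMAIN")
  if (any(bad)) stop("invalid vote value: ", unique(v[bad])[1])
  in_domain <- v != "OUTSIDE_DOMAIN"
  n_votes <- rowSums(in_domain)
  n_potent <- rowSums(v == "P")
  category <- character(nrow(v))
  confidence <- character(nrow(v))
  for (k in seq_len(nrow(v))) {
    if (n_votes[k] < 2) {
      category[k] <- "W"
      confidence[k] <- "UNCERTAIN"
      next
    }
    frac_p <- n_potent[k] / n_votes[k]
    category[k] <- switch(strategy,
      MAJORITY = if (frac_p > 0.5) "P" else "W",
      CONJUNCTION = if (n_potent[k] == n_votes[k]) "P" else "W",
      DISJUNCTION = if (n_potent[k] > 0) "P" else "W")
    # tiers grade confidence in the POTENT classification: the agreement
    # fraction is the share of in-domain votes calling the compound potent
    full_panel <- n_votes[k] == length(methods) ||
      (allow_two_voter_probable && n_votes[k] >= 2)
    confidence[k] <- if (frac_p == 1 && full_panel) "PROBABLE"
      else if (frac_p > 0.5) "PLAUSIBLE"  # incl. unanimous reduced panel
      else "UNCERTAIN"
  }
  out <- data.frame(id = votes$id, votes[methods],
                    n_votes = n_votes, n_potent = n_potent,
                    category = category, confidence = confidence,
                    stringsAsFactors = FALSE)
  attr(out, "strategy") <- strategy
  out
}

#' Audit potent-call counts against the training prior
#'
#' Compares the number of potent consensus calls (overall and per MW band)
#' with the Wilson expected-count interval scaled from training-set
#' proportions, flagging counts outside their interval.
#'
#' @param calls data.frame from [combine_votes()].
#' @param bands optional factor/character of `"LOW"`/`"HIGH"` per call row;
#'   enables the per-band audit.
#' @param prior_k,prior_n overall training prior (potent / total).
#' @param prior_low,prior_high optional per-band priors as `c(k, n)`.
#' @param confidence confidence level.
#' @return list with one element per audited scope: observed count, set
#'   size, expected `c(low, high)`, and `within` flag.
#' @export
audit_counts <- function(calls, bands = NULL, prior_k = 33, prior_n = 121,
                         prior_low = c(15, 82), prior_high = c(18, 39),
                         confidence = 0.95) {
  if (!nrow(calls)) return(list())
  audit_one <- function(n_p, m, k, n) {
    expected <- expected_count_interval(k, n, m, confidence)
    list(observed = n_p, set_size = m,
         expected_low = unname(expected["low"]),
         expected_high = unname(expected["high"]),
         within = n_p >= expected["low"] && n_p <= expected["high"])
  }
  out <- list(overall = audit_one(sum(calls$category == "P"), nrow(calls),
                                  prior_k, prior_n))
  if (!is.null(bands)) {
    bands <- as.character(bands)
    for (b in c("LOW", "HIGH")) {
      sel <- bands == b
      if (!any(sel)) next
      prior <- if (b == "LOW") prior_low else prior_high
      out[[tolower(b)]] <- audit_one(sum(calls$category == "P" & sel),
                                     sum(sel), prior[1], prior[2])
    }
  }
  out
}
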