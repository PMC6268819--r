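---
title: "Consensus classification of potent and weak CYP3A4 inhibitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus classification of potent and weak CYP3A4 inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cypconsensus)
```

## The problem

CYP3A4 is the most abundant hepatic and enteric cytochrome P450 isozyme and
metabolizes a large share of marketed drugs. A chemical that inhibits
CYP3A4 can raise the exposure of co-administered drugs that share the
pathway — a drug--drug interaction whose clinical severity is graded by the
fold change *R* of the victim drug's area-under-the-curve (AUC). This
package implements a complete analysis chain for deciding whether a
chemical is a *potent* (strong or moderate, `"P"`) or *weak* (`"W"`)
CYP3A4 inhibitor:

1. **In vitro to in vivo extrapolation** of screening IC50 values to AUC
   fold changes, with interval propagation and categorization.
2. **Molecular-weight band statistics** locating and exploiting the
   ~450 Da threshold above which inhibitors are enriched in potency.
3. Three **machine classifiers** — a logistic regression on standardized
   docking scores (DLR), a spectral data--activity relationship model on
   binned ¹³C/¹⁵N NMR shifts (SDAR), and a five-tree decision forest on
   molecular descriptors (SAR).
4. A **majority-rules consensus** with confidence tiers, audited against
   binomial expectation intervals.
5. A repeated tenfold **cross-validation** harness shared by all three
   classifiers.

The bundled fixtures are the printed 121-compound clinical training set
(33 potent, 88 weak; 82 at or below 450 Da, 39 above) and the 17-drug
bioassay/exposure table used for the extrapolation analysis. Docking
scores, predicted NMR spectra and molecular descriptors for real compounds
are *not* computable here (they require commercial docking and prediction
software); every stage that consumes them is exercised on synthetic data
with the same statistical structure.

## Extrapolation model

Under competitive Michaelis--Menten inhibition the substrate's apparent
Michaelis constant scales as $K_{m,i} = K_m (1 + [I]/K_i)$. Because AUC is
inversely proportional to intrinsic clearance, the AUC fold change at low
substrate concentration is

$$R = 1 + \frac{[I]}{K_i}, \qquad
  K_i = \frac{\mathrm{IC}_{50}}{1 + [S]/K_m} \xrightarrow{[S]\to 0}
  \mathrm{IC}_{50},$$

implemented in `compute_r()`, `cheng_prusoff_ki()` and `apparent_km()`.
The inhibitor concentration $[I]$ comes in four variants
(`intake_concentration()`):

* **R1** — `MRDD × BA / MW × 1000`: the absorbed maximum recommended daily
  dose in µmol per kg of body mass, read as µmol/L (1 kg body mass ≈ 1 L
  of distribution volume). This convention is not stated in the source
  material; it was adopted because it reproduces the printed fold changes
  for diltiazem, glibenclamide, losartan and irbesartan exactly.
* **R2** — the same with a user-supplied alternative bioavailability.
* **R3** — the same with bioavailability forced to 100%.
* **R4** — the reported peak plasma concentration Cmax, unchanged.

The CI on *R* is obtained by inverting the IC50 interval
(`propagate_r_ci()`): the upper IC50 bound gives the lower *R* bound, and
a zero lower IC50 bound gives an infinite upper *R* bound — matching every
printed `(x, ∞)` cell. Categorization (`categorize_r()`) is `"P"` when
*R* > 2 with the whole CI above 2, `"W"` when *R* and its CI lie in
[1.25, 2], else `"ND"`.

`table1_report()` recomputes the whole table and *audits* it instead of
forcing agreement. Three kinds of divergence are surfaced:

* rows whose printed IC50 is too coarsely rounded for exact agreement
  (clotrimazole at ~1%, ketoconazole at ~3% — the ketoconazole rows are
  mutually consistent only at the unrounded IC50 ≈ 0.126 µM);
* isoniazid's R-1, which equals its R-3 despite an 80% bioavailability
  (reproducible only with BA = 1; the fixture keeps the reported 0.80);
* category cells that contradict the stated rule (e.g. methoxsalen C-1 is
  printed `W` with *R* = 1.07 below the weak floor). These are reported as
  divergences, never overwritten.

## Molecular-weight band statistics

`wilson_interval()` implements the score interval without continuity
correction, using the exact normal quantile (1.959964…) rather than 1.96
(a documented `z` argument allows overriding). `two_proportion_z()` is the
pooled-variance one-tailed z-test; `two_proportion_power()` uses the
normal approximation with the pooled SE under the null and the unpooled SE
under the alternative — the exact formula behind the published power
figure is unknown (it came from a commercial statistics package), so the
implementation targets the published 93% within ±2 points rather than
claiming exact agreement.

`normalized_histogram()` bins active and inactive compounds in 50-Da bins
anchored at 0 (the bin width was not stated; 50 Da reproduces the visual
granularity of the published figure and is configurable). Empty bins have
undefined fractions and are excluded from fitting. `fit_band_threshold()`
fits a log-logistic sigmoid $y = a/(1 + (x_0/x)^b)$ for MW ≤ 950 Da, a
line on 150–550 Da, and optionally a four-parameter Weibull peak on the
full domain; fits are unweighted by default (matching a plotting-tool
least-squares workflow on normalized fractions), with per-bin count
weighting available. The band threshold is the sigmoid–line intersection
nearest the upper end of the linear range, located by bisection; the
printed parameter sets intersect at ≈462 Da, inside the 430–470 Da window
the analysis treats as "about 450 Da". The boundary itself is assigned to
the low band (`HIGH` iff MW > 450), a choice the source never states.

`expected_count_interval()` scales a Wilson interval to a new set size and
rounds to whole counts: the training prior 33/121 on a 120-compound set
gives 24–43 expected potent calls, and the band priors 15/82 and 18/39
give 9–23 and 12–24 on their own bands.

## The three classifiers

**DLR.** Docking scores (28 columns: four programs × seven binding-site
runs on four crystal structures) are standardized per column
(`standardize_scores()`; sample SD by convention, with the population SD
available — the source does not say which was used), storing the training
means/SDs for apply-time reuse. `fit_logistic()` is a maximum-likelihood
binomial GLM with Wald statistics; selection is forward/backward stepwise
on Wald p-values (`select_stepwise()`, entry/stay α = 0.05, ties broken
toward the larger |coefficient| then column order) or *manual*
(`select_manual()`): keep the columns significant at α = 0.05 in the full
model, then add the fewest columns with p < 0.10 until the training ROC
AUC exceeds 0.8. If nothing is significant the model falls back to the
single best column, flagged. `roc_curve()` computes sensitivity and
specificity over a cutoff grid, the exact trapezoidal AUC over the
empirical staircase (equal to the Mann--Whitney rank statistic, with ties
at half weight), and four named operating points: A — highest cutoff
maximizing specificity with nonzero sensitivity, B — cutoff maximizing
accuracy (ties toward the larger cutoff), C — cutoff minimizing
|sens − spec|, D — lowest cutoff maximizing sensitivity. These operational
definitions are ours; the source labels the points but does not define
them. The final published seven-score model ships as a fixed-coefficient
fixture (`dlr_published_model()`) so probability scoring is testable
without any docking run; `truncate_domain()` restricts training and
application to the high-MW band (the TD-DLR variant), reporting excluded
compounds as outside the applicability domain.

**SDAR.** `bin_spectra()` counts predicted peaks into
`floor(shift/width)` bins (1 ppm carbon, 5 ppm nitrogen, namespaced `C`/
`N`). Bin values are integer peak counts rather than binary presence —
"hits" is ambiguous in the source and counts retain more information; a
`binary` switch restores presence coding. `filter_bins()` keeps bins hit
by ≥ 3 distinct compounds. `train_discriminant()` grows a forward
stepwise linear discriminant with F-to-enter 4.0: for two classes the
partial F of a candidate bin equals the F-to-enter of the class-indicator
regression, computed incrementally via QR; ties break toward the lower
bin index, collinear candidates are skipped, and bins with zero pooled
within-class variance are skipped with a warning (they would make the
discriminant singular). No F-to-remove is implemented (entry-only), a
possible divergence from the original software's behaviour. The final
discriminant is a linear discriminant with equal priors regardless of the
33:88 imbalance; `classify_sdar()` returns equal-prior posteriors, and
rows carrying none of the selected bins are flagged low-information.
Absolute bin numbering against a published reference scale is not
attempted — the ¹⁵N reference convention is unstated — so only relative
binning on the predicted shift scale is meaningful.

**SAR.** `shannon_entropy()` measures column information content in bits
after 10-equal-width-bin discretization of continuous columns;
`filter_descriptors()` drops columns below 0.5 bits (the threshold that
produced the published 327-of-777 retention is not given; 0.5 bits is the
package default and the synthetic descriptor table is constructed so that
exactly 327 columns clear it). `build_tree()` is a CART-style Gini tree:
candidate thresholds are midpoints of adjacent sorted unique values,
splits require ≥ `min_leaf` = 5 compounds per child, and growth stops at
purity or no positive impurity decrease; there is no pruning (none is
described). `train_forest()` grows exactly five trees sequentially,
excluding descriptors used by earlier trees, so the trees' descriptor
sets are pairwise disjoint — this is the single biggest reimplementation
assumption: the source calls the trees "distinct but comparable" without
detail, and descriptor exclusion is the mechanism of the cited decision
forest method. Prediction is the unweighted mean of leaf class fractions,
potent at ≥ 0.5. `usage_tally()` counts, per descriptor, the trees using
it across any collection of forests.

## Consensus and auditing

`combine_votes()` takes one `"P"`/`"W"`/`"OUTSIDE_DOMAIN"` vote per
method. Out-of-domain votes (e.g. TD-DLR below 450 Da) shrink the
denominator. Majority rules calls potent on > 50% of in-domain votes;
conjunction and disjunction are available and nest around it. Confidence
tiers grade agreement on the *potent* call: `PROBABLE` requires all
methods voting and unanimous `P`; `PLAUSIBLE` is > 50% but < 100% (with
three voters, exactly 2 of 3); anything at or below 50% is `UNCERTAIN`. A
unanimous two-voter panel is *not* promoted to `PROBABLE` by default —
full agreement is read as "all three methods able to vote and agreeing" —
with `allow_two_voter_probable = TRUE` to relax this; the source is
silent on the reduced-panel case. `audit_counts()` compares the potent
count, overall and per band, with the scaled Wilson expectation intervals
and flags counts outside them. The audit reports rather than resolves the
known tension that a majority consensus near 23 calls on 120 compounds
sits just below the overall 24–43 interval while both band counts are
comfortably inside their intervals.

## Cross-validation

`kfold_cv()` partitions compounds uniformly at random into k folds
(unstratified by default, matching a plain "randomly divided" protocol;
stratification is available), retrains from scratch on each 90% and
evaluates both the training fit and the held-out 10%, with no information
carried between folds or repeats. A fold that loses a class is redrawn
once, then errors. Reports are means and SDs of sensitivity, specificity,
correct-classification rate and the complementary type I/II errors. The
conventional call sites use 10 repeats for DLR and 100 for SDAR/SAR.

## What the synthetic generator emulates

`synth_config()` centralizes the study conditions:

* **Screening library** (`gen_library()`): base MW drawn from the density
  `g ∝ f_active/c` on a 1-Da grid, where `f_active` is the lognormal of
  active compounds (log₁₀ mean 2.578, SD 0.1313) and `c` the enrichment
  sigmoid `0.5047/[1 + (285.1/x)^6.266]`; each compound is then active
  with probability `c(mw)`. By construction the actives are exactly
  lognormal and the per-bin active fraction follows the sigmoid. The
  high-band active fraction therefore converges to the sigmoid plateau
  (≈0.50–0.51 at 10 000 compounds) — the observed value it emulates
  (0.5203) slightly exceeds the fitted asymptote (0.5047), so a generator
  faithful to the fitted curve necessarily sits at the low edge of that
  target.
* **Inhibitor sets** (`gen_compounds()`): MW lognormal with log₁₀ mean
  log₁₀(381) and SD 0.1885; potent with probability 15/82 below and 18/39
  above 450 Da.
* **Docking scores** (`gen_scores()`): each column is a mixture of a
  standardized-log-MW latent factor with loading drawn in 0.45–0.65
  (keeping realized MW correlations inside the reported 35–75% band) and
  independent noise; potent compounds are shifted by `score_effect_size`
  in the seven columns of the published model, echoing the concentration
  of informative scores at the catalytic site. The default effect size
  0.4 was calibrated so that the full 28-column logistic model on 121
  compounds remains estimable (larger effects cause complete separation)
  and manual selection lands, as in the published model, at roughly six
  significant scores with training ROC AUC > 0.8.
* **Spectra** (`gen_spectra()`): Poisson(MW/13) background carbon peaks —
  a crude carbon-count proxy, a synthetic convention rather than
  chemistry — plus a small number of nitrogen peaks, and three planted
  class-informative bins hit with probability 0.9 (potent) versus 0.05
  (weak).
* **Descriptors** (`gen_descriptors()`): 777 columns — 15 informative
  (class shift 2.0, mildly MW-correlated), 312 noise, and 450
  near-constant columns whose discretized entropy is below the filter
  threshold by construction, so the default filter retains exactly 327.
  The informative-column count and effect were calibrated to the
  generator's own contract that the end-to-end consensus recovers the
  generating potent proportions (weaker settings reproduce the
  conservative-count regime in which the consensus undercalls potency,
  the same tension the published counts show).

The three data views are generated conditionally independent given
(category, MW); no joint distribution linking them is claimed by the
source, and this simplification means passing tests demonstrate that the
pipeline recovers *planted* signal of realistic strength — not that real
docking scores, spectra or descriptors carry such signal. Real-data
features the generator does not emulate include inter-program correlation
structure among docking scores beyond the shared MW factor, chemically
meaningful shift positions, and descriptor redundancy.

## Numerical choices

* Display rounding is half-up to two decimals (`round_half_up()`);
  computation is at full precision.
* Critical values use exact normal quantiles.
* The sigmoid/Weibull fits use Levenberg--Marquardt least squares;
  a sigmoid that fails (e.g. flat fractions) is flagged, not fatal.
* Intersection finding brackets the root on a 1000-point grid and
  bisects, taking the root nearest the upper end of the linear range.
* Stepwise ties: logistic selection prefers the larger |coefficient| then
  column order; discriminant selection prefers the lower bin index; tree
  splits prefer the earlier descriptor column.
* Degenerate inputs: constant score columns are rejected at
  standardization; compounds with no peaks get zero rows with a warning;
  all-constant descriptor tables are an error; a forest that cannot fill
  five informative trees is returned short and flagged.

## Problem sizes used by the test-suite

The packaged tests run training sets of 121 synthetic compounds with
evaluation sets of 120 (mirroring the fixture sizes), libraries of
8 000–10 000 compounds for distributional checks, 100-seed repetitions for
the selection-frequency and consensus-count properties, and 10-seed
repetitions for accuracy-band properties. These sizes were chosen as the
smallest at which the binomial/selection properties have comfortable
margins over their asserted rates.

## Known limitations

* The published cross-validation means, the external-set call lists and
  the screening-library statistics depend on proprietary docking scores,
  predicted spectra and descriptor tables; they are covered structurally
  (shape, metric identities, planted-signal recovery), not numerically.
* The power calculation is a normal approximation targeted at ±2
  percentage points of the published figure.
* Entry-only stepwise discriminant selection may differ from software
  that also removes bins.
* The decision forest's "distinct but comparable" mechanism is
  interpreted as cross-tree descriptor exclusion.
* Equal-prior posteriors make the SDAR classifier deliberately
  insensitive to training imbalance; with heavily imbalanced bins this
  can overcall the minority class.
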