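---
title: "Measuring the overall burden of child malnutrition: methods behind eciaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the overall burden of child malnutrition: methods behind eciaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eciaf)
```

## The problem

Stunting (low height-for-age), wasting (low weight-for-height) and
underweight (low weight-for-age) are the conventional indicators of child
undernutrition, but they overlap: a child can fail on one, two or all three
at once, and none of them alone measures how many children have *any*
anthropometric failure. The composite index of anthropometric failure (CIAF)
partitions children aged under five into mutually exclusive groups by their
combination of failures; its extension (eCIAF) adds over-nutrition
(overweight, alone or combined with stunting), so its complement of
"no failure" is the overall prevalence of malnutrition. This package
implements that pipeline for household-survey data: z-scoring, plausibility
screening, classification, design-based prevalence estimation, between-survey
comparison of failure configurations, and distribution-level comparison of
z-scores -- together with a survey simulator that provides ground truth for
every stage.

## Z-scores and plausibility screening

Anthropometric z-scores are computed by the LMS method: a reference
distribution for each indicator, sex and key (age in completed months, or
height in cm for weight-for-height) is summarized by a Box-Cox power $L$,
median $M$ and coefficient of variation $S$, and

$$ z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
   z = \frac{\log(x/M)}{S} \quad (L = 0). $$

Reference rows are interpolated linearly in the key between bracketing rows,
the conventional practice for tabulated LMS references. Age is treated as
completed months, the resolution survey data actually carry. Weight-for-height
is keyed on the measured height, with no recumbent-versus-standing
correction (the surveys this mirrors record a single measured length/height).

The weight-based scores (WAZ, WHZ, BMIZ) receive the *restricted* tail
adjustment: beyond $\pm 3$ SD the LMS curve is replaced by a linear scale
anchored at the reference's $\pm 2$ and $\pm 3$ SD points,
$z = 3 + (x - SD_3)/(SD_3 - SD_2)$ above, mirrored below. It is continuous
at the knots, changes nothing within $\pm 3$ SD, and preserves ordering.
HAZ is never adjusted. The adjustment is on by default
(`compute_zscores(..., restricted = TRUE)`) because the official tabulations
of the surveys this package emulates use it; it never moves a score across
the $\pm 2$ thresholds, so classification is unaffected either way.

Implausibility flags use the standard fixed-exclusion ranges, as closed
intervals on the adjusted scores: HAZ in $[-6, 6]$, WAZ in $[-6, 5]$, WHZ
and BMIZ in $[-5, 5]$. They live in one exported constant
(`zscore_flag_limits`) so an alternative policy is a one-line change.
Exclusion is separate from flagging: `apply_exclusions()` drops children
younger than 6 months (adiposity changes rapidly before that age, the usual
reason such analyses start at 6 months) and children with any flag, counting
each child once. The age rule is applied first; published tallies report the
two counts without stating a precedence, so one had to be fixed, and
age-first matches the order in which the rules are described. Missing
measurements yield missing z-scores and the child is simply absent from any
statistic needing that component; nothing is imputed.

### The packaged reference table

The package ships a clearly labelled *synthetic* LMS reference
(`synthetic_lms_reference()`, `inst/extdata/lms_reference_synthetic.csv`):
smooth curves with the broad shape of early-childhood growth, mutually
consistent across the four indicators, covering ages 0--60 months and
heights 38--150 cm. The true WHO 2006 standard is distributed under its own
terms and is not bundled; any table in the same CSV layout
(`indicator,sex,key,L,M,S`) can be substituted via `read_lms_reference()`.
Every packaged analysis and test is either arithmetic on published tables
(independent of the reference) or a property of the pipeline (roundtrips,
partitions, coverage) that holds for any valid reference, so the synthetic
table is sufficient for validation -- but substantive analyses of real
children must use the real standard.

## Classification

Case definitions use strict inequalities exactly as conventionally printed:
stunted iff HAZ $< -2$, wasted iff WHZ $< -2$, underweight iff WAZ $< -2$,
overweight iff WHZ $> +2$. A score of exactly $-2.0$ is not a failure.
Overweight on WHZ (rather than WAZ or BMIZ) is the DHS/MICS convention and
the only definition under which "stunting and overweight" is a coherent,
commonly observed category; `overweight_on = "bmiz"` is available as a
switch.

The eCIAF groups are: A no failure, B wasting only, C wasting and
underweight, D stunting + wasting + underweight, E stunting and underweight,
F stunting only, Y underweight only, G stunting and overweight, H overweight
only. Two corners of the indicator space need decisions the taxonomy does
not make:

* stunted + wasted but *not* underweight has no letter in the original
  taxonomy. It is biologically improbable (weight deficits that produce both
  low WHZ and low HAZ almost always drag WAZ down) and published
  configuration tables show it with observed count 0, but it is logically
  possible; it gets the sentinel code X, counts as a failure, and is
  reported separately.
* underweight + overweight is possible because underweight is defined on
  WAZ and overweight on WHZ. It maps to H (G if also stunted) with a
  data-quality warning. Wasted + overweight is impossible by construction
  (both defined on WHZ) and is rejected.

The CIAF view (`classify_ciaf()`) ignores over-nutrition: G collapses to F
and H to A. Overall burden is `1 - P(A)` under either index, so eCIAF burden
is never below CIAF burden.

## Design-based prevalence

Surveys of this kind use a two-stage stratified design: regions are strata,
clusters (PSUs) are sampled within region, households within cluster, and
children carry sampling weights. `weighted_prevalence()` estimates
$\hat p = \sum w_i y_i / \sum w_i$ and obtains its variance by first-stage
Taylor linearization with the with-replacement PSU approximation: with
linearized scores $z_i = w_i (y_i - \hat p) / \sum w$ totalled into PSU
sums $z_{hj}$, the variance is
$\sum_h \frac{n_h}{n_h - 1} \sum_j (z_{hj} - \bar z_h)^2$.
This is the default variance method of standard survey software, which is
why it was chosen; replicate-weight methods are out of scope. The household
(secondary sampling unit) is retained in the design specification for
fidelity but does not enter a first-stage variance. Confidence intervals are
symmetric Wald on the proportion scale, clipped to $[0,1]$ -- matching the
symmetric intervals such reports print -- with a logit-scale option.
Weights enter raw; the ratio estimator is scale-invariant, which the tests
assert.

Single-PSU strata admit no variance contribution; the default is an error,
with `collapse` (merge with the adjacent stratum, repeated until no
singleton remains) and `certainty` (zero contribution) as explicit options.
Regional estimates are domain estimates; because regions *are* the strata,
restricting the score sums to the region is exact.

## Two-group configural frequency analysis

To compare the pattern of failures between two surveys, children are
cross-classified over the $2^3$ stunting x wasting x underweight
configurations (order YYY, YYN, ..., NNN). Counts are unweighted: the CFA is
a test on observed frequencies, and published configuration tables match
unweighted designs. The chance model is independence of configuration and
group, so expected counts are $E_{cg} = \text{row}_c \cdot N_g / N$, which
conserves both margins exactly -- these expected frequencies are the part of
a published CFA table that can be reproduced from the printed counts alone,
and the acceptance suite does exactly that.

Each configuration is tested with a two-sided Fisher exact test
(minimum-likelihood rule) on the 2x2 table [this configuration vs all
others] x [group 1, group 2]; a configuration observed in neither group has
p = 1 and is retained, not dropped. Multiplicity is handled by Bonferroni
over the 8 configurations (local level $\alpha/8 = 0.00625$ at the default
$\alpha = 0.05$): published discrimination patterns mark p-values of .014
and .015 as non-significant under a stated 0.05 level, which only an
adjusted local level explains, and $\alpha/8$ fits every printed row. Holm
and unadjusted thresholds are available. Published per-configuration
p-values themselves are *not* reproducible from printed counts by Fisher or
chi-square recomputation -- the original local test is not identifiable from
the publication -- so the package fixes Fisher + Bonferroni and validates
the p-value machinery against a brute-force hypergeometric enumeration
instead.

## Quantile profiles

Whole-distribution comparisons fit the $\tau$-quantile of each z-score per
survey over the grid $\tau = 0.05, 0.075, \ldots, 0.95$ (37 points),
stratified by sex and by age group (6--23 vs 24--59 completed months; a
23-month-old is "younger", a 24-month-old "older"). The estimator is the
weighted interpolated sample quantile: observations sorted, given midpoint
positions $(\mathrm{cum}\,w - w/2)/\sum w$, and interpolated linearly. With
equal weights this is exactly `quantile(type = 5)` and agrees with the
pinball-loss minimizer up to the flat region of the loss at a single
order-statistic gap (the tests cross-check against `quantreg`). Weights are
applied inside the quantile so the profiles are consistent with the weighted
prevalences elsewhere in the pipeline.

Uncertainty comes from a cluster bootstrap -- PSUs resampled with
replacement within group, 999 replicates by default, percentile bands,
seeded -- because it respects the survey design and is fully specifiable;
rank-score asymptotics would be an alternative but are tied to a particular
regression implementation. Two profiles differ "significantly" at a $\tau$
where their 95% bands are disjoint, the same polygon-overlap criterion used
for the prevalence tables. Estimates are nondecreasing in $\tau$ by
construction; bootstrap band edges are monotone-rearranged in case replicate
noise makes them cross.

## The survey simulator

`generate_survey()` emulates the structure of the real surveys: 10 region
strata, clusters drawn without replacement from a per-region pool,
a fixed number of households sampled per cluster from a household pool, all
children in sampled households measured, and weights equal to inverse
inclusion probabilities (self-weighting within region). Child anthropometry
is driven by a latent bivariate (HAZ, WHZ) normal -- region shift + cluster
effect with variance $\mathrm{icc}\cdot\sigma^2$ + child effect with
variance $(1-\mathrm{icc})\sigma^2$ and correlation
$\rho_{\mathrm{HAZ,WHZ}}$ -- and the latent scores are pushed through the
*inverse* LMS transform to produce raw height and weight. WAZ and BMIZ are
never simulated directly: they emerge from the generated measurements via
the reference, exactly as in real data, which keeps the four indices
internally consistent and makes latent HAZ/WHZ exactly recoverable by
re-scoring (the roundtrip tests assert recovery to 1e-6).

Because shifts are on the z-score scale, configured prevalences have
closed-form normal-tail targets: a region at mean shift $\mu$ with total SD
$\sigma$ has expected stunting $\Phi((-2-\mu)/\sigma)$. Defaults are chosen
once to be realistic for the setting the package addresses: mean HAZ shifts
from $-0.9$ (urban) to $-1.7$ (rural north), mean WHZ shifts $-0.2$ to
$-0.5$, total SD 1.1, ICC 0.1, HAZ-WHZ child correlation 0.2, 15 of 30
households per cluster, Poisson(0.8) eligible children per household, ages
uniform on 6--59 completed months, 51.2% male. The packaged three-survey
scenario (`generate_three_survey_scenario()`) contrasts a large MICS-style
survey (SD$_{WHZ}$ 1.10), a mid-sized DHS-style survey (1.35) and a smaller
panel-style survey with much heavier two-sided tails (2.20, with slightly
*higher* medians): the panel-style survey then shows more wasting and more
overweight despite similar medians -- the pattern that motivates comparing
full quantile profiles rather than medians.

What the simulator does *not* emulate: nonresponse, digit preference and
other measurement error, seasonality, age heaping, and oedema. Passing tests
therefore demonstrate that the estimators are correct under a clean
two-stage cluster design with smooth latent distributions; they do not
certify robustness to the messiness of field data.

## Target tracking

`relative_change()` and `assess_targets()` implement the global
nutrition-target rules: stunting, at least a 40% relative reduction from
baseline; wasting, follow-up prevalence below 5%; overweight, below 6%.
Rounding is half-up, applied only at render time ("Decrease of 37%");
computation keeps full precision. Whether a 39.9% reduction "meets" a 40%
target depends on whether the rule is applied to the raw or the rounded
change -- published assessments have treated a change printing as 40% as
met -- so both verdicts are reported (`met` on the raw change,
`met_rounded` on the printed integer) rather than silently choosing one.

## Numerical and testing choices

* Interpolation in the reference key is linear; keys outside coverage raise
  an error naming the indicator rather than extrapolating.
* Boundary conventions: flag limits are closed intervals (a score exactly at
  $-6$ is plausible); case thresholds are strict (exactly $-2$ is not a
  failure); confidence intervals sharing an endpoint overlap.
* Degenerate inputs: empty domains, all-zero weights, empty CFA groups and
  empty profiles error early with the offending name; zero-probability
  outcomes give degenerate zero-width intervals rather than NaN.
* The test suite validates the estimators at deliberately moderate sizes:
  CI coverage of the superpopulation eCIAF burden over 200 replicate
  surveys of roughly 2,400 children each; full Fisher-vs-enumeration sweeps
  over all 2x2 tables with grand totals up to 16 (plus seeded tables up to
  60, and up to 36 exhaustively in the acceptance script); quantile-oracle
  equality at n up to 1,000. These sizes make the whole suite run in about
  a minute while leaving Monte-Carlo margins wide enough that the
  assertions are not knife-edge.

## Known limitations

* The bundled growth reference is synthetic; results on real children
  require the real WHO tables (same file format).
* Variance estimation is first-stage with-replacement linearization only;
  no finite-population correction, replicate weights, calibration or
  design-effect reporting.
* The CFA is the two-group variant only, over the three undernutrition
  axes; one-sample types/antitypes and higher-order configurations
  (including overweight) are out of scope.
* Quantile profiles use a group-indicator design (one quantile per group),
  not covariate-rich quantile regression.
* Severity grades (below $-3$ SD), MUAC-based wasting and oedema are not
  implemented.
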