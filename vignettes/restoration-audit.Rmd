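---
title: "Auditing coral restoration: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing coral restoration: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`reefrestore` packages a four-stage audit of global coral restoration —
where restoration happens, whether its short-term outcome is predictable,
what thermal stress restored sites face, and what scaling restoration up
would cost. This vignette explains the models behind each stage, the
parameters that matter, and the design decisions taken where the problem
was genuinely open. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The site-selection model

Whether a 0.5° reef locality has been restored is modelled as a binary
response of seven predictors: gravity (a population/travel-time
accessibility index, dimensionless), remoteness (log travel minutes to
the nearest large settlement), mean and trend of cumulative human impact,
coral species richness, and the mean and ordinary-least-squares trend of
severe bleaching-alert counts (level I or worse) in the five years up to
a reference year. Restored localities use conditions preceding
restoration; non-restored localities have no restoration date, so their
window is anchored at the median restoration year of the record set (a
documented, configurable convention — the choice of anchor is not
determined by the problem itself).

The learner is stagewise gradient boosting of depth-limited regression
trees: shrinkage `learning_rate` (default 0.001), per-tree row
subsampling `bag_fraction` (0.5), interaction depth `tree_complexity`
(3), and an ensemble size chosen by k-fold cross-validated holdout
deviance over candidate sizes 50–10,000 in steps of 10 (ties go to the
smaller count — parsimony, and deterministic). Bernoulli deviance is
−2·Σ w·[y·log p + (1−y)·log(1−p)] with p clipped to [1e−12, 1−1e−12] for
numerical safety. Tree fitting is delegated to xgboost, which honours
the contracts the analysis relies on — bag fraction, depth limit,
observation weights in the loss, staged prediction at any intermediate
tree count, bit-reproducibility under a fixed seed — all of which the
test suite verifies. The internal fold count (default 5; 3 in the fast
test settings) is a package default, not a claim about any particular
historical analysis.

Because restored sites are rare (~6.5% prevalence), training rows are
weighted inversely to class prevalence, which pushes the fitted
probabilities toward balanced sensitivity and specificity. Skill is
evaluated on a held-out split as the true skill statistic
(TSS = sensitivity + specificity − 1) maximised over assignment
thresholds 0.001, 0.002, …, 0.900 (smallest threshold on ties; a case is
positive when its probability is ≥ the threshold).

Two evaluation caveats are built into the design:

* **Spatial independence.** Reef localities near one another share
  restoration status. Each replicate therefore draws a spatially thinned
  subset: localities are visited in a seeded random order and kept only
  if > 150 km (haversine, Earth radius 6,371 km) from every kept
  locality; the retained labels must then pass a join-count randomness
  screen at α = 0.05, and failing subsets are redrawn.
* **Threshold-scan optimism.** Maximising TSS over 900 thresholds on the
  test split is optimistically biased when the test split is small (on
  pure noise the bias is ≈ +0.14 with 20 test presences, shrinking
  roughly as the split grows). Calibration checks in the tests and the
  acceptance script therefore use null conditions with large test splits,
  where the chance-level model scores ≈ 0.05–0.09; the bias is a property
  of the published evaluation design that users should keep in mind when
  reading absolute TSS values.

## Spatial statistics

The join-count screen uses a distance-band neighbour graph. "Neighbour"
is not defined by the thinning rule itself, so the band defaults to twice
the thinning threshold (300 km for the 150 km sampler): every retained
point can still have neighbours at the thinned scale. Counts of
same-class and cross-class neighbour joins are compared with their
randomisation moments under non-free sampling (class counts fixed,
positions permuted; the classical falling-factorial formulas), giving
two-sided normal p-values; a permutation p (and its mid-p variant, which
half-weights permutations exactly as deviant as the observation) is
available for cross-checks. With two classes the screen is keyed to the
total same-class join count, which equals the constant total minus the
cross-class count — a single, correctly calibrated test (the minimum over
per-class p-values would double the type-I rate). Join counts are
integers; on small graphs their discreteness makes the plain permutation
p exceed the continuous normal p by up to ~0.2, which is why the test
suite compares the analytic p against the permutation **mid-p**.

For the continuous success score the screen is Moran's I under
inverse-distance weights, with the randomisation-null expectation
−1/(n−1) and variance (kurtosis-corrected closed form), plus an optional
permutation p. Degenerate inputs are defined, not fatal: single-class
labels or edgeless graphs yield a flagged "degenerate" join-count result
(treated as uninformative and accepted by the subset sampler), while
constant values are an error for Moran's I.

## The standardized success score

Observed percent survival S_o over t monitoring months is standardized
against an expected-survival curve S_e(t) = a + (100 − a)·exp(−k·t):
coral mortality is highest for small, recently outplanted colonies and
declines as they grow, so survival decays toward an asymptote a rather
than to zero. The asymptote matters numerically: monitoring durations
span 0.8–144 months, and a pure exponential would drive S_e → 0 at the
long end and explode the score. The score

S_r = log_e(1 + 100 − ((S_e − S_o)/S_e)·100) = log_e(1 + 100·S_o/S_e)

is 0 iff S_o = 0, log_e(101) ≈ 4.6151 at S_o = S_e, strictly increasing
in S_o and decreasing in S_e. Observed survival may exceed 100%
(fragmentation, colony fusion) up to a configurable cap of 120%, keeping
S_r finite.

The curve is fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm`), pinned at 100% at t = 0 by construction; an all-100%
input is flagged and returns the flat k → 0 limit. **The bundled
calibration points are a synthetic stand-in** shaped like published
outplant-survival trajectories (asymptote ≈ 20%, rate ≈ 0.05 month⁻¹,
i.e. half the excess mortality gone by ~14 months); real analyses must
supply their own digitized calibration.

The success analysis regresses S_r on technique flags (coral gardening,
direct transplantation, artificial reefs, larval enhancement), the
number of genera used, the locality covariates, and severe-alert counts
in the five years before and after restoration. The restoration year
belongs to the *pre* window and the post window is the five years
strictly after — an unambiguous partition chosen once and reused by the
exposure stage. Records are deduplicated at 1 km (coincident sites
collapse to one), screened with Moran's I (keep subsets with p > 0.05),
and evaluated by test-split Pearson R². When the replicate-mean R² falls
below 0.05 the model has no predictive skill, and relative influence and
partial dependence are withheld with a message: importance rankings from
a skill-less model invite over-interpretation. The boundary is sharp
(exactly 0.05 is *not* suppressed).

## Thermal exposure and costs

Alert histories are yearly counts of level-I and level-II events
(1986–2021). An "event-year" is a year with ≥ 1 event of the given
severity or worse; exposure fractions use event-years, while mean-event
statistics retain within-year multiplicity — both are provided. The
restored group for a target year contains localities restored in the
five preceding years (rolling membership), everything else is control;
fractions are aggregated in 5-year bins labelled by their upper boundary.
Projected annual-maximum DHW (2015–2100) is compared against an
**inclusive** ≥ 20 °C-weeks threshold — tested at exactly 20.0 — to count
exceedance years and the first exceedance year per locality.

Costs are linear through the origin: total = per-hectare bound × area,
for lower/median/upper bounds per technique, with km² → ha conversion
(× 100). The bundled cost table is a labelled synthetic stand-in anchored
to published headline figures (global range US$6,000–143M per hectare,
with US$261M recorded for the most intensive substrate-addition
approaches; a coral-gardening median of US$28,205/ha, consistent with
~US$3.3 billion for 117,000 ha); interior per-technique values are
plausible placeholders and should be replaced with a digitized published
table for real analyses.

## The synthetic generator

The generator emulates the statistical structure the audit assumes, not
any real reef. Defaults mirror the scale of the real dataset: ~3,900
localities, ~6.5% restored, monitoring 0.8–144 months, a restoration
record set reduced by ~20% unusable reports. Covariate marginals
(log-normal gravity and impact, truncated-normal remoteness,
negative-binomial richness) are pragmatic choices — the real marginals
are not published — and are flagged as such. Restored status follows a
logistic model on standardized covariates plus a Gaussian random field
with exponential covariance over great-circle distances (default range
300 km, s.d. 0.8 on the logit scale), the simplest mechanism giving
tunable clustering for the join-count machinery; the intercept is
calibrated by root-finding so the mean selection probability hits the
target prevalence. Survival is the decay-curve expectation times
multiplicative log-normal noise (s.d. 0.35 on the log scale), optionally
shifted by planted technique effects, capped at 120%. DHW series are
baseline + trend × (year − 2015) + noise, truncated at zero; the default
trend 0.30 ± 0.10 °C-weeks yr⁻¹ over a baseline of 2 puts first
exceedances of 20 °C-weeks in the mid-2060s to 2070s, the mid-century
risk horizon the audit is concerned with.

What the generator does **not** emulate — coastline geometry, covariate
spatial trends, technique–environment confounding, multi-model climate
ensembles, reporting biases of a volunteer-compiled database — bounds
what passing tests show: they demonstrate that the pipeline recovers
known structure and stays calibrated under its own assumptions, not that
the real data satisfy those assumptions.

## Reproducibility and problem sizes

Every stochastic function takes a seed; a single pipeline seed fans out
to stage seeds through a deterministic integer map, and identical
configurations reproduce outputs bit-for-bit (tested). The RNG state of
the caller is never clobbered.

The package defaults mirror the full-scale analysis (1,000 replicates,
tree search to 10,000 at learning rate 0.001). The test suite and the
acceptance script run the same code at reduced sizes chosen as the
package's own fast settings: grids of 500–1,600 localities, 2–10
replicates, tree search 50–300 at learning rate 0.05 with 3 folds, 500
simulations for type-I-error checks, 4,000–10,000 permutations for
oracle comparisons. These sizes keep every qualitative property being
tested (planted-truth recovery, chance-level nulls, nominal calibration)
while completing in minutes.

## Known limitations

* TSS measured with a test-split-optimised threshold is upward-biased on
  small splits (quantified above); comparisons between models evaluated
  at the same split sizes remain meaningful.
* The join-count normal approximation degrades on very small or sparse
  graphs; use the permutation option there.
* Partial dependence uses a quantile-spaced grid by default in the
  site-selection report because gravity and impact are strongly
  right-skewed; an even grid is available and spans the observed range.
* The success analysis assumes a single global decay curve; species- or
  size-structured survival is out of scope.
* Costs are linear extrapolations with no discounting, labour modelling
  or success-conditioning.
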