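---
title: "Flight morphometrics and the found-or-fly tradeoff: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flight morphometrics and the found-or-fly tradeoff: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foundorfly)
```

## The scientific problem

Queen-polymorphic ants such as the tropical fire ant (*Solenopsis geminata*)
and the red imported fire ant (*S. invicta*) produce two kinds of queens from
the same genome. Claustral queens carry heavy abdomens packed with fat and
protein and found colonies alone, feeding the first worker generation entirely
from those reserves. Parasitic queens carry minimal reserves and instead enter
orphaned conspecific colonies. Because a queen flies to disperse before she
founds, her abdominal nutrient load sets up a tradeoff: more reserves mean
more first-generation workers but worse flight. This package implements the
quantitative machinery for studying that tradeoff: flight-morphology indices,
caste-comparison statistics, maximum-performance (quantile) regression of
tethered-flight endurance, and a simple model converting abdomen mass into
dispersal quantities.

## Flight-morphology indices

For each queen, from dry masses (mg), linear measurements (mm) and wing areas
(mm²):

* **Flight muscle ratio** `FMR = thorax mass / body mass`. Thorax dry mass is
  accepted as the flight-muscle surrogate without a correction factor;
  dissection evidence in fire ant queens shows the thorax filled with
  well-developed flight muscle.
* **Wing loading** `= body mass / total area of all four wings` (mg/mm²).
* **Abdomen volume** by the prolate-spheroid formula, reading the measured
  maximum abdomen length `L` and height `H` as the *full diameters* of the
  major and minor axes:
  `V = (π/6)·L·H²`.
  This factor deserves emphasis: the semi-axis reading `V = (4π/3)·L·H²`
  would overstate volume eight-fold and is inconsistent with the observed
  drag magnitudes (a 5.6 mg abdomen would imply an implausible ~0.07 mg/mm³
  dry density). Caliper- and micrometer-style measurements are full spans,
  not semi-axes.
* **Abdomen drag reference area** `= V^(2/3)` (mm²), a two-dimensional
  size-and-shape proxy proportional to drag.
* **Aspect ratio** `= 4·(forewing length)²/total wing area` and
  **wing mass density** `= wing mass / wing area` (mg/mm²), two wing
  properties expected to be independent of abdomen load.

Indices are always computed per queen; group values are summaries of
per-queen indices, never index formulas applied to group means (the two
differ under Jensen-type nonlinearity, e.g. for drag).

## Caste comparisons

`compare_castes()` follows the analysis conventions of the field:
a Shapiro–Wilk gate per group at α = 0.05 routes each trait either to a
two-sample t-test (normal; summarized as mean ± SD) or to a two-group
Kruskal–Wallis test with tie correction (non-normal; medians and IQR).
Design choices worth recording:

* **Welch vs pooled t.** The t-test defaults to Welch's unequal-variance
  form, with `t_variant = "student"` available. With only "t-tests" stated
  in the source conventions and no raw data to adjudicate, Welch is the
  safer default (it is exact under equal variances asymptotically and robust
  otherwise).
* **Constant groups** cannot be Shapiro–Wilk tested; they route to the
  rank-based branch. This arises only in degenerate (zero-variance)
  synthetic cohorts used for arithmetic checks.
* **Contrast conventions.** Percent differences are relative to the
  parasitic group, `100·(mean_cl − mean_pa)/mean_pa`, and fold differences
  are `mean_cl/mean_pa`, matching the way caste contrasts are reported
  ("32% lower", "2.3 times heavier").
* **Pseudoreplication.** Sister queens from one colony are not independent;
  `colony_averages()` repeats any analysis with each colony collapsed to a
  single point. Mixed-effects modelling is deliberately out of scope — the
  averaging-plus-factor-check design is the one being reproduced.
* **Holm–Bonferroni families.** `holm_correction()` applies the step-down
  correction (sort ascending, multiply the i-th smallest of m by
  m − i + 1, running maximum, cap at 1). Families are explicit, never
  inferred: per-index across the four queen types (m = 4) for the
  morphology-on-abdomen-mass regressions, and per-method across the three
  predictors (m = 3) for the endurance table.

## Endurance analysis and the quantile solver

Total flight time is the sum of a queen's tethered bout durations (up to six
take-off trials). Minimum durations are uninformative — any queen can cut a
flight short for non-biomechanical reasons — so the analysis targets the
*upper envelope*: a linear quantile regression at τ = 0.75 of total flight
time on each of abdomen mass, log FMR (natural log, to meet normality in the
companion tests) and wing loading, one predictor at a time.

The solver minimizes the check loss
`Σ ρ_τ(y_i − b₀ − b₁x_i)`, `ρ_τ(u) = u(τ − 1[u<0])`,
by exhaustive search over all lines through two data points with distinct x.
This is exact: the problem is a linear program whose optimal basic solutions
interpolate at least two such points. At the cohort sizes involved (tens to
a few hundred queens) the O(n³) enumeration costs milliseconds to well under
a second, and exactness buys clean invariants — the suite verifies equality
with an independently coded brute-force oracle, the subgradient bracket
(≤ τn residuals strictly below, ≤ (1−τ)n strictly above), dominance over the
OLS line under ρ_τ, and the τ = 0.5 / least-absolute-deviations equivalence.
Objective ties are broken deterministically (smallest |slope|, then smallest
intercept). Residual sign counts use a tolerance of `1e-8·max(1, |y|)` so
that interpolated points are classified as on-line despite round-off.

**Slope inference** uses a seeded xy-pairs bootstrap (default 9999
resamples; two-sided p with a +1 continuity correction) rather than
rank-inversion: it is self-contained and exactly reproducible under the
package's master-seed scheme (child seeds are derived deterministically from
a label and the master seed). Published p-values for the corresponding fits
came from a different method and are therefore matched only approximately.

Companion analyses: OLS and Spearman rank correlations of the same pairs
(central-tendency comparators, expected non-significant when only the
envelope varies), colony-homogeneity checks (Kruskal–Wallis per variable,
one-way ANOVA for variables flagged normal after transform — by default the
log FMR), and an outlier rule for anomalously light abdomens (just-eclosed
queens). The outlier rule only *flags* by default — below an absolute
threshold or beyond k = 3 SD from the cohort mean — and removes records only
with explicit `apply = TRUE`, always logging the reason; the exclusion
criterion in the original experiment was not documented, so nothing is
hard-coded.

## The tradeoff model

Dispersal side, from dry abdomen mass `a` (mg):

* maximum flight duration `D(a) = max(6742.350 − 1096.915·a, 160)` s — the
  published upper-quartile envelope for claustral *S. invicta*, floored at
  160 s because the heaviest queens still fly short distances (under 400 m)
  rather than not at all. The floor crossing sits at ≈ 6.0 mg; predictions
  above it are speculative and flagged as such in the curve.
* flight speed: 1.5 m/s (tethered maximum, `constant_max`), or caste
  averages of 0.9 (parasitic) / 0.6 (claustral) m/s, or a user-supplied
  function of live body mass (`mass_formula`; the literature source formula
  is not reproduced here, so this mode requires the caller to supply one).
* range `= speed · duration` (m); potential colonization area
  `= π·(range in km)²` (km²), assuming purely horizontal flight.

Reproduction side: first-generation workers are reared entirely from
abdominal reserves. The default worker model is **explicitly a calibration,
not a derivation**: a straight line on live abdomen mass
(live = 2 × dry, the standard live:dry ratio) through the anchor pairs
(2.7 mg dry → 10 workers) and (5.3 mg dry → 31 workers), clamped at zero
below its root (≈ 1.46 mg dry). The underlying planting-experiment formula
is not printed in the source material; any monotone `worker_fn(live_mass)`
can be plugged in.

**Rounding conventions.** Headline values round durations to the nearest
100 s and areas to the nearest km² *before* forming ratios — the printed
pairs 900/3,800 s and 6/102 km² → 17-fold are only mutually consistent
under that convention. Unrounded values are always emitted alongside. One
known discrepancy is reported, not forced: under the caste-average speeds
the rounded area pair computes to 37 vs 1 km² (exact 36.4 vs 0.98 via
unrounded durations, 36.75 vs 0.92 via rounded ones), whereas the source
text prints "36 versus 1 km²" and calls it 36-fold; the package reports
both the rounded pair and the exact ratio (≈ 37–40) and leaves the
reconciliation open.

## The synthetic-queen generator

`table2_specs()` encodes the four reference cohorts (claustral/parasitic ×
two species) with their published sample sizes (13, 38, 58, 33 queens from
3–6 colonies) and trait means/SDs. Construction choices:

* **Body-frame + abdomen decomposition.** Thorax mass is mean FMR × mean
  dry mass, wing mass is mean wing-mass density × mean wing area, and the
  residual (head/legs/petiole) mass closes the budget so that body mass is
  the *exact* sum of components. Component SDs are not published; they scale
  the cohort's dry-mass SD proportionally to each component's mean share.
  Because indices are computed from the generated parts, index-vs-abdomen
  regressions emerge mechanistically (e.g. the wing-loading slope
  ≈ 1/mean wing area ≈ 0.037 per mg, matching the published 0.0367 for
  claustral *S. invicta*).
* **Truncated normals at zero** for all positive traits (only means/SDs are
  available), via rejection sampling.
* **Colony structure.** Additive normal colony shifts shared within colony,
  with between-colony SD a fraction (default 0.2) of trait SD and the
  within-colony SD scaled to preserve the total; the flight experiments
  found no colony effects, so the default is small.
* **Abdomen dimensions.** Volume = mass / density with a per-caste density
  calibrated so each cohort's mean drag area equals its published mean
  (0.53, 0.35, 0.51, 0.41 mg/mm³ for GC, GP, IC, IP). A single shared
  density cannot do this — drag would scale as mass^(2/3), inflating the
  caste drag contrast from the observed 32–33% to 56–74% — and the lower
  parasitic densities are biologically sensible (same cuticle envelope,
  little stored fat). A per-queen shape ratio L/H (mean 1.6, SD 0.08,
  truncated at 1 — typical gaster proportions; not published, chosen once)
  then yields `H = (6V/(πr))^(1/3)`, `L = rH`.
* **Flight realization.** A queen's latent maximum is
  `D_max(a) = max(intercept + slope·a, floor)` with the published envelope
  defaults; her realized total is `D_max·B`. `B` is a two-component Beta
  mixture: with probability `p_full = 0.35` she flies near her maximum
  (`B ~ Beta(20·opportunity_scale, 1)`), otherwise the flight is cut short
  (`B ~ Beta(1, opportunity_scale)`, default scale 1.5). The mixture is the
  minimal shape with both required features: minima short at *all* masses
  and a 75th percentile of `B` near 1 (≈ 0.96 at the defaults) so the
  τ = 0.75 regression of totals recovers the envelope slope with only a few
  percent attenuation. A single Beta family cannot satisfy both at once.
  `opportunity_scale = Inf` forces `B = 1` for degenerate checks. Totals
  are split into 1–6 positive bouts by uniform Dirichlet weights.

**What passing tests show — and do not show.** The generator reproduces the
first two moments of the published cohorts, their contrast directions and
magnitudes, and the envelope structure of flight durations. It does not
emulate measurement error correlation between traits, seasonal condition
differences, within-colony genetic structure beyond an additive shift, or
any tether-specific artifacts; parameter-recovery results therefore
demonstrate correctness of the estimators under the assumed data-generating
process, not field validity of the biological conclusions.

## Problem sizes and numerical choices

The test suite runs the quantile solver against the brute-force oracle on
200 random datasets of n ≤ 8, and checks envelope-slope recovery on 100
seeded replicates of n = 200 queens with abdomen masses uniform on
[3.5, 6.5] mg (the claustral mass range; the expected hit rate within ±25%
of the true slope is ≥ 90%, and pilot runs give ≈ 96%). Monte-Carlo
validation of the spheroid volume uses 10⁶ points (agreement within 1%).
Bootstrap counts in examples and tests are reduced (tens to hundreds) from
the 9999 default, which is used for real analyses. These sizes were chosen
as the smallest that make the statistical assertions stable across seeds.

Degenerate inputs are rejected rather than guessed at: all-equal predictors
(no quantile or OLS fit), groups under 3 values (no normality gate), single
colonies (no homogeneity check), non-positive measurements, and abdomen
height exceeding length. CSV serialization is deterministic (6 significant
digits, `%g`; byte-idempotent on re-write) and provenance headers
deliberately omit wall-clock timestamps by default so identical
config + seed runs produce identical bytes.

## Known limitations

* The worker-production and speed-vs-mass formulas are calibrations or
  caller-supplied stubs, not re-derivations of their literature sources.
* Quantile-slope p-values are bootstrap-based and only approximate the
  published (rank-inversion era) values; corrected p-values computed from
  *rounded* printed inputs can differ in the last digit from published
  corrected values computed on unrounded ones.
* The exact specimen-level dataset behind the published regression tables
  is not distributed with the package; reproducing those coefficient tables
  exactly requires obtaining it and running `read_morphometry_table()` /
  `read_flight_table()` on its CSV export as an optional external
  validation. All pipeline pathways are exercised on synthetic stand-ins of
  the same size and design.
* Extrapolations above the ≈ 6 mg floor crossing and all parasitic-queen
  flight predictions assume claustral-derived relationships transfer across
  castes.
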