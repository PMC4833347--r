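# foundorfly

Dispersal–reproduction tradeoffs in queen-polymorphic ants, quantified.

Colonies of the fire ants *Solenopsis geminata* and *S. invicta* can produce
two queen types from the same genome: **claustral** queens with heavy,
nutrient-packed abdomens that found colonies alone, and **parasitic** queens
with light abdomens that take over orphaned conspecific nests. A queen's
abdominal load is her colony-founding capital, but she has to fly with it
first — heavier abdomens depress the flight muscle ratio, raise wing loading
and drag, and shorten maximum flight duration. `foundorfly` implements the
full analysis pipeline for this *found-or-fly* tradeoff:

* **Morphometrics** — per-queen flight-morphology indices from dry
  measurements: flight muscle ratio `FMR = m_thorax / m_body`, wing loading
  `m_body / S_wing` (mg/mm²), prolate-spheroid abdomen volume
  `V = (π/6)·L·H²` and drag reference area `V^{2/3}` (mm²), aspect ratio
  `4·l_fw²/S_wing`, wing mass density (mg/mm²).
* **Caste comparisons** — Shapiro–Wilk-gated t / Kruskal–Wallis tests,
  percent and fold contrasts, colony-average mode against
  pseudoreplication, per-type OLS of each index on abdomen mass, and
  Holm–Bonferroni step-down correction with explicit families.
* **Flight endurance** — total tethered-flight time per queen and an exact
  upper-quartile (τ = 0.75) linear quantile regression
  `min_b Σ ρ_τ(y_i − b₀ − b₁x_i)` solved by exhaustive point-pair search,
  with seeded-bootstrap slope inference, plus OLS/Spearman comparators and
  colony-homogeneity checks.
* **Tradeoff model** — converts dry abdomen mass *a* into maximum flight
  duration `D(a) = max(6742.350 − 1096.915·a, 160)` s, flight range
  `v·D` and potential colonization area `π·(vD)²` under configurable speed
  assumptions, and first-generation worker production from a calibrated
  linear model on live abdomen mass.
* **Synthetic queens** — a seeded generator reproducing the published
  statistical structure of all four species × caste cohorts (body-frame +
  abdomen decomposition, colony effects, endurance envelope with
  short-flight noise), so every stage is testable without specimens.

## Worked example

```r
library(foundorfly)

## synthesize the four reference cohorts and profile them
specs    <- table2_specs()
morph    <- do.call(rbind, lapply(specs, generate_morphometry, seed = 42))
profiles <- profile_queens(morph)

## caste contrast: flight muscle ratio in S. geminata
gem <- profiles[profiles$species == "geminata", ]
compare_castes(gem$fmr[gem$caste == "claustral"],
               gem$fmr[gem$caste == "parasitic"], trait = "fmr")
#> Caste comparison: fmr
#>   claustral  mean 0.123 (sd 0.0142, n 13)
#>   parasitic  mean 0.1902 (sd 0.0176, n 38)
#>   t test: statistic -13.84, p = 2.05e-13
#>   claustral vs parasitic: -35.3% (0.647-fold)

## upper-quartile endurance envelope in a claustral S. invicta cohort
cohort  <- generate_morphometry(specs$IC, seed = 42)
flights <- generate_flights(cohort, flight_gen_spec(), seed = 42)
ds      <- build_endurance_dataset(flights, profile_queens(cohort))
fit_quantile(ds$abdomen_mass, ds$total_flight_time, tau = 0.75,
             n_boot = 999, seed = 42)
#> Quantile regression (tau = 0.75, n = 58)
#>   intercept 5146.869, slope -791.231 (check loss 7626.2321)
#>   residuals below/above line: 42 / 14
#>   bootstrap slope p = 0.002 (999 resamples)

## tradeoff contrast between the average claustral (5.3 mg) and
## parasitic (2.7 mg) queen at the 1.5 m/s maximum flight speed
cc <- caste_contrast(5.3, 2.7, tradeoff_config())
cc[cc$speed_mode == "constant_max",
   c("quantity", "claustral", "parasitic", "fold")]
#>                quantity claustral parasitic      fold
#> 1        max_duration_s       900      3800  4.222222
#> 2               range_m      1350      5700  4.222222
#> 3 colonization_area_km2         6       102 17.000000
#> 4               workers        31        10  3.100000
```

Reading the output: in the synthetic *S. geminata* cohort claustral queens
have a ~35% lower flight muscle ratio than parasitic queens (the reference
cohorts differ by 32% in the means). The fitted τ = 0.75 slope of about
−790 s/mg says each extra milligram of abdominal load removes roughly
13 minutes from this cohort's *maximum* flight duration (the true generator
envelope is −1096.915 s/mg; a single 58-queen cohort estimates it with
sizeable spread, and the residual split 42/14 brackets 0.75·58 ≈ 43.5 as the
quantile-regression optimality condition requires). The contrast table shows
the headline tradeoff: the average parasitic queen flies over four times as
long, covers a 17-fold larger potential colonization area, and produces less
than a third of the claustral queen's first workers.

`run_pipeline(run_config(seed = 1, out_dir = "out"))` runs every stage and
writes the profile, comparison, regression, endurance, tradeoff and manifest
CSVs (with `#` provenance headers) to `out/`; identical config and seed give
byte-identical files. `simulate_queens("fixtures", seed = 1)` writes
stand-alone `morph.csv` / `flights.csv` fixtures in the package's CSV
schema.

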