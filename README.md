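# eflowalt

Quantifying hydrologic alteration in rivers and its consequences for
native-fish biodiversity, at gauge and stream-reach resolution.

## The problem

Environmental-flow management needs to know, for every stream reach, how
far the flow regime has departed from its natural state and what that
departure costs ecologically. Flow–ecology relationships — the backbone of
the ELOHA (Ecological Limits of Hydrologic Alteration) framework — are
chronically data-limited: few reaches have both long gauge records and fish
surveys. `eflowalt` implements a complete modeling chain that bridges the
gap, for hydrologists and freshwater ecologists building regional flow
standards:

1. **Hydrologic indices.** From a screened daily-discharge record (water
   years with ≤ 30 missing days; at least 15 such years), 41 standard
   indices of magnitude, duration, frequency, timing and rate of change
   (MA, ML, MH, DL, DH, FL, FH, TA, RA codes) are computed, including
   Colwell's constancy/predictability and rolling-window annual extremes.
2. **Alteration at gauges.** Expected reference conditions *E* at
   non-reference gauges are estimated by random forests trained on
   reference gauges with natural covariates (class-envelope fallback for
   unreliable indices). Per-metric alteration is the capped proportional
   change `min(|(O − E)/E|, 1) ∈ [0, 1]`, 0 for reference gauges. Two
   cumulative indices summarise the multivariate regime: a **seasonality
   index** (cumulative deviation of the 12 monthly means) and the **HAI**
   (eigenvalue-weighted excursions of significant principal-component
   scores — broken-stick criterion — outside the gauge's hydrologic-class
   reference envelope), both min–max scaled within ecohydrologic regions.
3. **Extrapolation to reaches.** Per-metric random forests predict
   alteration from 50 disturbance covariates (urbanization, agriculture,
   dams, power, dischargers, composite indices, basin/climate, natural
   cover), validated with two rank-AUC measures (reference vs
   non-reference; alteration > 0.5 vs ≤ 0.5) and permutation importance
   scaled to [0, 1].
4. **Flow–ecology thresholds.** Wedge-shaped fish richness-residual
   responses are fit by linear quantile regression (τ = 0.50/0.75/0.95)
   per HUC-4 watershed (region-mean fallback); the tipping point is the
   alteration `T = −β₀/β₁` where the fitted quantile crosses zero. Binary
   exceedance across metrics averages to a per-reach probability of fish
   biodiversity loss.
5. **Compounded uncertainty.** Forest OOB error widens the alteration
   estimate (ĤA ± error), slope standard errors widen the threshold
   (T̄, T̿), and the orderings propagate to lower/upper loss probabilities
   and banded cumulative exceedance curves.

A first-class synthetic generator (`generate_gauge_network()`,
`simulate_reference_flow()`, `apply_disturbance()`,
`generate_covariates()`, `simulate_fish_responses()`) produces gauge
networks with known ground truth — class-specific seasonal flow regimes,
dam/withdrawal/urbanization disturbance operators, covariates statistically
linked to the imposed disturbance, and a wedge fish response with a known
tipping point — so every stage is testable.

## Worked example

```r
library(eflowalt)

cfg <- default_config(seed = 1)          # 200 gauges, 1000 reaches
res <- run_pipeline(cfg, out_dir = "results/run1")

# model validation (two AUC measures per metric)
summary(res$model_stats$auc_measure1)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9631  1.0000  1.0000  0.9986  1.0000  1.0000

# HAI tracks the imposed disturbance across non-reference gauges
nonref <- !res$network$gauges$is_reference
cor(res$summary_indices$hai_raw[nonref],
    res$network$gauges$disturbance_total[nonref], method = "spearman")
#> [1] 0.3973262

# tipping point recovered from the synthetic wedge (truth = 0.4)
head(tidy(res$quantile_fits))
autoplot(res$curves)                     # cumulative loss-probability band
```

On this synthetic network the per-metric forests separate reference from
non-reference gauges almost perfectly (mean AUC measure 1 ≈ 0.999 — the
imposed disturbance signal is strong by construction), the HAI is
positively rank-correlated with total imposed disturbance (ρ ≈ 0.40), and
the τ = 0.95 quantile fit of the wedge crosses zero at ≈ 0.35 against a
true tipping point of 0.4.

Single-gauge use works on plain files too:

```r
s <- read_daily_flow("gauge.rdb", dialect = "nwis-rdb", drainage_area = 250)
compute_metric_vector(s)   # one row, 41 index columns
```

## Layout

- `R/` — synthetic generators, metric engine, alteration indices
  (PCA/broken-stick/HAI), alteration models, flow-ecology quantile fits,
  uncertainty propagation, IO and pipeline orchestration.
- `vignettes/methods.Rmd` — the model, its assumptions, parameter choices
  and limitations.
- `tests/testthat/` — unit, property and acceptance suites with
  brute-force oracles (exhaustive window search, run-length scanner,
  literal broken-stick sums, pair-enumeration quantile regression).
- `inst/cli/eflow.R` — thin command-line wrapper over `run_pipeline()`.
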