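---
title: "Methods: from daily discharge to fish biodiversity risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from daily discharge to fish biodiversity risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eflowalt)
```

`eflowalt` chains five models: a hydrologic index engine, an
observed-vs-expected alteration calculus, covariate-driven extrapolation,
quantile-regression flow–ecology thresholds, and error propagation. This
vignette records the assumptions, the tunable parameters and the choices
made where the design was genuinely open.

## Record screening and the metric engine

A gauge record enters the analysis only if at least 15 water years
(October 1 – September 30, labelled by the ending calendar year) each have
at most 30 missing daily values. Shorter records make several annual
statistics unstable; the screen is a hard, typed failure rather than a
silent pass. Missing days inside retained years are excluded from means
and percentiles rather than imputed — with at most 30 missing days the
bias is bounded — and annual event counts are prorated to a 365-day year.

The 41 indices cover magnitude (MA1–MA3 mean/median/CV of daily flow,
MA12–23 monthly means, MA41 and MH20 per-km² runoff and annual maximum,
ML17/ML19 baseflow ratios), duration (DL1–5/DH1–5: annual extremes of
1/3/7/30/90-day trailing means, windows fully contained in a water year;
DL16/DH15 median pulse durations; DL18 zero-flow days), frequency
(FL1/FH1 excursion counts below/above the low/high pulse thresholds;
FH6/FH7 events above 3× and 7× the median daily flow), timing (Colwell's
constancy TA1 and predictability TA2) and rate of change (RA1 rise, RA3
fall — stored as a positive magnitude — and RA8 reversals).

Open choices, fixed as follows:

- **Pulse thresholds** are the 25th/75th percentiles of all daily flows in
  the screened record — the standard convention for low/high pulse
  indices.
- **Colwell discretisation**: 12 monthly periods crossed with 11
  logarithmically spaced flow states between the record's positive minimum
  and maximum; zero flows occupy their own state. With state entropy H(Y),
  month entropy H(X) and joint entropy H(XY), TA1 = 1 − H(Y)/log s and
  TA2 = 1 − (H(XY) − H(X))/log s. Both equal 1 for constant flow, and an
  exactly repeating seasonal cycle gives TA2 = 1 with TA1 < 1.
- **Calendar**: synthetic data use fixed 365-day years; the file readers
  drop 29 February. This keeps water-year arithmetic and rolling windows
  exact.
- An event is a *maximal run* of consecutive qualifying days, so a 65-day
  excursion is one event, not 65.

## Alteration at gauges

Expected (reference) conditions at non-reference gauges come from
per-metric random forests trained on reference gauges using natural
covariates only (basin size, climate proxy, natural cover). Indices whose
point models are unreliable — by default the timing pair TA1/TA2 —
instead use the central 90% interval (5th–95th percentile) of reference
values within the gauge's hydrologic class; "90th percent confidence
interval" is deliberately read as this empirical central interval, since
no estimator is otherwise defined. Classes with fewer than two reference
gauges inherit the pooled global envelope, with a warning.

Per-metric alteration is `min(|(O − E)/E|, 1)`: absolute proportional
change capped at 1, and exactly 0 for reference gauges. When E = 0 the
ratio is undefined; the conventions 0/0 → 0 and O>0/0 → 1 keep
intermittent-stream metrics defined and are logged when triggered. For an
interval expectation the alteration is zero inside the interval and the
capped proportional distance to the nearest bound outside it.

The **seasonality index** sums the twelve monthly deviations. The literal
signed sum lets a wet-season increase cancel a dry-season decrease into
zero "alteration", so the default sums absolute deviations; the signed
variant remains available (`seasonality$signed`) for fidelity.

The **HAI** measures multivariate departure: all metric columns are
min–max scaled to [0, 1], centred, and decomposed by PCA fit on reference
and non-reference gauges jointly (envelopes, however, use reference gauges
only). The number of significant components k follows the broken-stick
rule — component j is significant while its variance share strictly
exceeds b_j = (1/p) Σ_{i=j..p} 1/i — with a floor of one component so the
index stays defined on weakly structured tables. For each gauge, each
significant score S_i outside its class's reference envelope (a_i, b_i)
contributes |S_i − nearest bound| × V_i, V_i the eigenvalue. PC signs are
fixed (largest-magnitude loading positive) for reproducibility. Envelope
percentiles are computed before the regional scaling of the index, and a
gauge's hydrologic class must be given explicitly. Both cumulative indices
are then min–max scaled within each ecohydrologic region (rank-preserving;
a constant region scales to zeros with a warning).

## Alteration models and extrapolation

One random forest per metric and scope (US-wide, optionally per region)
regresses alteration on the 50 disturbance covariates. The response is
continuous in [0, 1], so the forests are regressions with clipped
predictions; a classification mode on the binarised response
(alteration > 0.5) exists for comparison, because fractional values
cannot be treated as strict binomial counts without a trials number.
Defaults: 500 trees in direct calls (300 in the pipeline), mtry = p/3,
minimum 20 training gauges per scope (smaller scopes are skipped with a
logged reason). Validation uses out-of-bag predictions and two midrank
AUCs: measure 1 against the reference/non-reference partition, measure 2
against high (> 0.5) vs low observed alteration; a single-class control
yields an undefined (NA) measure, never 0. Permutation importance is
min–max scaled to [0, 1] within each model and summarised by covariate
group. Under the regional scope policy a reach without a regional model
falls back to the US model and is tagged.

## Flow–ecology thresholds and loss probability

Richness residuals (observed − expected native species) respond to
alteration in a wedge: the upper envelope declines while low values occur
everywhere, so linear quantile regression at τ = 0.50/0.75/0.95 targets
the envelope. Fits are per HUC-4 and metric (HAI excluded from ecological
fitting), skipped below `min_n = 20` observations or for constant
alteration; missing HUC-4 coefficients fall back to the unweighted region
mean with root-mean-square-pooled slope SEs. Slope standard errors come
from a paired bootstrap (default 60–100 replicates, seeded); quantreg's
`nid` sandwich is available.

The tipping point is T = −β₀/β₁ clipped to [0, 1] when β₁ < 0; a
non-declining fit with β₀ < 0 means species are already lost at zero
alteration (T = 0); a non-declining fit with β₀ ≥ 0 never crosses zero, so
the threshold is undefined and the metric is excluded from that
subregion's response vector — shrinking the denominator n rather than
counting "no evidence" as safety. Exceedance uses the ≥ boundary rule
(alteration equal to the threshold counts as loss). The loss probability
is the mean of the binary exceedances across metrics; richness deltas
(β₀ + β₁·HA per metric) are summarised by their median and minimum.

## Uncertainty propagation

Alteration bounds add/subtract each model's OOB error (literal MSE by
default; an RMSE option exists because MSE is not in alteration units).
Threshold bounds re-derive the crossing at slopes β₁ ∓ SE; when the
flattened slope reaches zero the crossing escapes the unit interval and
the upper bound is 1. For the probability bounds the package defaults to
the ordering-consistent pairing — lower limit: even the minimum alteration
exceeds the maximum threshold; upper limit: the maximum alteration exceeds
the minimum threshold — which guarantees p_lower ≤ p ≤ p_upper. The
printed-inequality variant, which pairs the minimum threshold with the
maximum alteration for the *lower* limit and therefore reverses that
ordering, is available as `literal_eq67 = TRUE` and is recorded in output
metadata. Cumulative exceedance curves report, for each probability level
q, the (optionally length-weighted) share of reaches with p ≥ q; the band
curves bracket the point curve and all are non-increasing by construction.

## What the synthetic generator does and does not emulate

Reference flows are a class-specific seasonal sinusoid (specific runoff ×
drainage area; amplitude 0.3–0.8; class-specific phase) with
multiplicative lognormal noise (sd 0.15–0.20) and Poisson storm pulses
(8–16 per year, exponential decay); one class is intermittent with a
dry-season floor producing genuine zero-flow days. Disturbance operators:
withdrawal scales flows by 1 − w; dam storage blends toward a moving
average (window up to 31 days) with a minimum-release floor at the 20th
percentile, damping high-flow maxima and raising minima; urban flashiness
adds short spikes with fast recessions; a seasonal shift rotates each
water year by 30-day months. Covariates are noisy monotone transforms
(powers 0.5/1/2) of the true intensities, grouped as in the 8-group
predictor registry; natural covariates are deterministic functions of
area and class. Ground-truth alteration for tests is *computed* by running
the metric engine on paired reference/disturbed series, never assumed.

The fish response draws residuals uniformly in a band of width one species
below the wedge upper bound, which is 0 up to the true threshold and
declines linearly to −max_loss at full alteration. The band is deliberately
narrow: the τ = 0.95 linear fit targets the upper envelope, and a much
wider scatter band flattens the fitted line against the flat pre-threshold
limb and biases its zero crossing low, defeating the generator's purpose
of providing a recoverable tipping point. Uniform noise keeps the fitted
quantiles analytically predictable.

Not emulated: rainfall–runoff physics, spatial routing and flow
accumulation, climate nonstationarity, spatial autocorrelation of model
errors, and the joint distribution of real disturbance regimes (the
intensities are drawn independently). Passing tests therefore demonstrate
the *mechanics* of the chain — identifiability, orderings, determinism —
not predictive skill on real gauges; the near-perfect synthetic AUCs
reflect a deliberately strong disturbance signal, not expected real-world
performance.

## Problem sizes and numerical choices

The standard study configuration is 200 gauges (40% reference), 1000
reaches, 4 regions × 2 HUC-4s, 4 classes, 20-year records, covariate
noise sd 0.05, wedge threshold 0.4 with max loss 5 species — sizes at
which every stage's statistical behaviour (forest AUCs, envelope coverage,
quantile-fit recovery) is stable while a full run completes in about two
minutes. Test fixtures use 15–16-year records and 50–120-gauge networks.
Tolerances: exact (1e-12 … 1e-9) for the deterministic engine against its
brute-force oracles; ±0.1 for Monte-Carlo recoveries (tipping point,
null AUC). Degenerate inputs — constant series, all-zero eigenvalues,
single-class AUC controls, empty regions — return typed errors, warnings
or NA markers as documented, never silent zeros.

## Known limitations

- Alteration values are standardised to [0, 1] and are risk indicators,
  not probabilities in a strict sense; regional min–max scaling induces
  regional bias, so US-scope models are preferable for US-wide use.
- The MSE-based alteration bounds are literal (squared-unit) adjustments;
  use the RMSE option for unit-consistent bounds.
- The quantile fits are linear in alteration; no basis expansion is
  offered because the threshold derivation assumes a single zero crossing.
- With 60-replicate bootstrap SEs, threshold bounds have Monte-Carlo
  noise of a few percent; raise `ecology$n_boot` for tighter bounds.
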