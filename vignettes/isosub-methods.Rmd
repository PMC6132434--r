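---
title: "Methods: accelerometer processing and isotemporal substitution modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accelerometer processing and isotemporal substitution modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isosub)
```

## The scientific problem

Daily time is a closed budget: a child who spends more time in
moderate-to-vigorous physical activity (MVPA) necessarily spends less time
in sedentary behaviour or light physical activity (LPA).  Ordinary
regressions of a health marker on one behaviour ignore this constraint and
answer an ill-posed question ("more MVPA *and* more of everything else?").
Isotemporal substitution modelling makes the traded-off time explicit: it
estimates the association of moving a fixed amount of time from one
behaviour into another, holding the total measurement window constant.

`isosub` implements this analysis end to end for multi-study samples of
children and adolescents: processing epoch-level accelerometer counts into
per-person daily behaviour summaries, fitting the three model classes of
the framework with study-level clustering, and converting coefficients
into the relative (percent-of-mean) effects used for reporting.  Because
pooled youth accelerometer databases such as ICAD are access-restricted,
the package ships a synthetic cohort generator that emulates their
structure, so every stage is testable against known ground truth.

## Epoch processing

Raw count streams arrive as an `epoch_series`: one person's time-stamped,
gap-free (within a day) stream at a fixed epoch length.

* **Reintegration.** Streams recorded at finer epochs are summed into
  60-s epochs.  Input must tile the target windows exactly; gaps are an
  error rather than being zero-filled, because silently imputed zeros
  would manufacture sedentary time.
* **Non-wear scan.** A non-wear period is at least 60 min of consecutive
  zero-count epochs, allowing at most 2 min of non-zero interruption
  inside the run.  We interpret the allowance as *at most 2 non-zero
  epochs in total per candidate window, with no ceiling on the
  interrupting counts, and an interruption can neither open nor close a
  run* — the most literal reading of the rule.  The implementation marks
  the union of all qualifying windows in a single left-to-right pass; its
  behaviour is frozen by an independent brute-force window-enumeration
  oracle in the test suite, which the scan must match epoch-for-epoch on
  a thousand fuzzed day-length streams.
* **Intensity classification.** Counts per 60-s epoch are banded with the
  Evenson youth cut-points by default (sedentary ≤ 100 cpm, MVPA ≥ 2296
  cpm), supplied as configuration.  Band edges are inclusive on the upper
  side; this convention is ours and is stated in the documentation.
* **Validity.** A day is valid with wear time between 10 h and 16 h.  The
  16-h cap (a screen for monitors worn overnight) is applied *per day*
  rather than by dropping the person — the conservative reading — and both
  bounds are configurable.  Persons need at least one valid day; means are
  taken over valid days only.  Counts per minute (cpm) is defined as the
  per-day ratio of wear counts to wear minutes averaged over valid days.
* **Day boundary.** Days are calendar days in the stream's own clock
  (processed as UTC); the scan never crosses midnight.

Two invariants hold exactly, not approximately: intensity minutes
partition wear minutes, and reintegration conserves total counts per day.

## The synthetic cohort generator

The generator defines the conditions under which the package validates
itself.  It emulates a pooled database of 13 study clusters with three age
groups — children (< 10 y), adolescents (10 to < 15 y), older adolescents
(≥ 15 y) — in a roughly 27/60/13 mix, with group-level behaviour and
outcome distributions calibrated to the published pooled descriptives
(`icad_descriptives()`).  The default cohort size, 13 × 154 ≈ 2000
persons, is the scale used for the package's simulation studies.

Design choices worth stating explicitly:

* **Compositions.** Sedentary, LPA and MVPA minutes are drawn per person
  as independent normals truncated at zero, and wear time is *defined* as
  their sum, so the compositional identity holds exactly.  An alternative
  — drawing wear separately and rescaling the components onto it — was
  rejected because the rescaling distorts the component SDs by roughly a
  quarter, defeating the calibration targets.  The cost is that simulated
  wear time has a larger SD than the published descriptive (components
  drawn independently cannot reproduce the negative correlations of real
  time use); the published wear mean/SD are kept for scheduling and
  reporting only.
* **Moment calibration.** Truncation at zero shifts a naive draw's mean
  upward (for older adolescents' MVPA, mean 39 and SD 29, by about
  5 min/day).  The generator therefore solves for the parent mean and SD
  whose *truncated* moments equal the configured targets, so realised
  group means and SDs converge to the published values as the sample
  grows.
* **Planted effects.** Outcomes follow a linear model on the
  10-min/day exposure scale with fixed behaviour, sex and (for non-WC
  outcomes) WC effects, a study-level random intercept, and an i.i.d.
  residual.  The default true model plants the published
  waist-circumference partition coefficients per age group, with the MVPA
  coefficient anchored so the implied MVPA-for-sedentary substitution
  equals the published isotemporal estimate exactly (−0.287, −0.589,
  −0.814 cm per 10 min/day).  No variance components are published, so
  the study-intercept SD default (2 cm for WC) is an order-of-magnitude
  choice; residual SDs default to the published group outcome SDs
  (slightly conservative, since the planted fixed effects add variance on
  top).  Skewed outcomes such as insulin can be emulated by exponentiating
  a log-scale linear model, exercising the log-transform sensitivity path.
* **Stream realisation.** `realize_epoch_stream()` lays a composition out
  as randomised bouts of in-band counts plus zero-count non-wear blocks.
  Sedentary counts are drawn from 1–100 cpm so wear time contains no
  zero runs at all, blocks are at least 60 min, and consecutive blocks are
  separated by at least 3 wear minutes so the interruption allowance
  cannot bridge them: processing a realised stream recovers the intended
  composition *exactly*, and the test suite holds the package to that over
  hundreds of fuzzed compositions.

What the generator does **not** emulate: realistic diurnal activity
profiles, autocorrelated count series, device noise, or correlated
behaviour draws.  Passing tests therefore demonstrate the correctness of
the processing rules and estimators under the stated statistical
structure — not robustness to the messiness of real accelerometer data.

## The three-step modelling framework

Exposures are first divided by 10 so every coefficient reads as the effect
of reallocating 10 min/day.  For each outcome and age-group stratum the
framework fits, with sex (coded 0 = female, 1 = male) and — except when WC
is the outcome — waist circumference as covariates:

1. **Single-factor models**: one behaviour at a time, estimating its
   total, mutually unadjusted association.  The published description of
   these models does not list their covariates; we mirror the partition
   covariate set (minus the other behaviours) for comparability, and the
   inclusion of wear time is exposed as a switch (off by default).
2. **Partition model**: all three behaviours jointly, *without* wear time
   (which is their sum and would be collinear).  Coefficients are effects
   of adding time to one behaviour while the others are held fixed.
3. **Isotemporal substitution models**: drop one behaviour, keep the
   other two *plus wear time*.  Because wear = S + L + M in the data,
   this design spans the same column space as the partition design, and
   each retained behaviour's coefficient equals the difference between
   its partition coefficient and that of the dropped behaviour — the
   algebra that justifies the "substitution" interpretation.  The test
   suite verifies this identity to below 1e-8 under both estimators on
   hundreds of fuzzed cohorts, and it makes rendered substitution tables
   exactly antisymmetric.

### Estimation

Studies are panels and clusters.  The default estimator is a
random-study-intercept feasible GLS: variance components come from a
Swamy–Arora-type within/between moments decomposition (within-residual
variance from the fixed-effects regression; the study-intercept variance
from the group-means regression net of within noise, floored at zero),
followed by quasi-demeaning with the estimated fraction
θ_g = 1 − √(σ²_e / (σ²_e + T_g σ²_u)) and OLS on the transformed data.  A
pooled-OLS estimator is provided as the fully specified reference path,
and the identity tests run under both.

Standard errors are cluster-robust by default: the sandwich estimator
aggregating score contributions by study, with the standard finite-sample
scaling G/(G−1) × (N−1)/(N−k).  p-values and 95% intervals use the normal
reference distribution.  With 5–13 clusters this combination is known to
be slightly liberal; we document the caveat rather than adopt small-sample
corrections, and the package's coverage simulation (500 cohorts at the
default scale, planted effect −0.589) checks that nominal 95% intervals
cover the truth within the 93–97% band.  Conventional (i.i.d.) variance is
available for comparison and agrees with the cluster-robust estimate in
distribution when the study-intercept variance is truly zero.

### Diagnostics and screens

* **Collinearity**: per-exposure VIF = 1/(1 − R²) against the other
  non-intercept columns, with tolerance its reciprocal; each fit carries
  its mean VIF and minimum tolerance.  Rank-deficient designs are an
  error naming the offending columns, not a silent drop.
* **Effect modification**: `interaction_screen()` adds a sex × MVPA term
  to the partition design and reports its Wald p — the screen used to
  justify pooling sexes.
* **Skewed outcomes**: `log_sensitivity()` refits any specification on the
  natural log of a strictly positive outcome.
* **Missing data**: complete-case per model; each fit reports its own
  n, mirroring how the published tables vary in n across outcomes.

## Reporting

Relative effects are 100 × |β| / (stratum outcome mean), rounded half-up
to one decimal — the convention that reproduces every published headline
percentage from the full-precision coefficients (e.g. −0.287 cm against a
59.1 cm mean → 0.5%).  Rounding is half-up, not banker's, at one decimal
for percentages and three decimals for table coefficients.  The stratum
mean used in a live analysis is the observed outcome mean among the rows
entering the model; the worked examples inject the published means
directly.  One published glucose percentage (0.4%) is not reproducible
from the printed coefficient and mean (−0.016/5.16 ≈ 0.3%), so glucose is
excluded from the worked examples.

`render_table()` lays fits out in the conventional block structure
(Single / Partition / Reduce sedentary / Reduce LPA / Reduce MVPA per
stratum) with `Dropped` on the diagonal of the substitution block.

## Pipeline, configuration and reproducibility

`run_pipeline()` chains simulate → process → fit → report, writing every
intermediate table as headed CSV plus the rendered text tables, logging
the seed and per-stage row counts; identical configuration and seed give
byte-identical results.  Configuration can be supplied as a YAML file
(`read_pipeline_config()`); a demo configuration ships in
`inst/extdata/demo-config.yaml`.  The package's command surface is its
exported functions — this is a library meant to be driven from R scripts,
so no shell executable is installed; `scripts/acceptance.R` in the source
repository shows the full analysis driven non-interactively.

Validation (`validate_inputs()`) joins phenotypes to processed summaries,
assigns age groups at the 10- and 15-year boundaries, restricts ages to
the 4–18 range, and enforces the compositional identity to a 1-minute
tolerance; duplicate ids are fatal, everything else is excluded and
reported.

## Numerical choices and problem sizes

* Linear algebra via QR throughout; no matrix inversions except the
  bread of the sandwich (via Cholesky of X'X after a rank check).
* Degenerate inputs are errors with named causes: gaps in epoch grids,
  negative counts, rank-deficient designs, single-cluster cluster-robust
  requests, non-positive outcomes under log transform, constant outcomes
  in the interaction screen.
* Truncated-normal calibration solves a two-parameter moment match by
  Nelder–Mead to a relative objective below 1e-8; degenerate (SD 0)
  and effectively untruncated (mean/SD > 6) cases short-circuit.
* The simulation studies in the tests and the acceptance script use
  200 fuzzed cohorts of n = 500 for the identity check, 1000 fuzzed
  day-length streams for the non-wear oracle, 500 fuzzed compositions for
  the roundtrip, and 500 replicate cohorts of n ≈ 2000 for recovery and
  coverage — sizes chosen so each property is measured with comfortable
  Monte-Carlo precision.

## Known limitations

* The estimator quasi-demeans with a single moments-based variance
  decomposition; REML would differ slightly in small samples (the test
  suite cross-checks point estimates against a mixed-model fit).
* Normal-reference inference with ~13 clusters is mildly liberal; no
  cluster bootstrap or small-cluster degrees-of-freedom correction is
  implemented.
* One intensity band for MVPA (no separate vigorous band), no bout
  detection, no triaxial/raw-acceleration support.
* The generator's independence of behaviour draws understates real
  time-use correlations; simulated wear-time dispersion is therefore
  wider than the published descriptive.
* Insulin units are passed through as printed in the source descriptives
  without harmonisation.
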