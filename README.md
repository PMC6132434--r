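# isosub

Isotemporal substitution modelling of accelerometer-measured time use in
children and adolescents.

Daily time is a closed budget: time added to moderate-to-vigorous physical
activity (MVPA) must come out of sedentary time or light physical activity
(LPA). `isosub` implements the analysis framework built around that
constraint for pooled multi-study samples of young people:

* **Epoch processing** — reintegrates raw accelerometer count streams to
  60-s epochs, detects non-wear (≥ 60 min of consecutive zeros, allowing
  ≤ 2 min of non-zero interruption), screens days to 10–16 h of valid
  wear, classifies epochs with the Evenson youth cut-points (sedentary
  ≤ 100 cpm, MVPA ≥ 2296 cpm), and averages valid days into per-person
  summaries.
* **Three-step modelling** — with exposures scaled so coefficients are per
  10 min/day, fits *single-factor* models (one behaviour), the *partition*
  model (all behaviours, no wear time), and *isotemporal substitution*
  models (drop one behaviour, keep the rest plus wear time).  In the ISM
  design the coefficient b_j of a retained behaviour estimates the effect
  of reallocating 10 min/day into j from the dropped behaviour k, and
  equals the partition difference b_j − b_k exactly.  Estimation uses
  random study intercepts (feasible GLS with a Swamy–Arora-type moments
  decomposition) and cluster-robust sandwich variance aggregated by study;
  pooled OLS and conventional variance are available for comparison.
  Diagnostics include per-exposure VIF/tolerance, a sex × MVPA
  interaction screen, and a log-outcome sensitivity refit.
* **Reporting** — absolute coefficients with 95% CIs and significance
  flags (`*` p < 0.05, `**` p ≤ 0.001), relative effects as
  100 × |β| / stratum mean rounded half-up to one decimal, and
  published-style text tables.
* **Synthetic cohorts** — a generator emulating a pooled 13-study youth
  database (age groups < 10, 10–< 15, ≥ 15 years; behaviour and outcome
  distributions calibrated to published descriptives; planted
  reallocation effects; study-level random intercepts), plus an epoch
  stream realiser whose output processes back to the intended composition
  exactly.  Real pooled databases of this kind are access-restricted, so
  all validation is against this generator's known ground truth.

## Worked example

The shipped demo configuration simulates a small six-study cohort,
realises epoch streams, processes them back, fits the framework for waist
circumference (WC) and reports:

```r
library(isosub)
cfg <- read_pipeline_config(
  system.file("extdata", "demo-config.yaml", package = "isosub"),
  out_dir = tempfile("demo"))
res <- run_pipeline(cfg)
#> [isosub] simulate: seed = 20260301, 6 studies x 12 persons
#> [isosub] simulate: wrote 207360 epochs, 72 phenotype rows
#> [isosub] process: 144 person-days -> 72 person summaries
#> [isosub] validate: 72 persons kept, 0 issues
#> [isosub] fit: 21 models, 87 coefficient rows
#> [isosub] report: wrote relative effects and tables

subset(res$results, model_class == "isotemporal" & stratum == "adolescents" &
                    term %in% c("sedentary", "lpa", "mvpa"),
       c(substitution, term, beta, ci_low, ci_high, p, n))
#>      substitution      term    beta ci_low ci_high     p  n
#>  reduce_sedentary       lpa -0.3563 -1.339   0.627 0.477 39
#>  reduce_sedentary      mvpa -0.0234 -1.321   1.274 0.972 39
#>        reduce_lpa sedentary  0.3563 -0.627   1.339 0.477 39
#>        reduce_lpa      mvpa  0.3329 -1.404   2.070 0.707 39
#>       reduce_mvpa sedentary  0.0234 -1.274   1.321 0.972 39
#>       reduce_mvpa       lpa -0.3329 -2.070   1.404 0.707 39
```

Each `beta` is the estimated change in WC (cm) when 10 min/day moves from
the reduced behaviour into the named one, wear time held constant; note
the exact antisymmetry (reallocating j→k is minus k→j).  At this toy
sample size (39 adolescents) nothing is significant — the demo shows the
mechanics, not power.  `res$relative_effects` expresses the same
coefficients as percentages of the stratum WC mean, and
`res$paths$tables` contains the rendered table blocks.

The published headline relative effects are reproduced by the reporting
arithmetic directly from the published coefficients and stratum means:

```r
relative_effect(-0.287, 59.1)  # children, sedentary -> MVPA: 0.5 (%)
relative_effect(-0.019, 0.86)  # adolescents triglycerides: 2.2 (%)
```

## Documentation

The methods vignette (`vignettes/isosub-methods.Rmd`) describes the
processing rules, the estimator, the generator's design and its
deliberate simplifications, numerical choices, and known limitations.
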