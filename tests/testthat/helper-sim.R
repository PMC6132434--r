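# Small cohort configurations shared across model tests.

small_config <- function(seed = NULL, n_studies = 6L, persons_per_study = 50L,
                         study_sd = 2, resid_sd = NULL) {
  sim_config(n_studies = n_studies, persons_per_study = persons_per_study,
             study_intercept_sd = c(wc = study_sd),
             residual_sd = resid_sd, seed = seed)
}

# cohort with zero noise: outcomes are an exact linear function of the
# planted model, so fits must recover coefficients to numerical precision
noiseless_cohort <- function(seed = 11, n_studies = 5L,
                             persons_per_study = 40L) {
  cfg <- small_config(seed, n_studies, persons_per_study,
                      study_sd = 0, resid_sd = c(wc = 0))
  simulate_study(cfg)
}
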