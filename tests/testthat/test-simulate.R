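test_that("cohort generation is deterministic under a seed", {
  cfg <- small_config(seed = 123, persons_per_study = 20L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 124
  expect_false(identical(simulate_study(cfg2), a))
})

test_that("degenerate SDs give exactly the group-mean composition", {
  beh <- icad_descriptives()
  beh[paste0(c("sedentary", "lpa", "mvpa"), "_sd")] <- 0
  cfg <- sim_config(n_studies = 3L, persons_per_study = 30L,
                    behaviours = beh, seed = 1)
  co <- simulate_cohort(cfg)
  for (grp in c("children", "adolescents", "older")) {
    rows <- co$age_group == grp
    ref <- beh[beh$age_group == grp, ]
    expect_equal(unique(co$sedentary[rows]), ref$sedentary_mean)
    expect_equal(unique(co$lpa[rows]), ref$lpa_mean)
    expect_equal(unique(co$mvpa[rows]), ref$mvpa_mean)
  }
  # compositional identity always holds
  expect_equal(co$sedentary + co$lpa + co$mvpa, co$wear)
})

test_that("simulated behaviour moments converge to configured targets", {
  cfg <- sim_config(n_studies = 10L, persons_per_study = 600L, seed = 55)
  co <- simulate_cohort(cfg)
  beh <- icad_descriptives()
  for (grp in c("children", "adolescents", "older")) {
    rows <- co$age_group == grp
    n_g <- sum(rows)
    ref <- beh[beh$age_group == grp, ]
    for (b in c("sedentary", "lpa", "mvpa")) {
      m <- ref[[paste0(b, "_mean")]]; s <- ref[[paste0(b, "_sd")]]
      expect_lt(abs(mean(co[[b]][rows]) - m), 3 * s / sqrt(n_g))
      expect_lt(abs(sd(co[[b]][rows]) - s), 3 * s / sqrt(2 * n_g))
    }
  }
  # age groups respect their boundaries
  expect_true(all(co$age[co$age_group == "children"] < 10))
  expect_true(all(co$age[co$age_group == "adolescents"] >= 10 &
                    co$age[co$age_group == "adolescents"] < 15))
  expect_true(all(co$age[co$age_group == "older"] >= 15))
})

test_that("infeasible behaviour targets raise configuration errors", {
  beh <- icad_descriptives()
  beh$mvpa_mean <- -5
  expect_error(simulate_cohort(sim_config(behaviours = beh, seed = 1)),
               "infeasible")
  expect_error(sim_config(age_group_mix = c(children = 0.5,
                                            adolescents = 0.5, older = 0.5)),
               "sum to 1")
})

test_that("planted outcome effects are exact when variances are zero", {
  co <- noiseless_cohort()
  tm <- default_true_model()
  for (grp in c("children", "adolescents", "older")) {
    rows <- which(co$age_group == grp)[1:2]
    t_g <- tm[tm$age_group == grp, ]
    # move 10 min/day from sedentary to MVPA by hand and check the outcome
    delta <- co[rows[1], ]
    delta$sedentary <- delta$sedentary - 10
    delta$mvpa <- delta$mvpa + 10
    cfg <- small_config(study_sd = 0, resid_sd = c(wc = 0))
    y <- simulate_outcomes(rbind(co[rows[1], 1:9], delta[1:9]),
                           tm, cfg)$wc
    expect_equal(y[2] - y[1], t_g$b_mvpa - t_g$b_sed, tolerance = 1e-10)
  }
  # zero effects + zero variances -> outcome identically the intercept
  tm0 <- true_model("wc", "adolescents", 0, 0, 0, sex_effect = 0,
                    intercept = 42)
  cfg0 <- small_config(study_sd = 0, resid_sd = c(wc = 0))
  co0 <- co[co$age_group == "adolescents", 1:9]
  expect_equal(unique(simulate_outcomes(co0, tm0, cfg0)$wc), 42)
})

test_that("study intercepts alone create only between-study variance", {
  cfg <- small_config(seed = 99, n_studies = 10L, persons_per_study = 50L,
                      study_sd = 5, resid_sd = c(wc = 0))
  tm <- true_model("wc", "adolescents", 0, 0, 0, sex_effect = 0,
                   intercept = 60)
  cfg$age_group_mix <- c(children = 0, adolescents = 1, older = 0)
  co <- simulate_outcomes(simulate_cohort(cfg), tm, cfg)
  within_var <- tapply(co$wc, co$study_id, var)
  expect_true(all(within_var < 1e-20))
  expect_gt(var(tapply(co$wc, co$study_id, mean)), 0)
})

test_that("multiplicative models produce right-skewed positive outcomes", {
  cfg <- small_config(seed = 3, n_studies = 8L, persons_per_study = 100L,
                      study_sd = 0)
  cfg$age_group_mix <- c(children = 1, adolescents = 0, older = 0)
  tm <- true_model("insulin", "children", b_sed = 0.02, b_lpa = 0,
                   b_mvpa = -0.1, multiplicative = TRUE)
  co <- simulate_outcomes(simulate_cohort(cfg), tm, cfg)
  expect_true(all(co$insulin > 0))
  sk <- mean((co$insulin - mean(co$insulin))^3) / sd(co$insulin)^3
  expect_gt(sk, 0.5)
})
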