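test_that("exposure scaling is a pure change of units", {
  co <- simulate_study(small_config(seed = 2))
  sc <- scale_exposures(co, 10)
  expect_equal(sc$sedentary, co$sedentary / 10)
  expect_equal(attr(sc, "exposure_unit"), 10)
  expect_equal(scale_exposures(co, 1)$sedentary, co$sedentary)
  expect_error(scale_exposures(co, 0), "positive")

  # coefficients per 10 min are 10x coefficients per minute; t unchanged
  f10 <- fit_model(model_spec("partition", "wc", unit = 10,
                              stratum = "adolescents"), co)
  f1 <- fit_model(model_spec("partition", "wc", unit = 1,
                             stratum = "adolescents"), co)
  b10 <- f10$coefficients[f10$coefficients$term == "mvpa", ]
  b1 <- f1$coefficients[f1$coefficients$term == "mvpa", ]
  expect_equal(b10$estimate, 10 * b1$estimate, tolerance = 1e-8)
  expect_equal(b10$estimate / b10$se, b1$estimate / b1$se, tolerance = 1e-8)
})

test_that("designs contain exactly the specified columns", {
  co <- simulate_study(small_config(seed = 4))
  d_iso <- build_design(model_spec("isotemporal", "wc", drop = "sedentary",
                                   stratum = "children"), co)
  expect_equal(colnames(d_iso$X),
               c("(Intercept)", "lpa", "mvpa", "wear", "sex"))
  co$sbp <- rnorm(nrow(co), 100, 10)
  d_part <- build_design(model_spec("partition", "sbp",
                                    stratum = "adolescents"), co)
  expect_equal(colnames(d_part$X),
               c("(Intercept)", "sedentary", "lpa", "mvpa", "sex", "wc"))
  d_sing <- build_design(model_spec("single", "wc", exposure = "mvpa",
                                    stratum = "children"), co)
  expect_equal(colnames(d_sing$X), c("(Intercept)", "mvpa", "sex"))

  expect_error(build_design(model_spec("single", "wc", exposure = "mvpa",
                                       stratum = "toddlers"), co), "stratum")
  # wear alongside all three behaviours is rank-deficient, named as such
  spec_bad <- model_spec("partition", "wc", stratum = "children",
                         covariates = c("sex", "wear"))
  expect_error(build_design(spec_bad, co), "rank-deficient")
  expect_error(model_spec("isotemporal", "wc"), "drop")
  expect_error(model_spec("partition", "wc", include_wear = TRUE), "sum of")
})

test_that("complete-case filtering sets per-model n", {
  co <- simulate_study(small_config(seed = 6))
  co$wc[1:25] <- NA
  st <- as.character(co$age_group[1:25])
  f <- fit_model(model_spec("partition", "wc", stratum = "adolescents"), co)
  lost <- sum(st == "adolescents")
  expect_equal(f$n_obs, sum(co$age_group == "adolescents") - lost)
})

test_that("noiseless fits recover planted coefficients to 1e-8", {
  co <- noiseless_cohort()
  tm <- default_true_model()
  for (grp in c("children", "adolescents", "older")) {
    truth <- tm[tm$age_group == grp, ]
    for (est in c("pooled_ols", "random_effects_gls")) {
      f <- fit_model(model_spec("partition", "wc", stratum = grp,
                                estimator = est), co)
      b <- f$coefficients
      expect_equal(b$estimate[b$term == "sedentary"], truth$b_sed,
                   tolerance = 1e-8)
      expect_equal(b$estimate[b$term == "lpa"], truth$b_lpa,
                   tolerance = 1e-8)
      expect_equal(b$estimate[b$term == "mvpa"], truth$b_mvpa,
                   tolerance = 1e-8)
      g <- fit_model(model_spec("isotemporal", "wc", drop = "sedentary",
                                stratum = grp, estimator = est), co)
      expect_equal(g$coefficients$estimate[g$coefficients$term == "mvpa"],
                   truth$b_mvpa - truth$b_sed, tolerance = 1e-8)
    }
  }
})

test_that("pooled OLS path agrees with lm() and sandwich::vcovCL()", {
  skip_if_not_installed("sandwich")
  co <- simulate_study(small_config(seed = 13))
  spec <- model_spec("isotemporal", "wc", drop = "lpa",
                     stratum = "adolescents", estimator = "pooled_ols")
  f <- fit_model(spec, co)
  sub <- co[co$age_group == "adolescents", ]
  sub <- scale_exposures(sub, 10)
  lmf <- lm(wc ~ sedentary + mvpa + wear + sex, data = sub)
  expect_equal(unname(f$coefficients$estimate),
               unname(coef(lmf)[c("(Intercept)", "sedentary", "mvpa",
                                  "wear", "sex")]), tolerance = 1e-10)
  V <- sandwich::vcovCL(lmf, cluster = sub$study_id, type = "HC1")
  expect_equal(f$coefficients$se,
               unname(sqrt(diag(V))[c("(Intercept)", "sedentary", "mvpa",
                                      "wear", "sex")]), tolerance = 1e-8)
})

test_that("random-effects point estimates track a mixed-model oracle", {
  skip_if_not_installed("lme4")
  co <- simulate_study(small_config(seed = 21, n_studies = 10L,
                                    persons_per_study = 120L, study_sd = 3))
  f <- fit_model(model_spec("partition", "wc", stratum = "adolescents"), co)
  sub <- scale_exposures(co[co$age_group == "adolescents", ], 10)
  lmm <- lme4::lmer(wc ~ sedentary + lpa + mvpa + sex + (1 | study_id),
                    data = sub, REML = TRUE)
  fe <- lme4::fixef(lmm)
  b <- f$coefficients
  for (term in c("sedentary", "lpa", "mvpa", "sex"))
    expect_lt(abs(b$estimate[b$term == term] - unname(fe[term])), 0.02)
  # variance components are in the right neighbourhood too
  vc <- as.data.frame(lme4::VarCorr(lmm))
  expect_lt(abs(f$sigma_u - vc$sdcor[vc$grp == "study_id"]), 1)
  expect_lt(abs(f$sigma_e - vc$sdcor[vc$grp == "Residual"]), 0.5)
})

test_that("substitution identity holds on noisy data under both estimators", {
  set.seed(314)
  for (k in 1:10) {
    cfg <- small_config(seed = 1000 + k, n_studies = 8L,
                        persons_per_study = 40L, study_sd = 2)
    co <- simulate_study(cfg)
    for (est in c("pooled_ols", "random_effects_gls")) {
      part <- fit_model(model_spec("partition", "wc", stratum = "adolescents",
                                   estimator = est), co)
      pb <- part$coefficients
      b <- c(sedentary = pb$estimate[pb$term == "sedentary"],
             lpa = pb$estimate[pb$term == "lpa"],
             mvpa = pb$estimate[pb$term == "mvpa"])
      for (dropped in c("sedentary", "lpa", "mvpa")) {
        iso <- fit_model(model_spec("isotemporal", "wc", drop = dropped,
                                    stratum = "adolescents",
                                    estimator = est), co)
        ib <- iso$coefficients
        for (kept in setdiff(c("sedentary", "lpa", "mvpa"), dropped)) {
          expect_lt(abs(ib$estimate[ib$term == kept] -
                          (b[[kept]] - b[[dropped]])), 1e-8)
        }
        # wear-time coefficient equals the dropped behaviour's partition one
        expect_lt(abs(ib$estimate[ib$term == "wear"] - b[[dropped]]), 1e-8)
      }
    }
  }
})

test_that("degenerate panels behave as specified", {
  co <- simulate_study(small_config(seed = 17))
  one <- co[co$study_id == "study01", ]
  expect_error(fit_model(model_spec("partition", "wc",
                                    stratum = "adolescents"), one),
               "at least 2")
  f <- fit_model(model_spec("partition", "wc", stratum = "adolescents",
                            variance = "conventional"), one)
  g <- fit_model(model_spec("partition", "wc", stratum = "adolescents",
                            estimator = "pooled_ols",
                            variance = "conventional"), one)
  expect_equal(f$coefficients$estimate, g$coefficients$estimate,
               tolerance = 1e-10)
  co$wc[co$age_group == "children"][1] <- Inf
  expect_error(fit_model(model_spec("partition", "wc", stratum = "children"),
                         co), "non-finite")
})

test_that("framework produces the full block of fits per outcome-stratum", {
  co <- simulate_study(small_config(seed = 8))
  res <- run_framework(co, "wc", strata = "children")
  fits <- attr(res, "fits")
  expect_length(fits, 7L)
  expect_setequal(unique(res$model_class),
                  c("single", "partition", "isotemporal"))
  # WC outcome never adjusts for itself
  expect_false("wc" %in% res$term)
  # an outcome other than WC does adjust for WC
  co$trig <- 0.9 + 0.01 * co$sex + rnorm(nrow(co), 0, 0.2)
  res2 <- run_framework(co, "trig", strata = "children")
  expect_true("wc" %in% res2$term)
  # three strata x one outcome = 21 fits
  res3 <- run_framework(co, "wc")
  expect_length(attr(res3, "fits"), 21L)
})

test_that("VIF and tolerance follow the closed form", {
  set.seed(42)
  n <- 500
  # orthogonal columns
  X <- cbind("(Intercept)" = 1, a = rep(c(-1, 1), n / 2),
             b = rep(c(-1, -1, 1, 1), n / 4))
  vt <- vif_tolerance(X, c("a", "b"))
  expect_equal(vt$vif, c(1, 1), tolerance = 1e-10)
  expect_equal(vt$tolerance, 1 / vt$vif)

  # correlated pair: VIF = 1/(1-r^2), against a brute-force R^2
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, 0, 0.6)
  X2 <- cbind("(Intercept)" = 1, x = x, y = y)
  r2 <- summary(lm(x ~ y))$r.squared
  vt2 <- vif_tolerance(X2, "x")
  expect_equal(vt2$vif, 1 / (1 - r2), tolerance = 1e-8)

  X3 <- cbind("(Intercept)" = 1, x = x, x2 = x)
  expect_error(vif_tolerance(X3), "rank-deficient")
})

test_that("sex-by-MVPA screen controls size and detects planted interaction", {
  # under the null the rejection rate is near alpha
  set.seed(271)
  alpha_hits <- 0L
  n_rep <- 120L
  for (k in seq_len(n_rep)) {
    cfg <- small_config(n_studies = 8L, persons_per_study = 40L,
                        study_sd = 1)
    cfg$age_group_mix <- c(children = 0, adolescents = 1, older = 0)
    co <- simulate_study(cfg)
    p <- interaction_screen(co, "wc", "adolescents")
    if (p < 0.05) alpha_hits <- alpha_hits + 1L
  }
  rate <- alpha_hits / n_rep
  # binomial 3-SE band around 0.05 with n_rep replicates
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep) + 0.02)

  # a gross planted sex-specific MVPA effect is always detected
  set.seed(99)
  hits <- 0L
  for (k in 1:20) {
    cfg <- small_config(n_studies = 8L, persons_per_study = 40L,
                        study_sd = 0)
    cfg$age_group_mix <- c(children = 0, adolescents = 1, older = 0)
    co <- simulate_cohort(cfg)
    co$wc <- 60 + 2 * co$sex * co$mvpa / 10 + rnorm(nrow(co), 0, 2)
    if (interaction_screen(co, "wc", "adolescents") < 0.05) hits <- hits + 1L
  }
  expect_equal(hits, 20L)

  # degenerate and single-sex strata error
  co <- simulate_study(small_config(seed = 33))
  co$wc <- 60
  expect_error(interaction_screen(co, "wc", "adolescents"), "degenerate")
  co2 <- simulate_study(small_config(seed = 34))
  co2$sex <- 1
  expect_error(interaction_screen(co2, "wc", "adolescents"), "both sexes")
})

test_that("log sensitivity recovers multiplicative effects and guards zeros", {
  cfg <- small_config(seed = 44, n_studies = 8L, persons_per_study = 80L,
                      study_sd = 0)
  cfg$age_group_mix <- c(children = 1, adolescents = 0, older = 0)
  cfg$residual_sd <- c(insulin = 2)
  tm <- true_model("insulin", "children", b_sed = 0.02, b_lpa = -0.005,
                   b_mvpa = -0.12, multiplicative = TRUE)
  co <- simulate_outcomes(simulate_cohort(cfg), tm, cfg)
  spec <- model_spec("partition", "insulin", stratum = "children",
                     covariates = "sex", estimator = "pooled_ols",
                     variance = "conventional")
  f <- log_sensitivity(spec, co)
  expect_true(f$sensitivity)
  b <- f$coefficients
  expect_equal(b$estimate[b$term == "mvpa"], -0.12, tolerance = 0.03)
  # raw and log fits agree in sign on monotone planted data
  raw <- fit_model(spec, co)
  expect_equal(sign(raw$coefficients$estimate[b$term == "mvpa"]),
               sign(b$estimate[b$term == "mvpa"]))

  co$insulin[5] <- 0
  expect_error(log_sensitivity(spec, co), "non-positive")
})
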