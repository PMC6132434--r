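# Three-step substitution modelling framework: single-factor, partition and
# isotemporal substitution models over a multi-study cohort, with random
# study intercepts (feasible GLS, Swamy-Arora-type moments decomposition)
# and cluster-robust (sandwich) variance aggregated by study.

BEHAVIOURS <- c("sedentary", "lpa", "mvpa")

#' Rescale exposures so coefficients are per `unit` minutes/day
#'
#' Divides the behaviour columns (`sedentary`, `lpa`, `mvpa`, `wear`) by
#' `unit`.  With the default unit of 10, downstream regression coefficients
#' represent the reallocation of 10 min/day.  Rescaling is a pure change of
#' units: coefficients scale by `unit` while t-statistics are unchanged.
#'
#' @param table Cohort data frame with exposures in min/day.
#' @param unit Minutes per coefficient unit (default 10).
#' @return The table with rescaled exposure columns and an
#'   `exposure_unit` attribute.
#' @export
scale_exposures <- function(table, unit = 10) {
  if (!is.numeric(unit) || length(unit) != 1L || unit <= 0)
    stop("`unit` must be a single positive number of minutes")
  for (col in intersect(c(BEHAVIOURS, "wear"), names(table)))
    table[[col]] <- table[[col]] / unit
  attr(table, "exposure_unit") <- unit
  table
}

#' Describe one regression of the substitution framework
#'
#' @param model_class `"single"`, `"partition"` or `"isotemporal"`.
#' @param outcome Outcome column name.
#' @param exposure For single-factor models: the one behaviour examined.
#' @param drop For isotemporal models: the behaviour removed from the
#'   design; its time is the source of the modelled reallocation.
#' @param unit Minutes per coefficient unit (default 10).
#' @param stratum Age-group stratum to fit within (`NULL` = all rows).
#' @param covariates Adjustment covariates; defaults to sex, plus waist
#'   circumference unless WC is the outcome.
#' @param include_wear Whether monitor wear time enters the design.  Forced
#'   `TRUE` for isotemporal models (wear is the time-budget constraint) and
#'   `FALSE` for partition models (wear is the sum of the behaviours and
#'   would be collinear).  Default `FALSE` for single-factor models.
#' @param estimator `"random_effects_gls"` (random study intercept via
#'   feasible GLS) or `"pooled_ols"`.
#' @param variance `"cluster_robust"` (sandwich aggregated by study) or
#'   `"conventional"`.
#' @param log_outcome Fit the natural log of the outcome.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(model_class = c("single", "partition", "isotemporal"),
                       outcome, exposure = NULL, drop = NULL, unit = 10,
                       stratum = NULL, covariates = NULL,
                       include_wear = NULL,
                       estimator = c("random_effects_gls", "pooled_ols"),
                       variance = c("cluster_robust", "conventional"),
                       log_outcome = FALSE) {
  model_class <- match.arg(model_class)
  estimator <- match.arg(estimator)
  variance <- match.arg(variance)
  if (is.null(covariates))
    covariates <- c("sex", if (outcome != "wc") "wc")
  if (model_class == "single") {
    if (is.null(exposure) || !exposure %in% BEHAVIOURS)
      stop("single-factor models need `exposure` in ",
           paste(BEHAVIOURS, collapse = "/"))
    if (is.null(include_wear)) include_wear <- FALSE
  }
  if (model_class == "partition") {
    if (!is.null(include_wear) && include_wear)
      stop("partition models exclude wear time: it is the sum of the behaviours")
    include_wear <- FALSE
  }
  if (model_class == "isotemporal") {
    if (is.null(drop) || !drop %in% BEHAVIOURS)
      stop("isotemporal models need `drop` (exactly one of ",
           paste(BEHAVIOURS, collapse = "/"), ")")
    if (!is.null(include_wear) && !include_wear)
      stop("isotemporal models keep wear time constant; `include_wear` is forced TRUE")
    include_wear <- TRUE
  }
  structure(list(model_class = model_class, outcome = outcome,
                 exposure = exposure, drop = drop, unit = unit,
                 stratum = stratum, covariates = covariates,
                 include_wear = include_wear, estimator = estimator,
                 variance = variance, log_outcome = log_outcome),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$model_class, " model for ", x$outcome,
      if (!is.null(x$stratum)) paste0(" [", x$stratum, "]"),
      "; per ", x$unit, " min/day; ", x$estimator, " + ", x$variance, "\n",
      sep = "")
  invisible(x)
}

spec_exposures <- function(spec) {
  ex <- switch(spec$model_class,
               single = spec$exposure,
               partition = BEHAVIOURS,
               isotemporal = setdiff(BEHAVIOURS, spec$drop))
  c(ex, if (spec$include_wear) "wear")
}

#' Build the design matrix for a model specification
#'
#' Selects the stratum, applies complete-case filtering over outcome,
#' exposures and covariates, rescales exposures to `spec$unit`, and
#' assembles the design: intercept + exposures (+ wear time for
#' isotemporal models) + covariates.  Rank deficiency is an error naming
#' the offending columns.
#'
#' @param spec A [model_spec()].
#' @param table Cohort data frame (exposures in min/day).
#' @return List with `y`, `X` (matrix with named columns), `cluster`
#'   (study factor), `exposures` (exposure column names) and `rows`
#'   (row indices of `table` used).
#' @export
build_design <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  rows <- seq_len(nrow(table))
  if (!is.null(spec$stratum)) {
    rows <- rows[as.character(table$age_group) == spec$stratum]
    if (!length(rows)) stop("empty stratum '", spec$stratum, "'")
  }
  exposures <- spec_exposures(spec)
  needed <- c(spec$outcome, exposures, spec$covariates)
  miss <- setdiff(needed, names(table))
  if (length(miss))
    stop("cohort table lacks column(s): ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(table[rows, needed, drop = FALSE])
  rows <- rows[cc]
  if (!length(rows)) stop("no complete cases for outcome '", spec$outcome, "'")
  y <- table[[spec$outcome]][rows]
  if (spec$log_outcome) {
    if (any(y <= 0))
      stop("log transform impossible: non-positive outcome values in rows ",
           paste(utils::head(rows[y <= 0], 10L), collapse = ", "))
    y <- log(y)
  }
  X <- cbind("(Intercept)" = rep(1, length(rows)),
             as.matrix(table[rows, exposures, drop = FALSE]) / spec$unit,
             as.matrix(table[rows, spec$covariates, drop = FALSE]))
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
    stop("rank-deficient design: column(s) ", paste(bad, collapse = ", "),
         " are collinear with the rest")
  }
  cluster <- factor(table$study_id[rows])
  list(y = y, X = X, cluster = cluster, exposures = exposures, rows = rows)
}

# ---- estimation internals --------------------------------------------

group_means <- function(M, g) {
  gm <- rowsum(M, g) / as.vector(table(g))
  gm[as.character(g), , drop = FALSE]
}

# Swamy-Arora-type moments decomposition of the variance components:
# sigma2_e from the within (fixed-effects) residuals, sigma2_u from the
# between (group-means) regression net of the within noise.
swamy_arora <- function(y, X, g) {
  N <- length(y)
  Tg <- as.vector(table(g))
  G <- length(Tg)
  ybar <- group_means(cbind(y), g)[, 1]
  Xbar <- group_means(X, g)
  yw <- y - ybar
  Xw <- X - Xbar
  keep <- colSums(Xw^2) > 1e-9 * N
  K_w <- sum(keep)
  qw <- qr(Xw[, keep, drop = FALSE])
  ew <- qr.resid(qw, yw)
  df_w <- max(N - G - K_w, 1L)
  sigma2_e <- sum(ew^2) / df_w
  u_lev <- !duplicated(g)
  yb <- ybar[u_lev]
  Xb <- Xbar[u_lev, , drop = FALSE]
  qb <- qr(Xb)
  sigma2_u <- 0
  if (G - qb$rank > 0) {
    eb <- qr.resid(qb, yb)
    sigma2_b <- sum(eb^2) / (G - qb$rank)
    sigma2_u <- max(0, sigma2_b - sigma2_e * mean(1 / Tg))
  }
  theta_by_g <- if (sigma2_e <= 0) rep(0, G)
                else 1 - sqrt(sigma2_e / (sigma2_e + Tg * sigma2_u))
  names(theta_by_g) <- levels(g)
  list(sigma2_e = sigma2_e, sigma2_u = sigma2_u, theta = theta_by_g,
       ybar = ybar, Xbar = Xbar)
}

# cluster-robust sandwich with the standard finite-sample scaling
# G/(G-1) * (N-1)/(N-k)
crve <- function(X, e, g, bread) {
  S <- rowsum(X * e, g)
  G <- nrow(S); N <- nrow(X); k <- ncol(X)
  (G / (G - 1)) * ((N - 1) / (N - k)) * bread %*% crossprod(S) %*% bread
}

fit_design <- function(y, X, cluster, estimator, variance) {
  if (!all(is.finite(y))) stop("non-finite outcome values")
  if (length(y) <= ncol(X))
    stop("too few observations (", length(y), ") for ", ncol(X),
         " design columns")
  G <- nlevels(droplevels(cluster))
  if (variance == "cluster_robust" && G < 2L)
    stop("cluster-robust variance needs at least 2 study clusters")
  comps <- NULL
  if (estimator == "random_effects_gls") {
    comps <- swamy_arora(y, X, cluster)
    th <- comps$theta[as.character(cluster)]
    ys <- y - th * comps$ybar
    Xs <- X - th * comps$Xbar
  } else {
    ys <- y; Xs <- X
  }
  qs <- qr(Xs)
  beta <- qr.coef(qs, ys)
  e <- ys - as.vector(Xs %*% beta)
  N <- length(ys); k <- ncol(Xs)
  bread <- chol2inv(chol(crossprod(Xs)))
  V <- if (variance == "cluster_robust") crve(Xs, e, cluster, bread)
       else sum(e^2) / (N - k) * bread
  se <- sqrt(diag(V))
  stat <- beta / se
  normal_ref <- variance == "cluster_robust" ||
    estimator == "random_effects_gls"
  if (normal_ref) {
    p <- 2 * stats::pnorm(-abs(stat))
    q <- stats::qnorm(0.975)
  } else {
    p <- 2 * stats::pt(-abs(stat), df = N - k)
    q <- stats::qt(0.975, df = N - k)
  }
  coef <- data.frame(term = colnames(X), estimate = unname(beta),
                     se = unname(se), ci_low = unname(beta - q * se),
                     ci_high = unname(beta + q * se), p = unname(p),
                     flag = sig_flag(unname(p)))
  list(coefficients = coef, n_obs = N, n_clusters = G,
       sigma_u = if (is.null(comps)) NA_real_ else sqrt(comps$sigma2_u),
       sigma_e = if (is.null(comps)) NA_real_ else sqrt(comps$sigma2_e),
       theta_range = if (is.null(comps)) c(NA_real_, NA_real_)
                     else range(comps$theta),
       vcov = V)
}

sig_flag <- function(p) ifelse(p <= 0.001, "**", ifelse(p < 0.05, "*", ""))

#' Fit one model of the substitution framework
#'
#' Estimates the regression described by a [model_spec()]: random study
#' intercepts by feasible GLS (variance components from a within/between
#' moments decomposition, then quasi-demeaning by the estimated fraction),
#' or pooled OLS; variance either cluster-robust by study or conventional.
#' Two-sided p-values use the normal reference distribution for
#' cluster-robust and GLS fits (study counts are small; no small-sample
#' correction beyond the standard finite-sample scaling is applied).
#'
#' @param spec A [model_spec()].
#' @param table Cohort data frame with exposures in min/day.
#' @return An object of class `isosub_fit`: coefficient table (estimate,
#'   robust SE, 95% CI, p, significance flag with `*` p < 0.05 and `**`
#'   p <= 0.001), observation and cluster counts, variance components,
#'   quasi-demeaning range, and collinearity diagnostics (mean VIF,
#'   minimum tolerance over the exposure terms).
#' @export
fit_model <- function(spec, table) {
  d <- build_design(spec, table)
  fit <- fit_design(d$y, d$X, d$cluster, spec$estimator, spec$variance)
  vt <- vif_tolerance(d$X, d$exposures)
  structure(c(fit, list(spec = spec,
                        mean_vif = mean(vt$vif),
                        min_tolerance = min(vt$tolerance),
                        exposures = d$exposures)),
            class = "isosub_fit")
}

#' @export
print.isosub_fit <- function(x, digits = 3, ...) {
  s <- x$spec
  cat("<isosub_fit> ", s$model_class, " model: ", s$outcome,
      if (!is.null(s$stratum)) paste0(" [", s$stratum, "]"),
      if (s$model_class == "isotemporal") paste0(" (reduce ", s$drop, ")"),
      if (isTRUE(s$log_outcome)) " (log outcome)",
      "\n  ", s$estimator, ", ", s$variance, " variance; n = ", x$n_obs,
      ", clusters = ", x$n_clusters, "\n", sep = "")
  co <- x$coefficients
  co$estimate <- round(co$estimate, digits)
  co$se <- round(co$se, digits)
  co$ci_low <- round(co$ci_low, digits)
  co$ci_high <- round(co$ci_high, digits)
  co$p <- signif(co$p, 2)
  print(co, row.names = FALSE)
  cat("  mean VIF ", round(x$mean_vif, 2), ", min tolerance ",
      round(x$min_tolerance, 2), "\n", sep = "")
  invisible(x)
}

#' Tidy a fitted model into one row per term
#'
#' @param fit An `isosub_fit`.
#' @return Data frame: model_class, outcome, stratum, substitution, term,
#'   beta, se, ci_low, ci_high, p, flag, n, clusters, mean_vif,
#'   min_tolerance.
#' @export
tidy_fit <- function(fit) {
  stopifnot(inherits(fit, "isosub_fit"))
  s <- fit$spec
  co <- fit$coefficients
  data.frame(model_class = s$model_class, outcome = s$outcome,
             stratum = if (is.null(s$stratum)) NA_character_ else s$stratum,
             substitution = if (s$model_class == "isotemporal")
               paste0("reduce_", s$drop) else NA_character_,
             single_exposure = if (s$model_class == "single") s$exposure
               else NA_character_,
             term = co$term, beta = co$estimate, se = co$se,
             ci_low = co$ci_low, ci_high = co$ci_high, p = co$p,
             flag = co$flag, n = fit$n_obs, clusters = fit$n_clusters,
             mean_vif = fit$mean_vif, min_tolerance = fit$min_tolerance)
}

#' Run the full three-step framework
#'
#' For each outcome and age-group stratum, fits the three single-factor
#' models (one behaviour at a time), the partition model (all behaviours,
#' no wear time), and the three isotemporal substitution models (each
#' behaviour dropped in turn while the others and wear time stay in the
#' design) — seven fits per outcome-stratum, mirroring the row blocks of
#' the published tables.  WC is excluded from the covariate set whenever
#' WC is the outcome.
#'
#' @param table Cohort data frame (exposures in min/day).
#' @param outcomes Character vector of outcome columns.
#' @param strata Age-group strata (default all three).
#' @param unit Minutes per coefficient unit.
#' @param estimator,variance Passed to [model_spec()].
#' @return Tidy data frame of all coefficient rows (see [tidy_fit()]);
#'   the fitted objects are attached as attribute `"fits"`.
#' @export
run_framework <- function(table, outcomes,
                          strata = c("children", "adolescents", "older"),
                          unit = 10,
                          estimator = "random_effects_gls",
                          variance = "cluster_robust") {
  fits <- list()
  rows <- list()
  for (oc in outcomes) {
    for (st in strata) {
      specs <- c(
        lapply(BEHAVIOURS, function(b)
          model_spec("single", oc, exposure = b, unit = unit, stratum = st,
                     estimator = estimator, variance = variance)),
        list(model_spec("partition", oc, unit = unit, stratum = st,
                        estimator = estimator, variance = variance)),
        lapply(BEHAVIOURS, function(b)
          model_spec("isotemporal", oc, drop = b, unit = unit, stratum = st,
                     estimator = estimator, variance = variance)))
      for (sp in specs) {
        f <- fit_model(sp, table)
        key <- paste(oc, st, sp$model_class,
                     sp$exposure %||% sp$drop %||% "", sep = ".")
        fits[[key]] <- f
        rows[[key]] <- tidy_fit(f)
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "fits") <- fits
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variance inflation factors and tolerances
#'
#' For each requested column of a design matrix, regresses it on all other
#' non-intercept columns (with intercept) and reports
#' `VIF = 1 / (1 - R^2)` and `tolerance = 1 / VIF`.
#'
#' @param X Design matrix with named columns (an `"(Intercept)"` column is
#'   ignored as a regressand), or the list returned by [build_design()].
#' @param exposures Columns to diagnose; defaults to all non-intercept
#'   columns.
#' @return Data frame `term`, `vif`, `tolerance`.
#' @export
vif_tolerance <- function(X, exposures = NULL) {
  if (is.list(X) && !is.null(X$X)) {
    if (is.null(exposures)) exposures <- X$exposures
    X <- X$X
  }
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  others_all <- setdiff(colnames(X), "(Intercept)")
  if (is.null(exposures)) exposures <- others_all
  if (qr(X)$rank < ncol(X))
    stop("rank-deficient design: VIF is unbounded")
  out <- lapply(exposures, function(j) {
    v <- X[, j]
    Z <- X[, setdiff(others_all, j), drop = FALSE]
    tss <- sum((v - mean(v))^2)
    if (tss <= 0) stop("column '", j, "' is constant; VIF undefined")
    rss <- if (ncol(Z)) sum(qr.resid(qr(cbind(1, Z)), v)^2) else tss
    r2 <- 1 - rss / tss
    if (1 - r2 < 1e-10)
      stop("column '", j, "' is collinear with the remaining columns")
    data.frame(term = j, vif = 1 / (1 - r2), tolerance = 1 - r2)
  })
  do.call(rbind, out)
}

#' Screen for sex-by-MVPA effect modification
#'
#' Augments the partition design for one outcome and stratum with a
#' sex x MVPA product term and returns the two-sided Wald p-value for that
#' term — the screen used to justify pooling the sexes.
#'
#' @param table Cohort data frame.
#' @param outcome Outcome column.
#' @param stratum Age-group stratum.
#' @param unit,estimator,variance As in [model_spec()].
#' @return Scalar p-value, with attributes `estimate` and `se`.
#' @export
interaction_screen <- function(table, outcome, stratum, unit = 10,
                               estimator = "random_effects_gls",
                               variance = "cluster_robust") {
  in_stratum <- as.character(table$age_group) == stratum
  if (length(unique(table$sex[in_stratum])) < 2L)
    stop("interaction screen needs both sexes in stratum '", stratum, "'")
  spec <- model_spec("partition", outcome, unit = unit, stratum = stratum,
                     estimator = estimator, variance = variance)
  d <- build_design(spec, table)
  if (stats::var(d$y) == 0)
    stop("degenerate fit: outcome is constant in stratum '", stratum, "'")
  X <- cbind(d$X, "sex:mvpa" = d$X[, "sex"] * d$X[, "mvpa"])
  fit <- fit_design(d$y, X, d$cluster, estimator, variance)
  row <- fit$coefficients[fit$coefficients$term == "sex:mvpa", ]
  structure(row$p, estimate = row$estimate, se = row$se)
}

#' Refit a model on the log-transformed outcome
#'
#' Sensitivity analysis for skewed outcomes: refits the specification with
#' the natural log of the outcome; coefficients are then approximate
#' proportional changes per `unit` minutes/day.
#'
#' @param spec A [model_spec()].
#' @param table Cohort data frame.
#' @return An `isosub_fit` with `$sensitivity = TRUE`.
#' @export
log_sensitivity <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  spec$log_outcome <- TRUE
  fit <- fit_model(spec, table)
  fit$sensitivity <- TRUE
  fit
}
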