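# Synthetic multi-study cohort generator.  Emulates the structure of a
# pooled accelerometer database (study clusters, three age groups, daily
# time-use compositions, cardiometabolic outcomes with planted reallocation
# effects) so that the processing and modelling stages can be exercised and
# validated without the access-restricted real data.

# ---- truncated-normal machinery ---------------------------------------

# moments of N(mu, sigma^2) truncated below at 0
tn_moments <- function(mu, sigma) {
  a <- -mu / sigma
  la <- exp(stats::dnorm(a, log = TRUE) -
              stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
  m <- mu + sigma * la
  v <- sigma^2 * (1 + a * la - la^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# parent (mu, sigma) such that the 0-truncated draw has the requested
# mean/sd; keeps the generator's realised group moments on target even for
# behaviours (MVPA) whose mean sits within ~2 SDs of zero
tn_calibrate <- function(target_mean, target_sd) {
  if (target_sd < 0) stop("behaviour SDs must be >= 0")
  if (target_sd == 0) {
    if (target_mean < 0) stop("degenerate behaviour mean below 0 is infeasible")
    return(c(mu = target_mean, sigma = 0))
  }
  if (target_mean <= 0)
    stop("a positive truncated mean is infeasible for target mean ",
         target_mean, " (mean at or below the truncation point)")
  if (target_mean / target_sd > 6)  # truncation numerically irrelevant
    return(c(mu = target_mean, sigma = target_sd))
  obj <- function(p) {
    mo <- tn_moments(p[1], exp(p[2]))
    ((mo[1] - target_mean)^2 + (mo[2] - target_sd)^2) / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  if (fit$value > 1e-8)
    stop("cannot calibrate a 0-truncated normal to mean ", target_mean,
         " and SD ", target_sd)
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtrunc0 <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  lo <- stats::pnorm(0, mu, sigma)
  stats::qnorm(stats::runif(n, lo, 1), mu, sigma)
}

# ---- configuration ----------------------------------------------------

#' Configuration of the synthetic cohort generator
#'
#' Bundles every knob of the simulated multi-study sample.  Defaults mirror
#' the pooled database the generator emulates: 13 study clusters, an age
#' mix of roughly 27% children (< 10 y), 60% adolescents (10 to < 15 y) and
#' 13% older adolescents (>= 15 y), and group behaviour distributions
#' calibrated to the published descriptives ([icad_descriptives()]).  The
#' default cohort size (13 x 154 = 2002) is the scale at which the
#' package's simulation studies are run.
#'
#' Compositions are drawn per person as independent 0-truncated normals for
#' sedentary, LPA and MVPA minutes (moment-calibrated so realised group
#' means/SDs match the configured ones) and wear time is defined as their
#' sum, so the compositional identity sedentary + LPA + MVPA = wear holds
#' exactly.  The configured wear mean/SD are retained for stream scheduling
#' and reporting only.
#'
#' @param n_studies Number of study clusters.
#' @param persons_per_study Persons sampled per study.
#' @param age_group_mix Named proportions over
#'   `c("children", "adolescents", "older")`; must sum to 1.
#' @param behaviours Data frame of per-group behaviour/outcome means and
#'   SDs in the layout of [icad_descriptives()].
#' @param true_model Planted outcome model; see [true_model()] and
#'   [default_true_model()].
#' @param study_intercept_sd Named numeric: SD of the study-level random
#'   intercept per outcome (outcome units).  The source reports no variance
#'   components, so the default (2 cm for WC) is an order-of-magnitude
#'   choice, documented as such.
#' @param residual_sd Optional named numeric of residual SDs per outcome;
#'   when `NULL` the per-group published outcome SD is used.
#' @param n_days Recorded days per person when epoch streams are realised.
#' @param nonwear_blocks Non-wear blocks per simulated day.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return An object of class `sim_config` (a list).
#' @export
sim_config <- function(n_studies = 13L, persons_per_study = 154L,
                       age_group_mix = c(children = 0.27, adolescents = 0.60,
                                         older = 0.13),
                       behaviours = icad_descriptives(),
                       true_model = default_true_model(),
                       study_intercept_sd = c(wc = 2),
                       residual_sd = NULL,
                       n_days = 3L, nonwear_blocks = 1L, seed = NULL) {
  n_studies <- as.integer(n_studies)
  persons_per_study <- as.integer(persons_per_study)
  if (n_studies < 1L || persons_per_study < 1L)
    stop("need at least one study and one person per study")
  if (abs(sum(age_group_mix) - 1) > 1e-8)
    stop("`age_group_mix` proportions must sum to 1")
  if (!all(c("children", "adolescents", "older") %in% names(age_group_mix)))
    stop("`age_group_mix` must name children, adolescents and older")
  structure(list(n_studies = n_studies, persons_per_study = persons_per_study,
                 age_group_mix = age_group_mix, behaviours = behaviours,
                 true_model = true_model,
                 study_intercept_sd = study_intercept_sd,
                 residual_sd = residual_sd, n_days = as.integer(n_days),
                 nonwear_blocks = as.integer(nonwear_blocks), seed = seed),
            class = "sim_config")
}

#' Specify planted outcome effects for the generator
#'
#' One row of the "true model": the linear data-generating process for one
#' outcome in one age group, on the 10-minutes-per-day exposure scale used
#' throughout the modelling framework,
#' `y = intercept + b_sed*S/10 + b_lpa*L/10 + b_mvpa*M/10 +
#'  sex_effect*male + wc_effect*WC + study intercept + residual`.
#' Under this parameterisation the planted effect of reallocating
#' 10 min/day from behaviour k to behaviour j is `b_j - b_k`.
#'
#' @param outcome Outcome column name (`"wc"`, `"sbp"`, `"hdl"`, `"ldl"`,
#'   `"trig"`, `"insulin"`, `"glucose"`).
#' @param age_group One of `"children"`, `"adolescents"`, `"older"`.
#' @param b_sed,b_lpa,b_mvpa Outcome units per 10 min/day.
#' @param sex_effect Additive effect of male sex (sex coded 0 = female,
#'   1 = male).
#' @param wc_effect Additive effect per cm of waist circumference (ignored,
#'   and required to be 0, when the outcome is WC itself).
#' @param intercept Fixed intercept; `NA` (default) derives it so the group
#'   outcome mean matches the configured descriptive target.
#' @param multiplicative If `TRUE` the linear predictor acts on the log
#'   scale and the outcome is its exponential — used to emulate skewed
#'   outcomes such as insulin.
#' @return One-row data frame; rows may be stacked with `rbind()`.
#' @export
true_model <- function(outcome, age_group, b_sed, b_lpa, b_mvpa,
                       sex_effect = 0, wc_effect = 0, intercept = NA_real_,
                       multiplicative = FALSE) {
  if (outcome == "wc" && wc_effect != 0)
    stop("WC cannot be a covariate of itself")
  data.frame(outcome = outcome, age_group = age_group,
             intercept = intercept, b_sed = b_sed, b_lpa = b_lpa,
             b_mvpa = b_mvpa, sex_effect = sex_effect,
             wc_effect = wc_effect, multiplicative = multiplicative)
}

#' Default planted effects: published waist-circumference coefficients
#'
#' The default true model plants, per age group, the published
#' partition-model coefficients for waist circumference, with `b_mvpa`
#' anchored so that the implied MVPA-for-sedentary substitution effect
#' `b_mvpa - b_sed` equals the published isotemporal estimate exactly
#' (-0.287, -0.589 and -0.814 cm per 10 min/day in children, adolescents
#' and older adolescents).  A 1.5 cm male-female WC difference is planted
#' as a plausible sex effect.
#'
#' @return Data frame of [true_model()] rows.
#' @export
default_true_model <- function() {
  rbind(
    true_model("wc", "children", b_sed = 0.044, b_lpa = -0.014,
               b_mvpa = 0.044 - 0.287, sex_effect = 1.5),
    true_model("wc", "adolescents", b_sed = 0.035, b_lpa = -0.012,
               b_mvpa = 0.035 - 0.589, sex_effect = 1.5),
    true_model("wc", "older", b_sed = -0.125, b_lpa = -0.153,
               b_mvpa = -0.125 - 0.814, sex_effect = 1.5))
}

# ---- cohort -----------------------------------------------------------

#' Simulate a multi-study cohort of daily time-use compositions
#'
#' Draws persons across study clusters and age groups, then a daily
#' composition (sedentary, LPA, MVPA minutes) per person from 0-truncated
#' normals calibrated to the configured group means/SDs.  Wear time is the
#' sum of the three components.  Ages are uniform within each group's
#' range; sex is Bernoulli(0.5) coded 0 = female, 1 = male.
#'
#' @param config A [sim_config()].
#' @return Data frame: `person_id`, `study_id`, `age`, `age_group`, `sex`,
#'   `sedentary`, `lpa`, `mvpa`, `wear` (min/day).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_studies * config$persons_per_study
  groups <- c("children", "adolescents", "older")
  g <- sample(groups, n, replace = TRUE,
              prob = config$age_group_mix[groups])
  beh <- config$behaviours
  rownames(beh) <- beh$age_group
  age <- stats::runif(n, beh[g, "age_min"], beh[g, "age_max"])
  comp <- matrix(NA_real_, n, 3,
                 dimnames = list(NULL, c("sedentary", "lpa", "mvpa")))
  for (grp in groups) {
    idx <- which(g == grp)
    if (!length(idx)) next
    for (b in c("sedentary", "lpa", "mvpa")) {
      par <- tn_calibrate(beh[grp, paste0(b, "_mean")],
                          beh[grp, paste0(b, "_sd")])
      comp[idx, b] <- rtrunc0(length(idx), par["mu"], par["sigma"])
    }
  }
  data.frame(
    person_id = sprintf("p%05d", seq_len(n)),
    study_id = sprintf("study%02d", rep(seq_len(config$n_studies),
                                        each = config$persons_per_study)),
    age = age,
    age_group = factor(g, levels = groups),
    sex = stats::rbinom(n, 1, 0.5),
    sedentary = comp[, "sedentary"],
    lpa = comp[, "lpa"],
    mvpa = comp[, "mvpa"],
    wear = rowSums(comp))
}

#' Add simulated cardiometabolic outcomes to a cohort
#'
#' Applies the planted [true_model()] per outcome and age group: fixed
#' behaviour, sex and (for non-WC outcomes) WC effects, a study-level
#' random intercept, and an i.i.d. residual.  WC is generated first so it
#' can serve as a covariate for other outcomes.  When a model row is
#' `multiplicative` the linear predictor is built on the log scale from
#' log-scale targets and exponentiated, producing a right-skewed outcome.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param true_model Data frame of [true_model()] rows (default:
#'   `config$true_model`).
#' @param config A [sim_config()]; supplies variance components and the
#'   descriptive targets used to derive unspecified intercepts.
#' @param seed Optional seed applied before drawing random components.
#' @return `cohort` with one extra column per simulated outcome.
#' @export
simulate_outcomes <- function(cohort, true_model = NULL,
                              config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(true_model)) true_model <- config$true_model
  if (!is.null(seed)) set.seed(seed)
  beh <- config$behaviours
  rownames(beh) <- beh$age_group
  studies <- unique(cohort$study_id)
  outcomes <- unique(true_model$outcome)
  outcomes <- c(intersect("wc", outcomes), setdiff(outcomes, "wc"))
  for (oc in outcomes) {
    sd_u <- unname(config$study_intercept_sd[oc])
    if (is.null(sd_u) || length(sd_u) != 1L || is.na(sd_u)) sd_u <- 0
    u <- stats::rnorm(length(studies), 0, sd_u)
    names(u) <- studies
    y <- rep(NA_real_, nrow(cohort))
    for (grp in unique(as.character(cohort$age_group))) {
      tm <- true_model[true_model$outcome == oc &
                         true_model$age_group == grp, , drop = FALSE]
      if (!nrow(tm))
        stop("no true-model row for outcome '", oc, "' in group '", grp, "'")
      tm <- tm[1, ]
      idx <- which(cohort$age_group == grp)
      sd_e <- unname(config$residual_sd[oc])
      if (is.null(sd_e) || length(sd_e) != 1L || is.na(sd_e))
        sd_e <- beh[grp, paste0(oc, "_sd")]
      if (tm$multiplicative) sd_e <- sd_e / beh[grp, paste0(oc, "_mean")]
      target <- beh[grp, paste0(oc, "_mean")]
      if (tm$multiplicative) target <- log(target)
      uses_wc <- oc != "wc" && tm$wc_effect != 0
      if (uses_wc && is.null(cohort$wc))
        stop("true model for '", oc, "' needs WC as a covariate but the ",
             "cohort has no simulated WC")
      a <- tm$intercept
      if (is.na(a)) {
        a <- target -
          tm$b_sed * beh[grp, "sedentary_mean"] / 10 -
          tm$b_lpa * beh[grp, "lpa_mean"] / 10 -
          tm$b_mvpa * beh[grp, "mvpa_mean"] / 10 -
          tm$sex_effect * 0.5 -
          (if (uses_wc) tm$wc_effect * beh[grp, "wc_mean"] else 0)
      }
      eta <- a +
        tm$b_sed * cohort$sedentary[idx] / 10 +
        tm$b_lpa * cohort$lpa[idx] / 10 +
        tm$b_mvpa * cohort$mvpa[idx] / 10 +
        tm$sex_effect * cohort$sex[idx] +
        (if (uses_wc) tm$wc_effect * cohort$wc[idx] else 0) +
        u[cohort$study_id[idx]] +
        stats::rnorm(length(idx), 0, sd_e)
      y[idx] <- if (tm$multiplicative) exp(eta) else eta
    }
    cohort[[oc]] <- y
  }
  cohort
}

#' Simulate a complete cohort with outcomes
#'
#' Convenience wrapper: [simulate_cohort()] followed by
#' [simulate_outcomes()], sharing one RNG stream seeded from
#' `config$seed`.
#'
#' @inheritParams simulate_cohort
#' @return Cohort data frame with outcome columns.
#' @export
simulate_study <- function(config = sim_config()) {
  cohort <- simulate_cohort(config)
  simulate_outcomes(cohort, config$true_model, config)
}

# ---- epoch stream realisation ----------------------------------------

#' Realise a daily composition as a 60-s epoch stream
#'
#' Emits one recorded day whose processed summary recovers the requested
#' composition exactly: `sedentary`, `lpa` and `mvpa` wear minutes (counts
#' drawn uniformly inside each intensity band, sedentary counts kept >= 1
#' so no zero runs occur during wear) arranged in randomised bouts, plus
#' zero-count non-wear blocks.  Each non-wear block must be at least 60 min
#' so the non-wear scan recognises it, and blocks are separated by at least
#' 3 wear minutes so the 2-min interruption allowance cannot bridge them.
#'
#' @param sedentary,lpa,mvpa Wear minutes per intensity (non-negative
#'   integers).
#' @param nonwear Integer vector of non-wear block lengths in minutes
#'   (possibly empty); each must be >= 60.
#' @param thresholds An [intensity_thresholds()].
#' @param person_id,date Identity of the emitted stream.
#' @param bout_length Approximate bout length in minutes used when
#'   shuffling wear epochs (default 10).
#' @param mvpa_max Upper bound for simulated MVPA counts (cpm).
#' @return An [epoch_series()] starting at `date` 00:00 UTC.
#' @export
realize_epoch_stream <- function(sedentary, lpa, mvpa, nonwear = integer(0),
                                 thresholds = intensity_thresholds(),
                                 person_id = "p1", date = "2005-03-01",
                                 bout_length = 10L, mvpa_max = 8000) {
  comp <- c(sedentary = sedentary, lpa = lpa, mvpa = mvpa)
  if (any(comp < 0) || any(comp != round(comp)))
    stop("composition minutes must be non-negative integers")
  nonwear <- as.integer(nonwear)
  if (any(nonwear < 60L))
    stop("each non-wear block must be at least 60 min to be detectable")
  wear <- sum(comp)
  total <- wear + sum(nonwear)
  if (total > 1440L)
    stop("composition plus non-wear exceeds 24 h (", total, " min)")
  if (length(nonwear) > 1L && wear < 3L * (length(nonwear) - 1L))
    stop("not enough wear time to separate ", length(nonwear),
         " non-wear blocks by 3 min each")
  if (thresholds$sedentary_max < 1)
    stop("stream realisation needs a sedentary band containing counts >= 1")
  # wear epochs in shuffled bouts
  labels <- rep(names(comp), comp)
  if (length(labels)) {
    bouts <- split(labels, ceiling(seq_along(labels) / bout_length))
    labels <- unlist(bouts[sample.int(length(bouts))], use.names = FALSE)
  }
  counts <- numeric(length(labels))
  counts[labels == "sedentary"] <-
    sample(seq(1L, thresholds$sedentary_max), sum(labels == "sedentary"),
           replace = TRUE)
  counts[labels == "lpa"] <-
    sample(seq(thresholds$sedentary_max + 1L, thresholds$light_max),
           sum(labels == "lpa"), replace = TRUE)
  counts[labels == "mvpa"] <-
    sample(seq(thresholds$light_max + 1L, mvpa_max),
           sum(labels == "mvpa"), replace = TRUE)
  # split wear into segments around the non-wear blocks: interior gaps >= 3
  nb <- length(nonwear)
  if (nb) {
    n_seg <- nb + 1L
    base <- c(0L, rep(3L, max(nb - 1L, 0L)), 0L)[seq_len(n_seg)]
    spare <- wear - sum(base)
    extra <- if (spare > 0) stats::rmultinom(1, spare, rep(1, n_seg))[, 1]
             else rep(0L, n_seg)
    seg <- base + extra
    stream <- numeric(0)
    pos <- 0L
    for (k in seq_len(nb)) {
      stream <- c(stream, counts[seq_len(seg[k]) + pos], rep(0, nonwear[k]))
      pos <- pos + seg[k]
    }
    stream <- c(stream, counts[seq_len(seg[n_seg]) + pos])
  } else stream <- counts
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  epoch_series(person_id, t0 + 60 * (seq_along(stream) - 1), stream, 60L)
}

#' Realise epoch streams for every person in a cohort
#'
#' Rounds each person's composition to whole minutes, schedules the
#' remainder of the day (when >= 60 min) as a single non-wear block, and
#' emits `config$n_days` identical recorded days per person, so processed
#' per-person means equal the rounded compositions.  Compositions are
#' capped at the valid-wear window so the realised days survive wear-time
#' screening.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param config A [sim_config()].
#' @param thresholds An [intensity_thresholds()].
#' @param start_date First recorded day.
#' @return Long data frame `person_id`, `time`, `counts` in the layout
#'   consumed by [process_epochs()].
#' @export
simulate_epoch_data <- function(cohort, config = sim_config(),
                                thresholds = intensity_thresholds(),
                                start_date = "2005-03-01") {
  start <- as.Date(start_date)
  out <- vector("list", nrow(cohort) * config$n_days)
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    comp <- round(c(cohort$sedentary[i], cohort$lpa[i], cohort$mvpa[i]))
    if (sum(comp) > 960) comp <- round(comp * 960 / sum(comp))
    while (sum(comp) > 960) comp[which.max(comp)] <- comp[which.max(comp)] - 1
    if (sum(comp) < 600) comp[1] <- comp[1] + (600 - sum(comp))
    slack <- 1440 - sum(comp)
    blocks <- integer(0)
    if (slack >= 60 && config$nonwear_blocks >= 1L) {
      nb <- min(config$nonwear_blocks, slack %/% 60L)
      blocks <- rep(slack %/% nb, nb)
      blocks[1] <- blocks[1] + slack - sum(blocks)
    }
    for (d in seq_len(config$n_days)) {
      es <- realize_epoch_stream(comp[1], comp[2], comp[3], blocks,
                                 thresholds, cohort$person_id[i],
                                 as.character(start + d - 1L))
      k <- k + 1L
      out[[k]] <- data.frame(person_id = es$person_id,
                             time = es$data$time, counts = es$data$counts)
    }
  }
  do.call(rbind, out[seq_len(k)])
}
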