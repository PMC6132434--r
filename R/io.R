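# File plumbing and validation: comma-delimited UTF-8 tables with fixed,
# documented column orders, plus the end-to-end pipeline driver.

EPOCH_COLS <- c("person_id", "time", "counts")
DAY_COLS <- c("person_id", "date", "wear_minutes", "sedentary_minutes",
              "lpa_minutes", "mvpa_minutes", "total_counts", "valid")
PERSON_COLS <- c("person_id", "n_valid_days", "mean_wear", "mean_sedentary",
                 "mean_lpa", "mean_mvpa", "cpm")

#' Read an epoch-level count file
#'
#' Expects CSV columns `person_id`, `time` (ISO-8601), `counts`.
#'
#' @param path File path.
#' @return Data frame with `time` parsed as UTC `POSIXct`.
#' @export
read_epoch_file <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(EPOCH_COLS, names(df))
  if (length(miss))
    stop("epoch file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df$time <- parse_epoch_time(df$time)
  df[EPOCH_COLS]
}

#' Write epoch, day-record or person-summary tables
#'
#' Plain CSV writers with the package's fixed column orders.
#' @param x Table to write.
#' @param path Destination path.
#' @name io_writers
NULL

#' @rdname io_writers
#' @export
write_epoch_file <- function(x, path) {
  x$time <- format_ts(x$time)
  utils::write.csv(x[EPOCH_COLS], path, row.names = FALSE, quote = FALSE)
}

#' @rdname io_writers
#' @export
write_day_records <- function(x, path) {
  utils::write.csv(x[DAY_COLS], path, row.names = FALSE, quote = FALSE)
}

#' @rdname io_writers
#' @export
write_person_summaries <- function(x, path) {
  utils::write.csv(x[PERSON_COLS], path, row.names = FALSE, quote = FALSE)
}

#' Assign the analysis age groups
#'
#' Children are below 10 years, adolescents from 10 to below 15, older
#' adolescents 15 and above.
#'
#' @param age Ages in years.
#' @return Factor with levels `children`, `adolescents`, `older`.
#' @export
assign_age_group <- function(age) {
  cut(age, breaks = c(-Inf, 10, 15, Inf), right = FALSE,
      labels = c("children", "adolescents", "older"))
}

#' Merge phenotypes with activity summaries into a modelling cohort
#'
#' Joins the phenotype table and the per-person activity summaries on
#' `person_id`, assigns age groups, screens ages to the 4-18 year analysis
#' range, and checks the compositional identity sedentary + LPA + MVPA =
#' wear.  Duplicate person ids are an error; other problems exclude the
#' person and are reported, not fatal.
#'
#' @param phenotypes Data frame with `person_id`, `study_id`, `age`, `sex`
#'   and outcome columns.
#' @param summaries Per-person summaries from [process_epochs()] /
#'   [summarize_person()].
#' @param tol Tolerance (minutes) for the compositional identity.
#' @return List with `cohort` (modelling table: exposures renamed to
#'   `sedentary`, `lpa`, `mvpa`, `wear`) and `issues` (data frame of
#'   excluded person ids and reasons; zero rows when clean).
#' @export
validate_inputs <- function(phenotypes, summaries, tol = 1) {
  for (nm in c("person_id", "study_id", "age", "sex"))
    if (!nm %in% names(phenotypes))
      stop("phenotype table lacks column '", nm, "'")
  if (anyDuplicated(phenotypes$person_id))
    stop("duplicate person_id in phenotype table: ",
         phenotypes$person_id[duplicated(phenotypes$person_id)][1])
  if (anyDuplicated(summaries$person_id))
    stop("duplicate person_id in summary table: ",
         summaries$person_id[duplicated(summaries$person_id)][1])
  issues <- list()
  note <- function(id, why)
    issues[[length(issues) + 1L]] <<- data.frame(person_id = id, issue = why)
  no_summary <- setdiff(phenotypes$person_id, summaries$person_id)
  for (id in no_summary) note(id, "no valid accelerometer summary")
  m <- merge(phenotypes, summaries, by = "person_id", sort = FALSE)
  bad_age <- m$age < 4 | m$age > 18
  for (id in m$person_id[bad_age])
    note(id, "age outside the 4-18 year analysis range")
  mism <- abs(m$mean_sedentary + m$mean_lpa + m$mean_mvpa - m$mean_wear) > tol
  for (id in m$person_id[mism & !bad_age])
    note(id, "intensity minutes do not sum to wear time")
  keep <- !bad_age & !mism
  cohort <- m[keep, , drop = FALSE]
  cohort$age_group <- assign_age_group(cohort$age)
  nm <- names(cohort)
  nm[nm == "mean_sedentary"] <- "sedentary"
  nm[nm == "mean_lpa"] <- "lpa"
  nm[nm == "mean_mvpa"] <- "mvpa"
  nm[nm == "mean_wear"] <- "wear"
  names(cohort) <- nm
  rownames(cohort) <- NULL
  issues <- if (length(issues)) do.call(rbind, issues)
            else data.frame(person_id = character(0), issue = character(0))
  list(cohort = cohort, issues = issues)
}

#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param simulate If `TRUE` the pipeline generates its own inputs with the
#'   synthetic module; otherwise `epoch_path` and `phenotype_path` must
#'   point at existing files.
#' @param epoch_path,phenotype_path Input files for non-simulated runs.
#' @param sim Simulation settings: a [sim_config()].
#' @param outcomes Outcomes to model.
#' @param strata Age-group strata to model.
#' @param unit,estimator,variance Modelling settings.
#' @param epoch_length,target_epoch,min_window,max_interrupt,min_wear,max_wear,min_valid_days
#'   Epoch-processing settings.
#' @param thresholds An [intensity_thresholds()].
#' @param seed Pipeline seed (overrides `sim$seed`).
#' @param verbose Emit per-stage messages.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE, epoch_path = NULL,
                            phenotype_path = NULL, sim = sim_config(),
                            outcomes = "wc",
                            strata = c("children", "adolescents", "older"),
                            unit = 10, estimator = "random_effects_gls",
                            variance = "cluster_robust",
                            epoch_length = 60L, target_epoch = 60L,
                            min_window = 60L, max_interrupt = 2L,
                            min_wear = 600, max_wear = 960,
                            min_valid_days = 1L,
                            thresholds = intensity_thresholds(),
                            seed = NULL, verbose = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `sim` and `thresholds` blocks map onto [sim_config()] and
#' [intensity_thresholds()].
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$thresholds))
    raw$thresholds <- do.call(intensity_thresholds, raw$thresholds)
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(pipeline_config, raw)
}

#' Run the full pipeline: simulate, process, fit, report
#'
#' Executes the configured stages in order, writing every intermediate
#' artifact to `out_dir` as headed CSV (plus the rendered text tables) and
#' logging seed, stage and row counts.  Identical configuration and seed
#' give identical outputs.
#'
#' @param config A [pipeline_config()] or path to a YAML file.
#' @param seed Optional seed overriding the configured one.
#' @return Invisibly, a list with the cohort, tidy results, relative
#'   effects and output paths.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- seed
  say <- function(...) if (isTRUE(config$verbose)) message("[isosub] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  out <- function(name) file.path(config$out_dir, name)

  if (isTRUE(config$simulate)) {
    sim <- config$sim
    if (!is.null(config$seed)) sim$seed <- config$seed
    say("simulate: seed = ", sim$seed %||% "none", ", ", sim$n_studies,
        " studies x ", sim$persons_per_study, " persons")
    cohort0 <- simulate_cohort(sim)
    cohort0 <- simulate_outcomes(cohort0, sim$true_model, sim)
    epochs <- simulate_epoch_data(cohort0, sim, config$thresholds)
    phenotypes <- cohort0[, setdiff(names(cohort0),
                                    c(BEHAVIOURS, "wear", "age_group"))]
    paths$epochs <- out("epochs.csv")
    write_epoch_file(epochs, paths$epochs)
    paths$phenotypes <- out("phenotypes.csv")
    utils::write.csv(phenotypes, paths$phenotypes, row.names = FALSE,
                     quote = FALSE)
    say("simulate: wrote ", nrow(epochs), " epochs, ", nrow(phenotypes),
        " phenotype rows")
  } else {
    if (is.null(config$epoch_path) || is.null(config$phenotype_path))
      stop("non-simulated runs need `epoch_path` and `phenotype_path`")
    if (!file.exists(config$epoch_path))
      stop("epoch input not found: ", config$epoch_path)
    if (!file.exists(config$phenotype_path))
      stop("phenotype input not found: ", config$phenotype_path)
    epochs <- read_epoch_file(config$epoch_path)
    phenotypes <- utils::read.csv(config$phenotype_path,
                                  stringsAsFactors = FALSE)
  }

  processed <- process_epochs(epochs, config$epoch_length,
                              config$target_epoch, config$thresholds,
                              config$min_window, config$max_interrupt,
                              config$min_wear, config$max_wear,
                              config$min_valid_days)
  if (is.null(processed$persons))
    stop("processing stage produced no valid person summaries")
  paths$days <- out("day_records.csv")
  write_day_records(processed$days, paths$days)
  paths$persons <- out("person_summaries.csv")
  write_person_summaries(processed$persons, paths$persons)
  say("process: ", nrow(processed$days), " person-days -> ",
      nrow(processed$persons), " person summaries")

  val <- validate_inputs(phenotypes, processed$persons)
  say("validate: ", nrow(val$cohort), " persons kept, ",
      nrow(val$issues), " issues")
  if (nrow(val$issues)) {
    paths$issues <- out("validation_issues.csv")
    utils::write.csv(val$issues, paths$issues, row.names = FALSE,
                     quote = FALSE)
  }
  paths$cohort <- out("cohort.csv")
  utils::write.csv(val$cohort, paths$cohort, row.names = FALSE, quote = FALSE)

  outcomes <- intersect(config$outcomes, names(val$cohort))
  skipped <- setdiff(config$outcomes, outcomes)
  for (oc in skipped)
    warning("outcome '", oc, "' missing from cohort; skipped", call. = FALSE)
  if (!length(outcomes)) stop("no requested outcome present in the cohort")
  strata <- intersect(config$strata,
                      as.character(unique(val$cohort$age_group)))
  results <- run_framework(val$cohort, outcomes, strata, config$unit,
                           config$estimator, config$variance)
  paths$results <- out("results.csv")
  utils::write.csv(results, paths$results, row.names = FALSE, quote = FALSE)
  say("fit: ", length(attr(results, "fits")), " models, ",
      nrow(results), " coefficient rows")

  means <- do.call(rbind, lapply(outcomes, function(oc) {
    do.call(rbind, lapply(strata, function(st) {
      rows <- val$cohort$age_group == st & !is.na(val$cohort[[oc]])
      data.frame(outcome = oc, stratum = st,
                 stratum_mean = mean(val$cohort[[oc]][rows]))
    }))
  }))
  rel <- relative_effects_table(results, means)
  paths$relative <- out("relative_effects.csv")
  utils::write.csv(rel, paths$relative, row.names = FALSE, quote = FALSE)
  tables <- unlist(lapply(outcomes, function(oc)
    c(unclass(render_table(results, oc)), "")))
  paths$tables <- out("tables.txt")
  writeLines(tables, paths$tables)
  say("report: wrote relative effects and tables")

  invisible(list(cohort = val$cohort, results = results,
                 relative_effects = rel, issues = val$issues, paths = paths))
}
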