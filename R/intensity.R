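#' Intensity cut-points for 60-s count epochs
#'
#' Counts-per-minute thresholds separating sedentary time, light physical
#' activity (LPA) and moderate-to-vigorous physical activity (MVPA).  The
#' defaults are the Evenson youth cut-points (sedentary <= 100 cpm, MVPA
#' >= 2296 cpm).  Band edges are inclusive on the upper side: an epoch is
#' sedentary iff counts <= `sedentary_max`, LPA iff `sedentary_max` < counts
#' <= `light_max`, MVPA iff counts > `light_max`.
#'
#' @param sedentary_max Upper edge of the sedentary band (counts/min).
#' @param light_max Upper edge of the LPA band (counts/min).
#' @return An object of class `intensity_thresholds`.
#' @export
intensity_thresholds <- function(sedentary_max = 100, light_max = 2295) {
  if (!(sedentary_max >= 0 && sedentary_max < light_max))
    stop("need 0 <= sedentary_max < light_max")
  structure(list(sedentary_max = sedentary_max, light_max = light_max),
            class = "intensity_thresholds")
}

#' @export
print.intensity_thresholds <- function(x, ...) {
  cat("<intensity_thresholds> sedentary <=", x$sedentary_max,
      "| LPA <=", x$light_max, "| MVPA >", x$light_max, "cpm\n")
  invisible(x)
}

#' Classify 60-s epoch counts into intensity bands
#'
#' @param counts Non-negative counts per 60-s epoch (vectorised).
#' @param thresholds An [intensity_thresholds()].
#' @return Factor with levels `sedentary`, `lpa`, `mvpa`.
#' @export
#' @examples
#' classify_counts(c(0, 100, 101, 2295, 2296), intensity_thresholds())
classify_counts <- function(counts, thresholds = intensity_thresholds()) {
  stopifnot(inherits(thresholds, "intensity_thresholds"))
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  out <- ifelse(counts <= thresholds$sedentary_max, "sedentary",
                ifelse(counts <= thresholds$light_max, "lpa", "mvpa"))
  factor(out, levels = c("sedentary", "lpa", "mvpa"))
}

#' Summarise an epoch series into day records
#'
#' Applies non-wear detection per calendar day, classifies the remaining
#' wear epochs by intensity, and tallies minutes.  A day is valid when its
#' wear time lies between `min_wear` and `max_wear` minutes inclusive; the
#' upper cap screens out overnight wear.
#'
#' @param series An [epoch_series()] at 60-s epochs (coarser input is
#'   reintegrated first; finer raises the usual alignment errors).
#' @param thresholds An [intensity_thresholds()].
#' @param min_window,max_interrupt Passed to [detect_nonwear()].
#' @param min_wear Minimum valid wear time, minutes/day (default 600 = 10 h).
#' @param max_wear Maximum valid wear time, minutes/day (default 960 = 16 h).
#' @return Data frame with one row per recorded day: `person_id`, `date`,
#'   `wear_minutes`, `sedentary_minutes`, `lpa_minutes`, `mvpa_minutes`,
#'   `total_counts` (counts accumulated during wear), `valid`.  The three
#'   intensity columns always sum exactly to `wear_minutes`.
#' @export
summarize_days <- function(series, thresholds = intensity_thresholds(),
                           min_window = 60L, max_interrupt = 2L,
                           min_wear = 600, max_wear = 960) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$epoch_length != 60L) series <- reintegrate(series, 60L)
  empty <- data.frame(person_id = character(0), date = as.Date(character(0)),
                      wear_minutes = numeric(0), sedentary_minutes = numeric(0),
                      lpa_minutes = numeric(0), mvpa_minutes = numeric(0),
                      total_counts = numeric(0), valid = logical(0))
  if (!nrow(series$data)) return(empty)
  day <- as.Date(series$data$time, tz = "UTC")
  rows <- lapply(split(seq_len(nrow(series$data)), day), function(d) {
    cnt <- series$data$counts[d]
    nw <- nonwear_flag(cnt, min_window, max_interrupt)
    wear_cnt <- cnt[!nw]
    band <- classify_counts(wear_cnt, thresholds)
    tab <- table(band)
    wear <- length(wear_cnt)
    data.frame(person_id = series$person_id,
               date = as.Date(series$data$time[d[1]], tz = "UTC"),
               wear_minutes = wear,
               sedentary_minutes = as.numeric(tab[["sedentary"]]),
               lpa_minutes = as.numeric(tab[["lpa"]]),
               mvpa_minutes = as.numeric(tab[["mvpa"]]),
               total_counts = sum(wear_cnt),
               valid = wear >= min_wear && wear <= max_wear)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average valid days into a per-person activity summary
#'
#' @param days Day records as returned by [summarize_days()] (one person).
#' @param min_valid_days Minimum number of valid days required for a summary
#'   (default 1).
#' @return One-row data frame (`person_id`, `n_valid_days`, `mean_wear`,
#'   `mean_sedentary`, `mean_lpa`, `mean_mvpa`, `cpm`) or `NULL` when fewer
#'   than `min_valid_days` valid days are available.  `cpm` is the per-day
#'   ratio of wear counts to wear minutes, averaged over valid days.
#' @export
summarize_person <- function(days, min_valid_days = 1L) {
  if (!nrow(days)) return(NULL)
  if (length(unique(days$person_id)) != 1L)
    stop("`days` must belong to a single person")
  v <- days[days$valid, , drop = FALSE]
  if (nrow(v) < min_valid_days) return(NULL)
  data.frame(person_id = days$person_id[1],
             n_valid_days = nrow(v),
             mean_wear = mean(v$wear_minutes),
             mean_sedentary = mean(v$sedentary_minutes),
             mean_lpa = mean(v$lpa_minutes),
             mean_mvpa = mean(v$mvpa_minutes),
             cpm = mean(v$total_counts / v$wear_minutes))
}

#' Process a multi-person epoch table into daily and per-person summaries
#'
#' Driver over [reintegrate()], [detect_nonwear()], [summarize_days()] and
#' [summarize_person()] for a long-format epoch table covering many people.
#'
#' @param epochs Data frame with columns `person_id`, `time` (ISO-8601 or
#'   `POSIXct`) and `counts`.
#' @param epoch_length Epoch length of the input stream, seconds.
#' @param target_epoch Epoch length used for analysis (default 60 s).
#' @param thresholds An [intensity_thresholds()].
#' @param min_window,max_interrupt,min_wear,max_wear,min_valid_days
#'   Processing parameters; see [summarize_days()] and [summarize_person()].
#' @return List with elements `days` (all day records) and `persons`
#'   (summaries for people with enough valid days).
#' @export
process_epochs <- function(epochs, epoch_length = 60L, target_epoch = 60L,
                           thresholds = intensity_thresholds(),
                           min_window = 60L, max_interrupt = 2L,
                           min_wear = 600, max_wear = 960,
                           min_valid_days = 1L) {
  stopifnot(all(c("person_id", "time", "counts") %in% names(epochs)))
  days <- list(); persons <- list()
  for (pid in unique(epochs$person_id)) {
    e <- epochs[epochs$person_id == pid, , drop = FALSE]
    es <- epoch_series(pid, e$time, e$counts, epoch_length)
    if (es$epoch_length != target_epoch) es <- reintegrate(es, target_epoch)
    d <- summarize_days(es, thresholds, min_window, max_interrupt,
                        min_wear, max_wear)
    days[[pid]] <- d
    s <- summarize_person(d, min_valid_days)
    if (!is.null(s)) persons[[pid]] <- s
  }
  list(days = if (length(days)) do.call(rbind, c(days, make.row.names = FALSE))
       else NULL,
       persons = if (length(persons))
         do.call(rbind, c(persons, make.row.names = FALSE)) else NULL)
}
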