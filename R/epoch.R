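#' Construct an epoch-level activity count series
#'
#' An `epoch_series` holds one person's time-stamped accelerometer count
#' stream at a fixed epoch length.  Within each calendar day the epochs must
#' be contiguous (spaced exactly `epoch_length` seconds apart); gaps between
#' days are allowed, so a series may span several (possibly non-consecutive)
#' recording days.
#'
#' @param person_id Scalar identifier (character or coercible).
#' @param time Epoch start times: `POSIXct`, or character in ISO-8601
#'   (`"YYYY-MM-DDTHH:MM:SS"` or with a space separator), interpreted as UTC.
#' @param counts Non-negative integer activity counts, one per epoch.
#' @param epoch_length Epoch duration in seconds; a positive divisor of 60.
#'
#' @return An object of class `epoch_series`: a list with elements
#'   `person_id`, `epoch_length` and `data` (a data frame with columns
#'   `time` and `counts`).
#' @seealso [reintegrate()], [detect_nonwear()], [summarize_days()]
#' @export
#' @examples
#' t0 <- as.POSIXct("2005-03-01 08:00:00", tz = "UTC")
#' es <- epoch_series("p1", t0 + seq(0, 59) * 60, rpois(60, 200))
#' es
epoch_series <- function(person_id, time, counts, epoch_length = 60L) {
  if (length(person_id) != 1L) stop("`person_id` must be a single value")
  epoch_length <- as.integer(epoch_length)
  if (is.na(epoch_length) || epoch_length <= 0L || 60L %% epoch_length != 0L)
    stop("`epoch_length` must be a positive divisor of 60 (seconds)")
  time <- parse_epoch_time(time)
  if (anyNA(time)) stop("unparseable timestamps in `time`")
  counts <- as.numeric(counts)
  if (length(counts) != length(time))
    stop("`time` and `counts` must have the same length")
  if (anyNA(counts) || any(counts < 0))
    stop("activity counts must be non-negative and non-missing")
  if (length(time) > 1L) {
    dt <- diff(as.numeric(time))
    if (any(dt <= 0))
      stop("timestamps must be strictly increasing; first violation at ",
           format_ts(time[which(dt <= 0)[1] + 1L]))
    same_day <- as.Date(time[-1L], tz = "UTC") == as.Date(time[-length(time)], tz = "UTC")
    bad <- which(same_day & dt != epoch_length)
    if (length(bad))
      stop("gap in epoch stream within a day: expected ", epoch_length,
           " s spacing before ", format_ts(time[bad[1] + 1L]))
  }
  structure(
    list(person_id = as.character(person_id),
         epoch_length = epoch_length,
         data = data.frame(time = time, counts = counts)),
    class = "epoch_series")
}

parse_epoch_time <- function(time) {
  if (inherits(time, "POSIXct")) return(as.POSIXct(as.numeric(time),
                                                   origin = "1970-01-01", tz = "UTC"))
  time <- gsub("T", " ", as.character(time), fixed = TRUE)
  as.POSIXct(time, tz = "UTC")
}

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' @export
print.epoch_series <- function(x, ...) {
  n <- nrow(x$data)
  cat("<epoch_series> person ", x$person_id, ": ", n, " epochs of ",
      x$epoch_length, " s", sep = "")
  if (n) {
    cat(", ", format_ts(x$data$time[1]), " .. ", format_ts(x$data$time[n]),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Reintegrate an epoch series to a coarser epoch length
#'
#' Sums activity counts of consecutive short epochs into longer ones (the
#' conventional preprocessing step that makes streams collected at, say,
#' 15-s epochs comparable to 60-s processing rules).  Total counts per day
#' are conserved.  Input epochs must align to the target epoch boundaries
#' within each day and cover each target epoch completely; partial or
#' misaligned target windows raise an error rather than being zero-filled,
#' so that missing data cannot masquerade as sedentary time.
#'
#' @param series An [epoch_series()].
#' @param target_epoch Target epoch length in seconds (default 60); must be
#'   a multiple of `series$epoch_length`.
#' @return An `epoch_series` at `target_epoch` resolution.
#' @export
#' @examples
#' t0 <- as.POSIXct("2005-03-01", tz = "UTC")
#' es <- epoch_series("p1", t0 + seq(0, 45, by = 15), c(10, 20, 0, 5),
#'                    epoch_length = 15)
#' reintegrate(es, 60)$data$counts  # 35
reintegrate <- function(series, target_epoch = 60L) {
  stopifnot(inherits(series, "epoch_series"))
  target_epoch <- as.integer(target_epoch)
  if (is.na(target_epoch) || target_epoch <= 0L ||
      target_epoch %% series$epoch_length != 0L)
    stop("`target_epoch` must be a positive multiple of the input epoch length (",
         series$epoch_length, " s)")
  if (target_epoch == series$epoch_length) return(series)
  m <- target_epoch %/% series$epoch_length
  tt <- series$data$time
  if (!length(tt))
    return(epoch_series(series$person_id, tt, numeric(0), target_epoch))
  day <- as.Date(tt, tz = "UTC")
  sod <- as.numeric(tt) - as.numeric(as.POSIXct(day, tz = "UTC"))
  bin <- sod %/% target_epoch
  key <- paste(day, bin)
  misaligned <- which(sod %% series$epoch_length != 0)
  if (length(misaligned))
    stop("epoch timestamps not aligned to the epoch grid at ",
         format_ts(tt[misaligned[1]]))
  # contiguity within a day is guaranteed by the constructor, so each target
  # bin is complete iff it contains exactly m input epochs
  sizes <- table(factor(key, levels = unique(key)))
  if (any(sizes != m)) {
    bad <- names(sizes)[sizes != m][1]
    first <- tt[key == bad][1]
    stop("incomplete ", target_epoch, "-s window (", sizes[bad], "/", m,
         " epochs) starting near ", format_ts(first),
         "; refusing to reintegrate over gaps")
  }
  keep <- !duplicated(key)
  new_time <- as.POSIXct(as.numeric(as.POSIXct(day[keep], tz = "UTC")) +
                           bin[keep] * target_epoch,
                         origin = "1970-01-01", tz = "UTC")
  new_counts <- as.numeric(rowsum(series$data$counts, key, reorder = FALSE))
  epoch_series(series$person_id, new_time, new_counts, target_epoch)
}
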