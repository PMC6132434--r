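#' Detect monitor non-wear periods in a 60-s epoch series
#'
#' Scans each recorded day for periods of at least `min_window` minutes of
#' consecutive zero counts, allowing up to `max_interrupt` minutes of
#' non-zero interruptions inside the period.  A qualifying window must open
#' and close on a zero epoch (an interruption can neither start nor end a
#' non-wear run), and any epoch covered by at least one qualifying window is
#' flagged as non-wear.  There is no ceiling on the magnitude of the
#' interrupting counts.  Days are calendar days in the stream's clock; the
#' scan never crosses midnight.
#'
#' @param series An [epoch_series()] at 60-s epochs.
#' @param min_window Minimum run length in minutes (default 60).
#' @param max_interrupt Maximum number of non-zero epochs tolerated inside a
#'   run (default 2).
#' @return A data frame of wear intervals tiling each day's recorded epochs:
#'   columns `person_id`, `date`, `start`, `end` (end-exclusive `POSIXct`),
#'   `status` (`"wear"`/`"nonwear"`) and `n_epochs`.  Empty series give a
#'   zero-row frame.
#' @export
detect_nonwear <- function(series, min_window = 60L, max_interrupt = 2L) {
  stopifnot(inherits(series, "epoch_series"))
  if (series$epoch_length != 60L)
    stop("non-wear detection requires a 60-s epoch series; call reintegrate() first")
  out <- list()
  if (nrow(series$data)) {
    day <- as.Date(series$data$time, tz = "UTC")
    for (d in split(seq_len(nrow(series$data)), day)) {
      flag <- nonwear_flag(series$data$counts[d], min_window, max_interrupt)
      r <- rle(flag)
      hi <- cumsum(r$lengths)
      lo <- hi - r$lengths + 1L
      tt <- series$data$time[d]
      out[[length(out) + 1L]] <- data.frame(
        person_id = series$person_id,
        date = as.Date(tt[1], tz = "UTC"),
        start = tt[lo],
        end = tt[hi] + 60,
        status = ifelse(r$values, "nonwear", "wear"),
        n_epochs = r$lengths)
    }
  }
  if (!length(out))
    return(data.frame(person_id = character(0), date = as.Date(character(0)),
                      start = as.POSIXct(character(0), tz = "UTC"),
                      end = as.POSIXct(character(0), tz = "UTC"),
                      status = character(0), n_epochs = integer(0)))
  do.call(rbind, out)
}

# Core scan on one day's 60-s count vector.  Marks the union of all windows
# [i, j] with counts[i] == counts[j] == 0, at most `max_interrupt` non-zero
# epochs inside, and length >= min_window.  Only maximal windows matter for
# the union, and a maximal window starts at a zero whose predecessor is
# non-zero (or at position 1), so the scan loops over those starts only.
nonwear_flag <- function(counts, min_window = 60L, max_interrupt = 2L) {
  n <- length(counts)
  flag <- logical(n)
  if (!n) return(flag)
  z <- counts == 0
  if (!any(z)) return(flag)
  idx <- seq_len(n)
  cnz <- cumsum(!z)                       # non-zero epochs up to position
  nz_pos <- idx[!z]
  lz <- cummax(ifelse(z, idx, 0L))        # last zero at or before position
  starts <- idx[z & c(TRUE, !z[-n])]
  for (i in starts) {
    used <- cnz[i]                        # non-zeros strictly before i
    lim <- used + max_interrupt + 1L      # first disallowed non-zero
    j_limit <- if (lim <= length(nz_pos)) nz_pos[lim] - 1L else n
    j <- lz[j_limit]                      # close the run on a zero
    if (j - i + 1L >= min_window) flag[i:j] <- TRUE
  }
  flag
}
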