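# Brute-force oracle for the non-wear scan: enumerate every window that
# starts on a zero epoch, walk forward epoch by epoch counting non-zero
# interruptions, and mark the union of all windows that (i) end on a zero,
# (ii) contain at most `max_interrupt` non-zeros, and (iii) are at least
# `min_window` epochs long.  Deliberately naive and independent of the
# package's single-pass scan.
nonwear_oracle <- function(counts, min_window = 60L, max_interrupt = 2L) {
  n <- length(counts)
  flag <- logical(n)
  for (i in seq_len(n)) {
    if (counts[i] != 0) next
    interrupts <- 0L
    best_end <- i
    j <- i
    while (j <= n) {
      if (counts[j] != 0) {
        interrupts <- interrupts + 1L
        if (interrupts > max_interrupt) break
      } else {
        best_end <- j
      }
      j <- j + 1L
    }
    if (best_end - i + 1L >= min_window) flag[i:best_end] <- TRUE
  }
  flag
}

# random day-length 60-s count vector with tunable zero density
fuzz_counts <- function(n, p_nonzero) {
  nz <- stats::runif(n) < p_nonzero
  counts <- numeric(n)
  counts[nz] <- stats::rpois(sum(nz), 400) + 1
  counts
}

nonwear_runs_status <- function(counts) {
  ifelse(rle(nonwear_oracle(counts))$values, "nonwear", "wear")
}

make_series <- function(counts, person = "p1", date = "2005-03-01") {
  t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  epoch_series(person, t0 + 60 * (seq_along(counts) - 1), counts, 60L)
}
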