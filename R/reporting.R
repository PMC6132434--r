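# Presentation of fitted coefficients: relative effects against stratum
# means and text tables shaped like the published ones.

round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5 + 1e-9) / s
}

#' Relative effect of a coefficient against the stratum outcome mean
#'
#' Expresses an absolute reallocation coefficient as a percentage of the
#' mean outcome in the stratum it was estimated in:
#' `100 * |beta| / stratum_mean`, rounded half-up to one decimal.
#'
#' @param beta Coefficient in outcome units (vectorised).
#' @param stratum_mean Mean outcome in the stratum; must be positive.
#' @return Percentages rounded to one decimal.
#' @export
#' @examples
#' relative_effect(-0.287, 59.1)  # 0.5
#' relative_effect(-0.019, 0.86)  # 2.2
relative_effect <- function(beta, stratum_mean) {
  if (any(!is.finite(stratum_mean)) || any(stratum_mean <= 0))
    stop("`stratum_mean` must be positive")
  round_half_up(100 * abs(beta) / stratum_mean, 1)
}

#' Tabulate relative effects for a set of fitted results
#'
#' Joins tidy isotemporal coefficients with stratum outcome means and adds
#' the relative percentage and a direction label.  For risk markers where
#' lower is better (everything here except HDL-C), a negative coefficient
#' is `favourable`; for HDL-C the sign flips.
#'
#' @param results Tidy results from [run_framework()].
#' @param means Data frame with columns `outcome`, `stratum`,
#'   `stratum_mean` (observed or published stratum outcome means).
#' @return Data frame of isotemporal behaviour terms with `relative_pct`
#'   and `direction`.
#' @export
relative_effects_table <- function(results, means) {
  iso <- results[results$model_class == "isotemporal" &
                   results$term %in% BEHAVIOURS, , drop = FALSE]
  out <- merge(iso, means, by = c("outcome", "stratum"), sort = FALSE)
  out$relative_pct <- relative_effect(out$beta, out$stratum_mean)
  higher_is_better <- out$outcome == "hdl"
  out$direction <- ifelse((out$beta < 0) != higher_is_better,
                          "favourable", "unfavourable")
  out[out$beta == 0, "direction"] <- "null"
  out
}

fmt_cell <- function(beta, lo, hi, flag) {
  if (any(is.na(c(beta, lo, hi)))) return("")
  sprintf("%.3f (%.3f to %.3f)%s", beta, lo, hi, flag)
}

#' Render framework results as a published-style text table
#'
#' One block per age-group stratum with rows in the conventional order —
#' Single, Partition, then the isotemporal substitution rows (Reduce
#' sedentary / Reduce LPA / Reduce MVPA) — and one column per behaviour,
#' cells formatted `beta (low to high)` to three decimals with
#' significance flags.  The dropped behaviour's own cell reads `Dropped`;
#' a missing model class renders as a blank cell with a warning.
#'
#' @param results Tidy results from [run_framework()].
#' @param outcome Outcome to render.
#' @return Character vector of lines, class `substitution_table` (printed
#'   as text).
#' @export
render_table <- function(results, outcome) {
  res <- results[results$outcome == outcome, , drop = FALSE]
  if (!nrow(res)) stop("no results for outcome '", outcome, "'")
  strata <- unique(res$stratum)
  labels <- c(sedentary = "Sedentary", lpa = "LPA", mvpa = "MVPA")
  width <- 30L
  pad <- function(x) formatC(x, width = width, flag = "-")
  lines <- c(sprintf("Outcome: %s (per 10 min/day reallocation)", outcome),
             paste0(formatC("", width = 24L),
                    paste(vapply(labels, pad, ""), collapse = "")))
  cell <- function(sub, term) {
    row <- sub[sub$term == term, , drop = FALSE]
    if (!nrow(row)) return("")
    fmt_cell(row$beta[1], row$ci_low[1], row$ci_high[1], row$flag[1])
  }
  for (st in strata) {
    blk <- res[res$stratum == st, , drop = FALSE]
    n <- unique(blk$n)
    lines <- c(lines, sprintf("%s (n = %s)", st, paste(n, collapse = "/")))
    single <- blk[blk$model_class == "single", , drop = FALSE]
    if (!nrow(single)) warning("no single-factor fits for ", outcome, " / ", st)
    cells <- vapply(names(labels), function(b) {
      s <- single[single$single_exposure == b & single$term == b, , drop = FALSE]
      if (!nrow(s)) "" else fmt_cell(s$beta[1], s$ci_low[1], s$ci_high[1], s$flag[1])
    }, "")
    lines <- c(lines, paste0(formatC("  Single", width = 24L, flag = "-"),
                             paste(vapply(cells, pad, ""), collapse = "")))
    part <- blk[blk$model_class == "partition", , drop = FALSE]
    if (!nrow(part)) warning("no partition fit for ", outcome, " / ", st)
    cells <- vapply(names(labels), function(b) cell(part, b), "")
    lines <- c(lines, paste0(formatC("  Partition", width = 24L, flag = "-"),
                             paste(vapply(cells, pad, ""), collapse = "")))
    lines <- c(lines, "  Isotemporal substitution")
    iso <- blk[blk$model_class == "isotemporal", , drop = FALSE]
    if (!nrow(iso)) warning("no isotemporal fits for ", outcome, " / ", st)
    for (dropped in names(labels)) {
      sub <- iso[iso$substitution == paste0("reduce_", dropped), , drop = FALSE]
      cells <- vapply(names(labels), function(b)
        if (b == dropped) "Dropped" else cell(sub, b), "")
      lines <- c(lines,
                 paste0(formatC(paste0("    Reduce ", labels[[dropped]]),
                                width = 24L, flag = "-"),
                        paste(vapply(cells, pad, ""), collapse = "")))
    }
  }
  structure(lines, class = "substitution_table")
}

#' @export
print.substitution_table <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
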