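#' Published ICAD descriptive statistics by age group
#'
#' Mean (SD) behaviour and risk-marker descriptives from the pooled ICAD
#' cross-sectional analysis of 18,200 young people in 13 studies, stratified
#' into children (< 10 years), adolescents (10 to < 15 years) and older
#' adolescents (>= 15 years).  These values calibrate the synthetic cohort
#' generator and supply the stratum means used for relative-effect
#' worked examples.  Behaviours are minutes/day; outcome units: WC cm, SBP
#' mmHg, lipids and glucose mmol/L, insulin in the source's printed units.
#'
#' @return Data frame, one row per age group.
#' @export
icad_descriptives <- function() {
  data.frame(
    age_group = c("children", "adolescents", "older"),
    n = c(4971L, 10836L, 2393L),
    age_min = c(4, 10, 15),
    age_max = c(10, 15, 18),
    wear_mean = c(779, 790, 815), wear_sd = c(68, 60, 77),
    cpm_mean = c(661, 578, 433), cpm_sd = c(233, 210, 197),
    sedentary_mean = c(313, 372, 455), sedentary_sd = c(95, 82, 102),
    lpa_mean = c(405, 361, 318), lpa_sd = c(72, 65, 83),
    mvpa_mean = c(56, 54, 39), mvpa_sd = c(31, 29, 29),
    wc_mean = c(59.1, 68.6, 78.1), wc_sd = c(8.2, 10.8, 14.4),
    sbp_mean = c(99.0, 105.5, 110.6), sbp_sd = c(8.9, 9.8, 10.8),
    hdl_mean = c(1.53, 1.43, 1.35), hdl_sd = c(0.32, 0.34, 0.30),
    ldl_mean = c(2.57, 2.41, 2.39), ldl_sd = c(0.75, 0.67, 0.69),
    insulin_mean = c(34.8, 66.9, 74.3), insulin_sd = c(24.7, 54.4, 64.6),
    trig_mean = c(0.74, 0.86, 0.90), trig_sd = c(0.37, 0.45, 0.50),
    glucose_mean = c(4.94, 5.16, 5.14), glucose_sd = c(0.52, 0.82, 0.50))
}

#' Published isotemporal substitution worked examples
#'
#' The headline substitution estimates from the pooled ICAD analysis,
#' paired with the stratum outcome means against which the source reports
#' them in relative terms.  `beta` is the change in the outcome per
#' reallocation of 10 min/day from the `from` behaviour to the `to`
#' behaviour; `published_pct` is the relative effect the source quotes.
#' Used as worked-example inputs for [relative_effect()] and as planted
#' effects for simulation-based checks — they are not reproducible from the
#' synthetic data, which only emulates the pooled dataset's structure.
#'
#' @return Data frame with one row per worked example.
#' @export
icad_worked_examples <- function() {
  data.frame(
    outcome = c("wc", "wc", "wc", "sbp", "hdl", "ldl", "ldl", "trig",
                "insulin"),
    stratum = c("children", "adolescents", "older", "adolescents",
                "children", "children", "adolescents", "adolescents",
                "children"),
    from = c("sedentary", "sedentary", "sedentary", "sedentary", "lpa",
             "sedentary", "sedentary", "sedentary", "sedentary"),
    to = c("mvpa", "mvpa", "mvpa", "mvpa", "mvpa", "mvpa", "mvpa", "mvpa",
           "mvpa"),
    beta = c(-0.287, -0.589, -0.814, -0.084, 0.010, -0.022, -0.012, -0.019,
             -0.850),
    ci_low = c(-0.518, -0.702, -1.334, -0.143, 0.001, -0.032, -0.023,
               -0.026, -1.614),
    ci_high = c(-0.056, -0.477, -0.294, -0.025, 0.019, -0.012, -0.001,
                -0.012, -0.086),
    stratum_mean = c(59.1, 68.6, 78.1, 105.5, 1.53, 2.57, 2.41, 0.86, 34.8),
    published_pct = c(0.5, 0.9, 1.0, 0.1, 0.7, 0.9, 0.5, 2.2, 2.4),
    n = c(4971L, 10836L, 1896L, 8100L, 3112L, 2428L, 1166L, 1160L, 2151L))
}
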