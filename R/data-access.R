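#' Country-level severe-wasting summary for 51 LMICs
#'
#' A compiled country-level summary of pooled Demographic and Health
#' Surveys (2010-2018) across 51 low- and middle-income countries: the
#' survey year, number of under-five children, weighted severe-wasting
#' prevalence overall and by the poor/non-poor wealth dichotomy, and the
#' weighted share of children from poor households, all in percent to
#' one decimal. These published country figures serve as ready-made
#' inputs for the risk-difference and quadrant-classification tools when
#' the underlying microdata are not available.
#'
#' @return Data frame with columns `region`, `country`, `year`, `n`,
#'   `prev_all`, `poor_pct`, `prev_poor`, `prev_nonpoor`.
#' @examples
#' cs <- country_summary()
#' head(risk_difference(cs$prev_poor, cs$prev_nonpoor))
#' @export
country_summary <- function() {
  utils::read.csv(system.file("extdata", "lmic_sw_country_summary.csv",
                              package = "swdecomp"),
                  stringsAsFactors = FALSE)
}
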