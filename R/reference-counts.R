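#' Published reference tabulations
#'
#' Stratified counts transcribed from the published tables of a
#' population-based Ontario colon-cancer cohort diagnosed 2007--2019
#' (N = 64,303): cohort characteristics by neighbourhood income
#' quintile, and diagnostic-interval features by symptom status and
#' quintile.  These are the tabulations the generator defaults are
#' calibrated to; the package's percent/summary operations reproduce
#' the published column percents from them (see the worked example in
#' the README and `scripts/acceptance.R`).
#'
#' @param table `"cohort"` for demographic/disease characteristics by
#'   quintile, `"pathway"` for interval features by symptom status and
#'   quintile.
#' @return tibble of counts in long format (`variable`, `level`,
#'   `quintile`, `n`, and `status` for the pathway table).
#' @export
#' @examples
#' head(reference_counts("pathway"))
reference_counts <- function(table = c("cohort", "pathway")) {
  table <- match.arg(table)
  f <- system.file("extdata",
                   paste0("published_", table, "_counts.csv"),
                   package = "dxinterval", mustWork = TRUE)
  readr::read_csv(f, show_col_types = FALSE)
}
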