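#' Stratified counts and column percents
#'
#' Counts the levels of a categorical variable within each stratum and
#' reports column percents (100 * n / stratum denominator), rounded
#' half-up to one decimal, matching the convention of printed cohort
#' tables.
#'
#' @param data a data frame.
#' @param variable variable to tabulate (tidy-eval column).
#' @param stratum stratifying variable (tidy-eval column); omit for a
#'   single overall column.
#' @param weight optional count column: when supplied, `data` is
#'   treated as pre-aggregated counts rather than one row per subject.
#' @return tibble `variable`, `level`, `stratum`, `n`, `pct`, with the
#'   stratum denominators as attribute `denominators`.
#' @export
#' @examples
#' df <- tibble::tibble(q = rep(1:2, c(30, 70)), x = rep(c("a", "b", "a", "b"),
#'                      c(10, 20, 35, 35)))
#' stratified_counts(df, x, q)
stratified_counts <- function(data, variable, stratum = NULL, weight = NULL) {
  var_q <- rlang::enquo(variable)
  str_q <- rlang::enquo(stratum)
  w_q <- rlang::enquo(weight)
  var_name <- rlang::as_name(var_q)
  check_columns(data, var_name, "data")
  has_stratum <- !rlang::quo_is_null(str_q)
  has_weight <- !rlang::quo_is_null(w_q)

  grouped <- if (has_stratum) {
    data %>% dplyr::group_by(stratum = !!str_q, level = !!var_q)
  } else {
    data %>% dplyr::mutate(stratum = "overall") %>%
      dplyr::group_by(.data$stratum, level = !!var_q)
  }
  counts <- if (has_weight) {
    grouped %>% dplyr::summarise(n = sum(!!w_q), .groups = "drop")
  } else {
    grouped %>% dplyr::summarise(n = dplyr::n(), .groups = "drop")
  }
  out <- counts %>%
    dplyr::group_by(.data$stratum) %>%
    dplyr::mutate(pct = round_half_up(100 * .data$n / sum(.data$n), 1)) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(variable = var_name, level = as.character(.data$level),
                  .before = 1)
  denoms <- counts %>%
    dplyr::group_by(.data$stratum) %>%
    dplyr::summarise(denominator = sum(.data$n), .groups = "drop")
  attr(out, "denominators") <- denoms
  out
}

#' Interval summaries by stratum
#'
#' Median, interquartile range and 90th percentile of the diagnostic
#' interval per stratum.  Quantiles use linear interpolation between
#' order statistics and are reported as whole days (rounded half-up).
#' Empty strata yield `n = 0` with missing quantiles.
#'
#' @param data a data frame of per-patient intervals.
#' @param value interval column (tidy-eval), e.g. `interval_days`.
#' @param ... stratifying columns (tidy-eval); omit for an overall row.
#' @return tibble with stratum columns plus `n`, `q25`, `median`,
#'   `q75`, `q90` (days).
#' @export
#' @examples
#' df <- tibble::tibble(g = rep(c("a", "b"), each = 50),
#'                      d = c(1:50, seq(2, 100, 2)))
#' interval_summary(df, d, g)
interval_summary <- function(data, value, ...) {
  val_q <- rlang::enquo(value)
  check_columns(data, rlang::as_name(val_q), "data")
  grouped <- dplyr::group_by(data, ...)
  grouped %>%
    dplyr::summarise(
      n = sum(!is.na(!!val_q)),
      q25 = qt_days(!!val_q, 0.25),
      median = qt_days(!!val_q, 0.5),
      q75 = qt_days(!!val_q, 0.75),
      q90 = qt_days(!!val_q, 0.9),
      .groups = "drop")
}

qt_days <- function(x, p) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  round_half_up(stats::quantile(x, p, type = 7, names = FALSE))
}

#' Pearson chi-squared test of independence
#'
#' Classic Pearson statistic \eqn{\sum (O - E)^2 / E} on a contingency
#' table, without continuity correction, with
#' `df = (rows - 1) * (cols - 1)` and an upper-tail p-value.  Tables
#' with an empty row or column margin are rejected.
#'
#' @param x either a contingency table (matrix) or a data frame.
#' @param row,col when `x` is a data frame: the two categorical columns
#'   (tidy-eval) to cross-tabulate.
#' @return one-row tibble `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_squared_test(matrix(c(20, 10, 10, 20), 2))
chi_squared_test <- function(x, row = NULL, col = NULL) {
  if (is.data.frame(x)) {
    row_q <- rlang::enquo(row)
    col_q <- rlang::enquo(col)
    tab <- table(dplyr::pull(x, !!row_q), dplyr::pull(x, !!col_q))
  } else {
    tab <- as.matrix(x)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate table: empty row or column margin",
          class = "dx_degenerate_table_error")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}
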