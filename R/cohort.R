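#' Apply cohort eligibility and exclusion rules
#'
#' Sequentially applies the study exclusion rules to the registry:
#' (1) death before diagnosis, (2) multiple cancers diagnosed on the
#' same day, (3) no continuous insurance eligibility over the 2 years
#' before diagnosis, (4) missing neighbourhood income quintile.  Each
#' patient is excluded by the earliest applicable rule only, matching
#' attrition-flow-diagram convention.  A fifth rule (first contact not
#' identifiable) is applied later by [build_intervals()] and can be
#' appended to the report with [append_attrition()].
#'
#' A death date *equal to* the diagnosis date is retained: exclusion
#' requires death strictly before diagnosis.  Continuous eligibility
#' tolerates administrative gaps of up to `max_gap_days` between
#' successive coverage spans.
#'
#' @param registry tibble with `patient_id`, `diagnosis_date` (possibly
#'   several rows per patient on the same day for synchronous cancers).
#' @param persons tibble with `patient_id`, `death_date`,
#'   `income_quintile`.
#' @param eligibility tibble of coverage spans with `patient_id`,
#'   `start_date`, `end_date`.
#' @param window_days length of the pre-diagnosis coverage window
#'   (default 730 days, i.e. 2 years).
#' @param max_gap_days largest coverage gap still counted as continuous.
#' @return list with `cohort` (one row per retained patient, registry
#'   columns plus person columns) and `attrition` (tibble of
#'   `rule`, `n_excluded`, `n_remaining`).
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 300, seed = 11))
#' res <- apply_exclusions(sim$registry, sim$persons, sim$eligibility)
#' res$attrition
apply_exclusions <- function(registry, persons, eligibility,
                             window_days = 730, max_gap_days = 30) {
  check_columns(registry, c("patient_id", "diagnosis_date"), "registry")
  check_columns(persons, c("patient_id", "death_date", "income_quintile"),
                "persons")
  check_columns(eligibility, c("patient_id", "start_date", "end_date"),
                "eligibility")

  # one analytic row per patient (first diagnosis date), remembering
  # how many registry rows shared that date
  first_dx <- registry %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::filter(.data$diagnosis_date == min(.data$diagnosis_date)) %>%
    dplyr::mutate(n_same_day = dplyr::n()) %>%
    dplyr::slice(1) %>%
    dplyr::ungroup()

  df <- dplyr::left_join(first_dx, persons, by = "patient_id")
  n0 <- nrow(df)

  covered <- continuous_coverage(eligibility, df, window_days, max_gap_days)

  viol <- dplyr::transmute(
    df,
    patient_id = .data$patient_id,
    r1 = !is.na(.data$death_date) & .data$death_date < .data$diagnosis_date,
    r2 = .data$n_same_day > 1,
    r3 = !.data$patient_id %in% covered,
    r4 = is.na(.data$income_quintile))

  rule_names <- c("death before diagnosis",
                  "multiple cancers on the same day",
                  "no continuous eligibility 2 years before diagnosis",
                  "missing income quintile")
  first_rule <- apply(as.matrix(viol[, c("r1", "r2", "r3", "r4")]), 1,
                      function(r) if (any(r)) which(r)[1] else 0L)

  att <- tibble::tibble(rule = rule_names,
                        n_excluded = vapply(1:4, function(k)
                          sum(first_rule == k), integer(1)))
  att$n_remaining <- n0 - cumsum(att$n_excluded)

  keep <- viol$patient_id[first_rule == 0L]
  cohort <- df %>%
    dplyr::filter(.data$patient_id %in% keep) %>%
    dplyr::select(-"n_same_day")
  list(cohort = cohort,
       attrition = structure(att, class = c("dx_attrition", class(att))))
}

# patient ids whose merged coverage spans (gaps <= max_gap_days bridged)
# contain [diagnosis - window_days, diagnosis]
continuous_coverage <- function(eligibility, df, window_days, max_gap_days) {
  if (nrow(eligibility) == 0) return(character(0))
  spans <- eligibility %>%
    dplyr::inner_join(df[, c("patient_id", "diagnosis_date")],
                      by = "patient_id") %>%
    dplyr::arrange(.data$patient_id, .data$start_date)
  merged <- spans %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::mutate(
      gap = as.numeric(.data$start_date -
                         dplyr::lag(cummax_date(.data$end_date))),
      piece = cumsum(dplyr::coalesce(.data$gap > max_gap_days, TRUE))) %>%
    dplyr::group_by(.data$patient_id, .data$piece) %>%
    dplyr::summarise(start_date = min(.data$start_date),
                     end_date = max(.data$end_date),
                     diagnosis_date = .data$diagnosis_date[1],
                     .groups = "drop")
  ok <- merged %>%
    dplyr::filter(.data$start_date <= .data$diagnosis_date - window_days,
                  .data$end_date >= .data$diagnosis_date)
  unique(ok$patient_id)
}

# running maximum that preserves Date class
cummax_date <- function(x) as.Date(cummax(as.numeric(x)), origin = "1970-01-01")

#' Append a later exclusion step to an attrition report
#'
#' @param attrition an attrition report from [apply_exclusions()].
#' @param rule rule label.
#' @param n_excluded number of patients removed at this step.
#' @return the extended attrition report.
#' @export
append_attrition <- function(attrition, rule, n_excluded) {
  last_remaining <- attrition$n_remaining[nrow(attrition)]
  out <- dplyr::bind_rows(
    attrition,
    tibble::tibble(rule = rule, n_excluded = as.integer(n_excluded),
                   n_remaining = last_remaining - as.integer(n_excluded)))
  structure(out, class = class(attrition))
}

#' @export
print.dx_attrition <- function(x, ...) {
  cat("Cohort attrition\n")
  NextMethod()
}
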