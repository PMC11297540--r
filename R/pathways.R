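#' Classify symptom status from the index-date encounter set
#'
#' A patient is asymptomatic (screen-detected proxy) when every
#' encounter on the first-encounter date is a screening test (stool
#' test or lower GI endoscopy) or a consultation, at least one of them
#' is a screening test, and none occurred in the emergency department.
#' Any symptom-coded or non-screening first encounter, or an ED first
#' encounter, makes the interval symptomatic.  A consultation alone
#' (no screening test that day) is symptomatic.
#'
#' @param categories character vector of the index-date encounter
#'   categories (must be non-empty).
#' @param ed_flags logical vector, same length: whether each index-date
#'   encounter occurred in the ED.
#' @param groups category groups, see [category_groups()].
#' @return `"asymptomatic"` or `"symptomatic"`.
#' @export
#' @examples
#' classify_symptom_status("gfobt", FALSE)
#' classify_symptom_status(c("lower_gi_endoscopy", "consultation"), c(FALSE, FALSE))
#' classify_symptom_status("lower_gi_endoscopy", TRUE)   # ED scope
classify_symptom_status <- function(categories, ed_flags,
                                    groups = category_groups()) {
  if (length(categories) == 0) {
    abort("index-date encounter set must be non-empty",
          class = "dx_contract_error")
  }
  allowed <- c(groups$screening, groups$consultation)
  asym <- all(categories %in% allowed) &&
    any(categories %in% groups$screening) &&
    !any(ed_flags)
  if (asym) "asymptomatic" else "symptomatic"
}

#' Assign the nine-way diagnostic pathway code
#'
#' Pathway 1 is every asymptomatic interval.  Symptomatic intervals
#' are coded by whether the interval contains a lower GI endoscopy,
#' whether it contains imaging, and whether the first encounter was in
#' the ED:
#' \tabular{llll}{
#'   code \tab scope \tab imaging \tab ED at index \cr
#'   2 \tab yes \tab no  \tab yes \cr
#'   3 \tab yes \tab no  \tab no  \cr
#'   4 \tab yes \tab yes \tab yes \cr
#'   5 \tab yes \tab yes \tab no  \cr
#'   6 \tab no  \tab yes \tab yes \cr
#'   7 \tab no  \tab yes \tab no  \cr
#'   8 \tab no  \tab no  \tab yes \cr
#'   9 \tab no  \tab no  \tab no
#' }
#'
#' All arguments are vectorized.
#'
#' @param status `"asymptomatic"` or `"symptomatic"`.
#' @param scope_any lower GI endoscopy anywhere in the interval?
#' @param imaging_any imaging anywhere in the interval?
#' @param ed_at_index first encounter in the emergency department?
#' @return integer pathway codes 1--9.
#' @export
#' @examples
#' assign_pathway("symptomatic", TRUE, FALSE, TRUE)   # 2
#' assign_pathway("asymptomatic", TRUE, TRUE, FALSE)  # 1
assign_pathway <- function(status, scope_any, imaging_any, ed_at_index) {
  sym <- dplyr::case_when(
    scope_any & !imaging_any & ed_at_index   ~ 2L,
    scope_any & !imaging_any & !ed_at_index  ~ 3L,
    scope_any & imaging_any & ed_at_index    ~ 4L,
    scope_any & imaging_any & !ed_at_index   ~ 5L,
    !scope_any & imaging_any & ed_at_index   ~ 6L,
    !scope_any & imaging_any & !ed_at_index  ~ 7L,
    !scope_any & !imaging_any & ed_at_index  ~ 8L,
    TRUE                                     ~ 9L)
  dplyr::if_else(status == "asymptomatic", 1L, sym)
}

#' Classify pathways and index-date features for a cohort
#'
#' Joins the built intervals back to the encounter table and derives,
#' per patient: symptom status (from the index-date encounter set),
#' the nine-way pathway code, ED presentation at index, whether a
#' referring-physician visit was the first contact, whether the
#' diagnosis fell on the index date (interval of 1 day), and the
#' number of lower GI endoscopies within the interval.
#'
#' @param intervals output of [build_intervals()] (unidentifiable rows
#'   are dropped).
#' @param encounters categorized encounters.
#' @param groups category groups, see [category_groups()].
#' @return tibble with one row per patient with an identified interval:
#'   `patient_id`, `status`, `pathway`, `ed_at_index`,
#'   `referring_first_contact`, `diagnosed_on_index`, `scope_count`,
#'   `first_encounter_categories` (list-column).
#' @export
classify_pathways <- function(intervals, encounters,
                              groups = category_groups()) {
  check_columns(intervals,
                c("patient_id", "index_date", "diagnosis_date",
                  "interval_days", "referral_extended", "unidentifiable",
                  "index_encounter_ids"),
                "intervals")
  check_columns(encounters,
                c("encounter_id", "patient_id", "date", "category", "ed_flag"),
                "encounters")
  ids <- intervals %>% dplyr::filter(!.data$unidentifiable)
  if (nrow(ids) == 0) {
    return(tibble::tibble(patient_id = character(), status = character(),
                          pathway = integer(), ed_at_index = logical(),
                          referring_first_contact = logical(),
                          diagnosed_on_index = logical(),
                          scope_count = integer(),
                          first_encounter_categories = list()))
  }

  index_ids <- ids %>%
    dplyr::select("patient_id", "index_encounter_ids") %>%
    tidyr::unnest("index_encounter_ids") %>%
    dplyr::rename(encounter_id = "index_encounter_ids")
  index_enc <- index_ids %>%
    dplyr::inner_join(encounters[, c("encounter_id", "category", "ed_flag")],
                      by = "encounter_id")
  idx_feat <- index_enc %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(
      status = classify_symptom_status(.data$category, .data$ed_flag,
                                       groups = groups),
      ed_at_index = any(.data$ed_flag),
      first_encounter_categories = list(sort(unique(.data$category))),
      .groups = "drop")

  in_interval <- encounters %>%
    dplyr::inner_join(ids[, c("patient_id", "index_date", "diagnosis_date")],
                      by = "patient_id") %>%
    dplyr::filter(.data$date >= .data$index_date,
                  .data$date <= .data$diagnosis_date)
  iv_feat <- in_interval %>%
    dplyr::group_by(.data$patient_id) %>%
    dplyr::summarise(
      scope_any = any(.data$category %in% groups$scope),
      imaging_any = any(.data$category %in% groups$imaging),
      scope_count = sum(.data$category %in% groups$scope),
      .groups = "drop")

  ids %>%
    dplyr::select("patient_id", "interval_days", "referral_extended") %>%
    dplyr::left_join(idx_feat, by = "patient_id") %>%
    dplyr::left_join(iv_feat, by = "patient_id") %>%
    dplyr::mutate(
      scope_any = dplyr::coalesce(.data$scope_any, FALSE),
      imaging_any = dplyr::coalesce(.data$imaging_any, FALSE),
      scope_count = dplyr::coalesce(.data$scope_count, 0L),
      pathway = assign_pathway(.data$status, .data$scope_any,
                               .data$imaging_any, .data$ed_at_index),
      referring_first_contact = .data$referral_extended,
      diagnosed_on_index = .data$interval_days == 1L) %>%
    dplyr::select("patient_id", "status", "pathway", "ed_at_index",
                  "referring_first_contact", "diagnosed_on_index",
                  "scope_count", "first_encounter_categories")
}
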