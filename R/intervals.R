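#' Eligible encounters under category lookback windows
#'
#' An encounter is eligible to open the diagnostic interval when its
#' category appears in the lookback table and it falls within that
#' category's window: between `lookback_days` before diagnosis and the
#' diagnosis date itself (a diagnosis-day contact counts, giving an
#' interval of 1 day).  Encounters after diagnosis are never eligible.
#'
#' @param encounters categorized encounters (`patient_id`, `date`,
#'   `category`, plus any carried columns).
#' @param lookbacks lookback table from [build_lookback_table()]
#'   (`category`, `lookback_days`).
#' @param diagnoses tibble with `patient_id`, `diagnosis_date`.
#' @return the eligible subset of `encounters`, with
#'   `days_before_diagnosis` added.
#' @export
eligible_encounters <- function(encounters, lookbacks, diagnoses) {
  check_columns(encounters, c("patient_id", "date", "category"), "encounters")
  check_columns(lookbacks, c("category", "lookback_days"), "lookbacks")
  check_columns(diagnoses, c("patient_id", "diagnosis_date"), "diagnoses")
  encounters %>%
    dplyr::inner_join(lookbacks[, c("category", "lookback_days")],
                      by = "category") %>%
    dplyr::inner_join(diagnoses[, c("patient_id", "diagnosis_date")],
                      by = "patient_id") %>%
    dplyr::mutate(days_before_diagnosis =
                    as.numeric(.data$diagnosis_date - .data$date)) %>%
    dplyr::filter(.data$days_before_diagnosis >= 0,
                  .data$days_before_diagnosis <= .data$lookback_days) %>%
    dplyr::select(-"lookback_days", -"diagnosis_date")
}

#' Link a procedure encounter to its referring-physician visit
#'
#' For a procedure encounter carrying a referring provider id, returns
#' the earliest visit by that provider occurring strictly less than
#' 365 days before the procedure (and strictly before it).  Returns a
#' zero-row tibble when the procedure has no referrer or no visit
#' qualifies.
#'
#' @param procedure one-row tibble (or list) with `date` and
#'   `referring_provider_id`.
#' @param visits tibble of the patient's visit encounters with `date`
#'   and `provider_id`.
#' @return zero- or one-row tibble from `visits`.
#' @export
link_referring_visit <- function(procedure, visits) {
  ref <- procedure$referring_provider_id[1]
  if (is.null(ref) || is.na(ref) || nrow(visits) == 0) {
    return(visits[0, , drop = FALSE])
  }
  gap <- as.numeric(procedure$date[1] - visits$date)
  ok <- visits[visits$provider_id == ref & gap > 0 & gap < 365, , drop = FALSE]
  if (nrow(ok) == 0) return(ok)
  ok[which.min(ok$date), , drop = FALSE]
}

#' Build per-patient diagnostic intervals
#'
#' Identifies each patient's earliest eligible encounter and computes
#' the diagnostic interval.  Candidate index dates are the dates of all
#' eligible encounters plus, for every eligible procedure-flagged
#' encounter with a referring provider, the date of the linked
#' referring-physician visit (earliest visit by that provider strictly
#' within 365 days before the procedure).  The index date is the
#' minimum candidate; the interval is
#' `diagnosis_date - index_date + 1` days, so a diagnosis-day first
#' contact yields a 1-day interval.  Patients with no candidate signal
#' an unidentifiable first contact and are excluded (flagged, not
#' dropped from the return).
#'
#' Visits searched for referral linkage are non-procedure billing
#' encounters with a recorded provider.
#'
#' @param encounters categorized encounters including `encounter_id`,
#'   `provider_id`, `referring_provider_id`, `procedure_flag`,
#'   `source`, `ed_flag`.
#' @param lookbacks lookback table from [build_lookback_table()].
#' @param diagnoses tibble with `patient_id`, `diagnosis_date`.
#' @return tibble with one row per patient in `diagnoses`:
#'   `patient_id`, `index_date`, `diagnosis_date`, `interval_days`,
#'   `referral_extended`, `unidentifiable`, and the list-column
#'   `index_encounter_ids` (eligible encounters on the index date,
#'   plus the contributing referral visit when the index came from
#'   one).
#' @export
build_intervals <- function(encounters, lookbacks, diagnoses) {
  check_columns(diagnoses, c("patient_id", "diagnosis_date"), "diagnoses")
  if (anyNA(diagnoses$diagnosis_date)) {
    abort("diagnosis_date must be non-missing for every patient",
          class = "dx_contract_error")
  }
  check_columns(encounters,
                c("encounter_id", "patient_id", "date", "category",
                  "provider_id", "referring_provider_id", "procedure_flag"),
                "encounters")

  elig <- eligible_encounters(encounters, lookbacks, diagnoses)

  # referral candidates: earliest qualifying visit per eligible
  # procedure encounter with a referrer
  procs <- elig %>%
    dplyr::filter(.data$procedure_flag, !is.na(.data$referring_provider_id))
  visits <- encounters %>%
    dplyr::filter(!.data$procedure_flag, .data$source == "billing",
                  !is.na(.data$provider_id))
  ref_links <- link_referrals(procs, visits)

  candidates <- dplyr::bind_rows(
    elig %>%
      dplyr::transmute(patient_id = .data$patient_id, date = .data$date,
                       encounter_id = .data$encounter_id,
                       via_referral = FALSE),
    ref_links)

  idx <- if (nrow(candidates) == 0) {
    tibble::tibble(patient_id = character(),
                   index_date = as.Date(character()),
                   index_encounter_ids = list(),
                   referral_extended = logical())
  } else {
    candidates %>%
      dplyr::group_by(.data$patient_id) %>%
      dplyr::summarise(
        index_date = min(.data$date),
        index_encounter_ids =
          list(unique(.data$encounter_id[.data$date == min(.data$date)])),
        referral_extended =
          any(.data$via_referral[.data$date == min(.data$date)]),
        .groups = "drop")
  }

  diagnoses %>%
    dplyr::distinct(.data$patient_id, .data$diagnosis_date) %>%
    dplyr::left_join(idx, by = "patient_id") %>%
    dplyr::mutate(
      unidentifiable = is.na(.data$index_date),
      interval_days = as.integer(.data$diagnosis_date - .data$index_date) + 1L,
      referral_extended = dplyr::coalesce(.data$referral_extended, FALSE)) %>%
    dplyr::relocate("patient_id", "index_date", "diagnosis_date",
                    "interval_days", "referral_extended", "unidentifiable")
}

# vectorized referral linkage over all (procedure, visit) pairs
link_referrals <- function(procs, visits) {
  if (nrow(procs) == 0) {
    return(tibble::tibble(patient_id = character(), date = as.Date(character()),
                          encounter_id = character(), via_referral = logical()))
  }
  pairs <- procs %>%
    dplyr::transmute(patient_id = .data$patient_id,
                     proc_id = .data$encounter_id,
                     proc_date = .data$date,
                     referring_provider_id = .data$referring_provider_id) %>%
    dplyr::inner_join(
      visits %>%
        dplyr::transmute(patient_id = .data$patient_id,
                         visit_id = .data$encounter_id,
                         visit_date = .data$date,
                         provider_id = .data$provider_id),
      by = "patient_id", relationship = "many-to-many") %>%
    dplyr::filter(.data$provider_id == .data$referring_provider_id,
                  .data$proc_date - .data$visit_date > 0,
                  .data$proc_date - .data$visit_date < 365)
  pairs %>%
    dplyr::group_by(.data$proc_id) %>%
    dplyr::slice_min(.data$visit_date, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(patient_id = .data$patient_id, date = .data$visit_date,
                     encounter_id = .data$visit_id, via_referral = TRUE)
}
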