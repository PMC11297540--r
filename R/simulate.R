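#' Draw the patient-level table with ground-truth labels
#'
#' Samples, for `n_patients` diagnosed patients, the income quintile,
#' demographic covariates, diagnosis date, symptom status, the true
#' diagnostic interval (days, inclusive of the diagnosis day) and the
#' implied interval-onset date, plus injected exclusion conditions.
#' This table is the ground truth against which the encounter-level
#' reconstruction is judged, and it is directly usable as an
#' analysis-ready cohort for the quantile-regression layer (with
#' `true_interval_days` as the outcome).
#'
#' Intervals are drawn from the configured per-(status, quintile)
#' distribution, shifted additively by mean-centred covariate effects,
#' rounded, and floored at 1 day.
#'
#' @param config a [sim_config()] object.
#' @return tibble with one row per diagnosed patient.
#' @export
#' @examples
#' pts <- simulate_patients(sim_config(n_patients = 200, seed = 7))
#' dplyr::count(pts, quintile, status)
simulate_patients <- function(config) {
  stopifnot(inherits(config, "dx_sim_config"))
  n <- config$n_patients
  if (n == 0) return(empty_patients())
  set.seed(config$seed)
  cv <- config$covariates

  quintile <- sample.int(5, n, replace = TRUE, prob = config$quintile_probs)
  status <- ifelse(stats::runif(n) < config$asymptomatic_prob_by_quintile[quintile],
                   "asymptomatic", "symptomatic")
  age <- pmin(pmax(round(stats::rnorm(n, cv$age_mean[quintile], cv$age_sd)), 20), 105)
  sex <- ifelse(stats::runif(n) < cv$female_prob[quintile], "F", "M")
  rural <- stats::runif(n) < cv$rural_prob[quintile]
  rio_score <- ifelse(rural,
                      45 + floor(stats::runif(n) * 56),
                      floor(stats::runif(n) * 45))
  comorbidity_count <- stats::rpois(n, cv$comorbidity_lambda[quintile])
  stage_lv <- c("I", "II", "III", "IV", "unknown")
  stage <- character(n)
  for (q in 1:5) {
    idx <- which(quintile == q)
    if (length(idx)) {
      stage[idx] <- sample(stage_lv, length(idx), replace = TRUE,
                           prob = cv$stage_probs[q, ])
    }
  }
  histology <- ifelse(stats::runif(n) < cv$adenocarcinoma_prob,
                      "adenocarcinoma", "other")
  win <- config$diagnosis_window
  diagnosis_date <- win[1] +
    floor(stats::runif(n) * (as.numeric(win[2] - win[1]) + 1))
  dx_year <- as.integer(format(diagnosis_date, "%Y"))

  base <- draw_interval_base(config, status, quintile)
  shift <- covariate_shift(config, age, sex, rural, dx_year, quintile)
  true_interval_days <- pmax(
    1L,
    as.integer(round(pmin(base + shift, config$interval_cap_days))))
  # same-day diagnoses (diagnosis on the first-contact date)
  same_day <- stats::runif(n) <
    unname(config$same_day_prob_by_status[status])
  true_interval_days[same_day] <- 1L
  true_onset_date <- diagnosis_date - (true_interval_days - 1L)

  er <- config$exclusion_rates
  u <- stats::runif(n)   # one stream, mutually exclusive injections
  r1 <- er[["death_before_diagnosis"]]
  r2 <- r1 + er[["same_day_multiple_cancer"]]
  r3 <- r2 + er[["eligibility_gap"]]
  r4 <- r3 + er[["missing_income"]]

  tibble::tibble(
    patient_id = sprintf("P%06d", seq_len(n)),
    quintile = as.integer(quintile),
    age = as.numeric(age),
    sex = sex,
    rural = rural,
    rio_score = as.integer(rio_score),
    comorbidity_count = as.integer(comorbidity_count),
    stage = stage,
    histology = histology,
    diagnosis_date = diagnosis_date,
    dx_year = dx_year,
    status = status,
    true_interval_days = true_interval_days,
    true_onset_date = true_onset_date,
    excl_death = u < r1,
    excl_multi_cancer = u >= r1 & u < r2,
    excl_eligibility = u >= r2 & u < r3,
    excl_missing_income = u >= r3 & u < r4)
}

empty_patients <- function() {
  tibble::tibble(
    patient_id = character(), quintile = integer(), age = numeric(),
    sex = character(), rural = logical(), rio_score = integer(),
    comorbidity_count = integer(), stage = character(),
    histology = character(), diagnosis_date = as.Date(character()),
    dx_year = integer(), status = character(),
    true_interval_days = integer(), true_onset_date = as.Date(character()),
    excl_death = logical(), excl_multi_cancer = logical(),
    excl_eligibility = logical(), excl_missing_income = logical())
}

draw_interval_base <- function(config, status, quintile) {
  n <- length(status)
  out <- numeric(n)
  for (st in c("symptomatic", "asymptomatic")) {
    d <- config$interval_dist[[st]]
    for (q in 1:5) {
      idx <- which(status == st & quintile == q)
      if (!length(idx)) next
      p <- d$params[d$params$quintile == q, ]
      out[idx] <- if (d$family == "lnorm") {
        stats::rlnorm(length(idx), p$meanlog, p$sdlog)
      } else {
        stats::rgamma(length(idx), shape = p$shape, scale = p$scale)
      }
    }
  }
  out
}

# Additive covariate effects, centred at their population means so the
# marginal interval distribution keeps the calibrated quantiles.
covariate_shift <- function(config, age, sex, rural, dx_year, quintile) {
  ce <- config$covariate_effects
  cv <- config$covariates
  w <- config$quintile_probs
  mu_age <- sum(w * cv$age_mean)
  mu_fem <- sum(w * cv$female_prob)
  mu_rur <- sum(w * cv$rural_prob)
  yrs <- as.integer(format(config$diagnosis_window, "%Y"))
  mu_year <- mean(yrs)
  ce$age_per_year * (age - mu_age) +
    ce$female * ((sex == "F") - mu_fem) +
    ce$rural * (rural - mu_rur) +
    ce$per_year * (dx_year - mu_year)
}

#' Generate one patient's encounter history
#'
#' Draws the encounter sequence for a single patient: Poisson
#' background encounters per category per 30-day pre-diagnosis bin
#' (27 bins), a cancer-related surge between interval onset and
#' diagnosis, the onset encounter itself (screening test for
#' asymptomatic patients; symptom-coded or emergency-department visit
#' for symptomatic patients), an optional diagnosis-day procedure, and
#' referring-physician links with a matching prior visit for procedure
#' encounters.
#'
#' The RNG stream is seeded from `(config$seed, patient_id)`, so a
#' patient's history does not depend on how many other patients are
#' simulated.
#'
#' @param config a [sim_config()] object.
#' @param patient_id patient identifier (string).
#' @param diagnosis_date,onset_date,status,quintile the patient's
#'   ground-truth labels; `onset_date` must not be after
#'   `diagnosis_date`.
#' @return tibble of encounters with columns `patient_id`, `date`,
#'   `source` (`billing`/`ED`/`hospitalization`), `code`, `ed_flag`,
#'   `provider_id`, `referring_provider_id`, `procedure_flag`.
#' @export
generate_encounter_history <- function(config, patient_id, diagnosis_date,
                                       onset_date, status, quintile) {
  if (onset_date > diagnosis_date) {
    abort("internal consistency error: interval onset after diagnosis",
          class = "dx_internal_error")
  }
  set.seed(patient_seed(config$seed, which_patient_num(patient_id)))
  groups <- category_groups()
  codemap <- default_codemap()
  cats <- unique(codemap$category)
  n_bins <- 27L

  cat_v <- character(0); d_v <- integer(0)   # d = days before diagnosis

  rates <- category_rates(config, cats)

  # background: Poisson counts per (category, bin), bin b = days
  # b*30+1 .. b*30+30 before diagnosis
  counts <- stats::rpois(length(cats) * n_bins, rep(rates, each = n_bins))
  if (sum(counts) > 0) {
    cat_idx <- rep(rep(seq_along(cats), each = n_bins), counts)
    bin_idx <- rep(rep(seq_len(n_bins) - 1L, times = length(cats)), counts)
    cat_v <- cats[cat_idx]
    d_v <- bin_idx * 30L + sample.int(30L, length(cat_idx), replace = TRUE)
  }

  # cancer-related surge over [onset, diagnosis - 1]
  L <- as.integer(diagnosis_date - onset_date)
  if (L > 0 && config$surge_multiplier > 1) {
    cr <- groups$cancer_related
    extra <- stats::rpois(length(cr),
                          category_rates(config, cr) *
                            (config$surge_multiplier - 1) * L / 30)
    if (sum(extra) > 0) {
      cat_v <- c(cat_v, rep(cr, extra))
      d_v <- c(d_v, sample.int(L, sum(extra), replace = TRUE))
    }
  }
  src_v <- rep("billing", length(cat_v))
  src_v[cat_v == "hospital_admission"] <- "hospitalization"

  # onset encounter(s)
  if (status == "asymptomatic") {
    first <- if (stats::runif(1) < config$gfobt_first_prob_by_quintile[quintile])
      "gfobt" else "lower_gi_endoscopy"
    cat_v <- c(cat_v, first)
    d_v <- c(d_v, L)
    src_v <- c(src_v, "billing")
    if (stats::runif(1) < 0.3) {    # co-dated consultation
      cat_v <- c(cat_v, "consultation")
      d_v <- c(d_v, L)
      src_v <- c(src_v, "billing")
    }
  } else {
    ed <- stats::runif(1) < config$ed_prob_by_quintile[quintile]
    cat_v <- c(cat_v, "gi_symptoms")
    d_v <- c(d_v, L)
    src_v <- c(src_v, if (ed) "ED" else "billing")
  }

  # diagnosis-day encounter (the contact at which diagnosis is made)
  if (stats::runif(1) < config$dx_day_encounter_prob) {
    hosp <- stats::runif(1) < 0.2
    cat_v <- c(cat_v, if (hosp) "hospital_admission" else "lower_gi_endoscopy")
    d_v <- c(d_v, 0L)
    src_v <- c(src_v, if (hosp) "hospitalization" else "billing")
  }

  m <- length(cat_v)
  prov <- 10000L + floor(stats::runif(m) * 90000)
  ref <- rep(NA_integer_, m)
  proc <- cat_v %in% groups$procedure

  # referring-physician links: the referrer has a prior visit strictly
  # before the procedure and always < 365 days, so always linkable.
  # Symptomatic referral chains start after first presentation, so the
  # visit stays inside the surge window where possible; screening
  # (asymptomatic) referrals arise from routine care and may precede
  # interval onset.
  take <- which(proc & stats::runif(m) < config$referral_prob)
  if (length(take)) {
    ref_ids <- 10000L + floor(stats::runif(length(take)) * 90000)
    ref[take] <- ref_ids
    max_gap <- if (status == "symptomatic") {
      pmax(30L, pmin(200L, L - d_v[take]))
    } else {
      rep(200L, length(take))
    }
    gap <- 30L + floor(stats::runif(length(take)) * (max_gap - 29L))
    cat_v <- c(cat_v, rep("consultation", length(take)))
    d_v <- c(d_v, d_v[take] + gap)
    src_v <- c(src_v, rep("billing", length(take)))
    prov <- c(prov, ref_ids)
    ref <- c(ref, rep(NA_integer_, length(take)))
    proc <- c(proc, rep(FALSE, length(take)))
  }

  code_of <- split(codemap$code, codemap$category)
  code_v <- vapply(cat_v, function(cc) {
    pool <- code_of[[cc]]
    pool[sample.int(length(pool), 1)]
  }, character(1), USE.NAMES = FALSE)

  ord <- order(d_v, decreasing = TRUE)
  tibble::tibble(
    patient_id = patient_id,
    date = diagnosis_date - d_v[ord],
    source = src_v[ord],
    code = code_v[ord],
    ed_flag = src_v[ord] == "ED",
    provider_id = as.integer(prov[ord]),
    referring_provider_id = as.integer(ref[ord]),
    procedure_flag = proc[ord])
}

# per-category background rates: scalar configs apply uniformly,
# named vectors look up by category (absent categories get 0)
category_rates <- function(config, cats) {
  br <- config$background_rate
  if (length(br) == 1 && is.null(names(br))) {
    return(rep(unname(br), length(cats)))
  }
  out <- unname(br[cats])
  out[is.na(out)] <- 0
  out
}

which_patient_num <- function(patient_id) {
  n <- suppressWarnings(as.integer(sub("^P", "", patient_id)))
  if (is.na(n)) n <- sum(utf8ToInt(patient_id))
  n
}

#' Generate the full linked synthetic tables
#'
#' Runs the complete generator: the patient-level draw
#' ([simulate_patients()]) plus per-patient encounter histories
#' ([generate_encounter_history()]), and assembles the linked tables a
#' registry-claims extract would provide.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `dx_simulation`: a list with tibbles
#'   `persons`, `registry`, `eligibility`, `encounters`,
#'   `ground_truth`, and the `config`.
#' @export
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 50, seed = 3))
#' names(sim)
#' nrow(sim$encounters)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "dx_sim_config"))
  pts <- simulate_patients(config)
  n <- nrow(pts)

  if (n == 0) {
    sim <- list(persons = empty_persons(), registry = empty_registry(),
                eligibility = empty_eligibility(),
                encounters = empty_encounters(),
                ground_truth = empty_ground_truth(), config = config)
    return(structure(sim, class = "dx_simulation"))
  }

  # post-patient-level draws (deterministic given seed; the per-patient
  # encounter streams are re-seeded independently below)
  set.seed(config$seed + 1L)
  topo_pool <- c("C18.0", paste0("C18.", 2:9))
  topography <- sample(topo_pool, n, replace = TRUE)
  death_gap <- 1L + floor(stats::runif(n) * 300)
  elig_back <- 1500L + floor(stats::runif(n) * 1500)

  persons <- tibble::tibble(
    patient_id = pts$patient_id,
    birth_date = pts$diagnosis_date - round(pts$age * 365.25),
    sex = pts$sex,
    death_date = dplyr::if_else(pts$excl_death,
                                pts$diagnosis_date - death_gap,
                                as.Date(NA)),
    income_quintile = dplyr::if_else(pts$excl_missing_income,
                                     NA_integer_, pts$quintile),
    rio_score = pts$rio_score,
    comorbidity_count = pts$comorbidity_count)

  registry <- tibble::tibble(
    patient_id = pts$patient_id,
    diagnosis_date = pts$diagnosis_date,
    topography = topography,
    morphology = dplyr::if_else(pts$histology == "adenocarcinoma",
                                "8140/3", "8240/3"),
    stage = pts$stage)
  dup <- pts[pts$excl_multi_cancer, ]
  if (nrow(dup) > 0) {
    registry <- dplyr::bind_rows(
      registry,
      tibble::tibble(
        patient_id = dup$patient_id,
        diagnosis_date = dup$diagnosis_date,
        topography = "C18.7",
        morphology = "8140/3",
        stage = dup$stage)) %>%
      dplyr::arrange(.data$patient_id)
  }

  # continuous coverage except for injected >30-day gaps in the 2-year
  # pre-diagnosis window
  base_elig <- tibble::tibble(
    patient_id = pts$patient_id,
    start_date = pts$diagnosis_date - elig_back,
    end_date = pts$diagnosis_date + 180L,
    gap = pts$excl_eligibility)
  ok_rows <- base_elig[!base_elig$gap, c("patient_id", "start_date", "end_date")]
  gp <- base_elig[base_elig$gap, ]
  gap_rows <- NULL
  if (nrow(gp) > 0) {
    dxd <- pts$diagnosis_date[match(gp$patient_id, pts$patient_id)]
    gap_rows <- dplyr::bind_rows(
      tibble::tibble(patient_id = gp$patient_id, start_date = gp$start_date,
                     end_date = dxd - 400L),
      tibble::tibble(patient_id = gp$patient_id, start_date = dxd - 340L,
                     end_date = gp$end_date))
  }
  eligibility <- dplyr::arrange(dplyr::bind_rows(ok_rows, gap_rows),
                                .data$patient_id, .data$start_date)

  histories <- purrr::pmap(
    list(pts$patient_id, pts$diagnosis_date, pts$true_onset_date,
         pts$status, pts$quintile),
    function(id, dx, onset, st, q) {
      generate_encounter_history(config, id, dx, onset, st, q)
    })
  encounters <- dplyr::bind_rows(histories)
  encounters$encounter_id <- sprintf("E%07d", seq_len(nrow(encounters)))
  encounters <- dplyr::relocate(encounters, "encounter_id")

  ground_truth <- tibble::tibble(
    patient_id = pts$patient_id,
    true_onset_date = pts$true_onset_date,
    true_status = pts$status,
    true_interval_days = pts$true_interval_days,
    quintile = pts$quintile)

  structure(list(persons = persons, registry = registry,
                 eligibility = eligibility, encounters = encounters,
                 ground_truth = ground_truth, config = config),
            class = "dx_simulation")
}

empty_persons <- function() {
  tibble::tibble(patient_id = character(), birth_date = as.Date(character()),
                 sex = character(), death_date = as.Date(character()),
                 income_quintile = integer(), rio_score = integer(),
                 comorbidity_count = integer())
}
empty_registry <- function() {
  tibble::tibble(patient_id = character(),
                 diagnosis_date = as.Date(character()),
                 topography = character(), morphology = character(),
                 stage = character())
}
empty_eligibility <- function() {
  tibble::tibble(patient_id = character(),
                 start_date = as.Date(character()),
                 end_date = as.Date(character()))
}
empty_encounters <- function() {
  tibble::tibble(encounter_id = character(), patient_id = character(),
                 date = as.Date(character()), source = character(),
                 code = character(), ed_flag = logical(),
                 provider_id = integer(), referring_provider_id = integer(),
                 procedure_flag = logical())
}
empty_ground_truth <- function() {
  tibble::tibble(patient_id = character(),
                 true_onset_date = as.Date(character()),
                 true_status = character(), true_interval_days = integer(),
                 quintile = integer())
}

#' @export
print.dx_simulation <- function(x, ...) {
  cat("<dx_simulation>\n")
  cat("  patients:   ", nrow(x$ground_truth), "\n")
  cat("  encounters: ", nrow(x$encounters), "\n")
  cat("  seed:       ", x$config$seed, "\n")
  invisible(x)
}
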