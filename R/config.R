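#' Simulation configuration for the synthetic linked-data generator
#'
#' Builds and validates the configuration driving [simulate_cohort()].
#' Defaults emulate a population-based Ontario colon-cancer cohort
#' diagnosed 2007--2019: quintile sizes, asymptomatic (screen-detected)
#' shares, emergency-department presentation shares and the per-quintile
#' diagnostic-interval distributions are calibrated to published
#' stratified tabulations from such a cohort (see the package vignette).
#'
#' Interval distributions are specified per symptom status and income
#' quintile by their median and 90th percentile in days; the constructor
#' converts these to log-normal (symptomatic) or gamma (asymptomatic)
#' parameters.  Quintile contrasts therefore act more strongly on the
#' upper tail, which is where income disparities concentrate.
#'
#' @param n_patients number of diagnosed patients to simulate.
#' @param seed master integer seed; every draw is a pure function of
#'   `(config, seed)`.
#' @param quintile_probs length-5 probability vector for neighbourhood
#'   income quintiles 1 (lowest) to 5 (highest); must sum to 1.
#' @param asymptomatic_prob_by_quintile probability of an asymptomatic
#'   (screen-detected) pathway per quintile.
#' @param ed_prob_by_quintile probability that a symptomatic patient's
#'   onset encounter is an emergency-department visit, per quintile.
#' @param interval_dist list with components `symptomatic` and
#'   `asymptomatic`, each a list with `family` (`"lnorm"` or `"gamma"`)
#'   and length-5 numeric vectors `median` and `q90` (days).
#' @param background_rate expected background encounters per 30-day
#'   bin: either a single rate applied to every category, or a named
#'   vector of per-category rates.  The default reflects that routine
#'   primary-care and laboratory contacts are far more frequent than
#'   colonoscopies or CT scans.
#' @param surge_multiplier factor (>= 1) by which cancer-related
#'   categories are elevated between interval onset and diagnosis.
#' @param referral_prob probability that a procedure encounter carries a
#'   referring physician (with a linkable prior visit).
#' @param exclusion_rates named rates for injected cohort-exclusion
#'   conditions: `death_before_diagnosis`, `same_day_multiple_cancer`,
#'   `eligibility_gap`, `missing_income`.
#' @param diagnosis_window length-2 Date vector of admissible diagnosis
#'   dates.
#' @param covariate_effects additive effects (days) on the interval:
#'   `age_per_year` (per year above 65), `female`, `rural`, `per_year`
#'   (per diagnosis year after 2019).  Effects are centred at their
#'   population means when drawing so the marginal interval
#'   distributions stay at the calibrated quantiles.
#' @param dx_day_encounter_prob probability of a diagnosis-day procedure
#'   encounter (the biopsy-confirming contact).
#' @param gfobt_first_prob_by_quintile among asymptomatic patients,
#'   probability the screening onset encounter is a stool test rather
#'   than a lower GI endoscopy.
#' @param same_day_prob_by_status probability (by symptom status
#'   `asymptomatic`, `symptomatic`) that the true interval is a single
#'   day, i.e. diagnosis on the first-contact date.
#' @param interval_cap_days truncation of the true interval draws:
#'   pre-diagnosis surges longer than this are clinically implausible
#'   and would exceed the lookback horizon.  The cap sits well above
#'   the configured 90th percentiles, so conditional quantiles up to
#'   the 90th are unaffected.
#'
#' @return an object of class `dx_sim_config` (a validated list; the
#'   interval distributions gain fitted `params` per quintile).
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 100, seed = 42)
#' cfg$interval_dist$symptomatic$params
sim_config <- function(n_patients = 10000,
                       seed = 1L,
                       quintile_probs = c(13060, 13502, 12808, 12437, 12496) / 64303,
                       asymptomatic_prob_by_quintile =
                         c(1985 / 13060, 2386 / 13502, 2377 / 12808,
                           2309 / 12437, 2321 / 12496),
                       ed_prob_by_quintile =
                         c(3898 / 11075, 3640 / 11116, 3408 / 10431,
                           3202 / 10128, 3058 / 10175),
                       interval_dist = list(
                         symptomatic = list(
                           family = "lnorm",
                           median = c(126, 124, 122, 118, 116),
                           q90    = c(410, 410, 406, 400, 392)),
                         asymptomatic = list(
                           family = "gamma",
                           median = c(71, 71, 70, 70, 70),
                           q90    = c(222, 224, 225, 226, 228))),
                       background_rate = c(gfobt = 0.010,
                                           lower_gi_endoscopy = 0.003,
                                           consultation = 0.010,
                                           gi_symptoms = 0.010,
                                           family_physician = 0.080,
                                           imaging_ct = 0.005,
                                           imaging_us = 0.010,
                                           imaging_contrast = 0.003,
                                           lab_general = 0.060,
                                           hospital_admission = 0.010),
                       surge_multiplier = 4,
                       referral_prob = 0.5,
                       exclusion_rates = c(death_before_diagnosis = 0.015,
                                           same_day_multiple_cancer = 0.003,
                                           eligibility_gap = 0.015,
                                           missing_income = 0.012),
                       diagnosis_window = as.Date(c("2007-01-01", "2019-12-31")),
                       covariate_effects = list(age_per_year = 0.9,
                                                female = 18,
                                                rural = -12,
                                                per_year = -1),
                       dx_day_encounter_prob = 0.75,
                       gfobt_first_prob_by_quintile =
                         c(0.774, 0.765, 0.757, 0.748, 0.739),
                       same_day_prob_by_status = c(asymptomatic = 0.051,
                                                   symptomatic = 0.080),
                       interval_cap_days = 600) {
  cfg <- list(
    n_patients = n_patients,
    seed = as.integer(seed),
    quintile_probs = quintile_probs,
    asymptomatic_prob_by_quintile = asymptomatic_prob_by_quintile,
    ed_prob_by_quintile = ed_prob_by_quintile,
    interval_dist = interval_dist,
    background_rate = background_rate,
    surge_multiplier = surge_multiplier,
    referral_prob = referral_prob,
    exclusion_rates = exclusion_rates,
    diagnosis_window = as.Date(diagnosis_window),
    covariate_effects = covariate_effects,
    dx_day_encounter_prob = dx_day_encounter_prob,
    gfobt_first_prob_by_quintile = gfobt_first_prob_by_quintile,
    same_day_prob_by_status = same_day_prob_by_status,
    interval_cap_days = interval_cap_days,
    # per-quintile covariate distributions (calibrated to the published
    # cohort-characteristics table; see vignette)
    covariates = list(
      female_prob = c(0.511, 0.493, 0.485, 0.471, 0.478),
      rural_prob  = c(0.089, 0.080, 0.072, 0.061, 0.060),
      age_mean    = c(73, 72.5, 72, 71.5, 71),
      age_sd      = 13,
      comorbidity_lambda = c(2.15, 2.05, 2.00, 1.90, 1.88),
      adenocarcinoma_prob = 0.971,
      stage_probs = rbind(
        q1 = c(0.174, 0.253, 0.245, 0.175, 0.153),
        q2 = c(0.186, 0.252, 0.239, 0.170, 0.152),
        q3 = c(0.192, 0.247, 0.240, 0.174, 0.147),
        q4 = c(0.194, 0.246, 0.243, 0.177, 0.140),
        q5 = c(0.197, 0.250, 0.239, 0.174, 0.139))))
  validate_sim_config(cfg)
  cfg$interval_dist <- fit_interval_dist(cfg$interval_dist,
                                         cfg$same_day_prob_by_status)
  structure(cfg, class = "dx_sim_config")
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    abort(sprintf("invalid `%s`: %s", field, msg),
          class = "dx_config_error")
  }
  if (length(cfg$n_patients) != 1 || is.na(cfg$n_patients) ||
      cfg$n_patients < 0 || cfg$n_patients != floor(cfg$n_patients))
    stop_field("n_patients", "must be a single non-negative integer")
  prob_vec <- function(field, x, len = 5) {
    if (length(x) != len || anyNA(x) || any(x < 0) || any(x > 1))
      stop_field(field, sprintf("must be %d probabilities in [0, 1]", len))
  }
  prob_vec("quintile_probs", cfg$quintile_probs)
  if (abs(sum(cfg$quintile_probs) - 1) > 1e-6)
    stop_field("quintile_probs", "must sum to 1")
  prob_vec("asymptomatic_prob_by_quintile", cfg$asymptomatic_prob_by_quintile)
  prob_vec("ed_prob_by_quintile", cfg$ed_prob_by_quintile)
  prob_vec("gfobt_first_prob_by_quintile", cfg$gfobt_first_prob_by_quintile)
  if (cfg$surge_multiplier < 1)
    stop_field("surge_multiplier", "must be >= 1")
  if (anyNA(cfg$background_rate) || any(cfg$background_rate < 0))
    stop_field("background_rate", "must be non-negative")
  if (length(cfg$background_rate) > 1 && is.null(names(cfg$background_rate)))
    stop_field("background_rate",
               "per-category rates must be a named vector")
  prob_vec("referral_prob", cfg$referral_prob, len = 1)
  req <- c("death_before_diagnosis", "same_day_multiple_cancer",
           "eligibility_gap", "missing_income")
  if (!all(req %in% names(cfg$exclusion_rates)))
    stop_field("exclusion_rates",
               paste("must name rates:", paste(req, collapse = ", ")))
  prob_vec("exclusion_rates", cfg$exclusion_rates[req], len = 4)
  for (status in c("symptomatic", "asymptomatic")) {
    d <- cfg$interval_dist[[status]]
    if (is.null(d) || !d$family %in% c("lnorm", "gamma"))
      stop_field("interval_dist",
                 sprintf("`%s` must give family 'lnorm' or 'gamma'", status))
    if (length(d$median) != 5 || length(d$q90) != 5 ||
        any(d$median <= 0) || any(d$q90 <= d$median))
      stop_field("interval_dist",
                 sprintf("`%s` needs 5 medians and 5 q90s with q90 > median > 0",
                         status))
  }
  if (length(cfg$diagnosis_window) != 2 || anyNA(cfg$diagnosis_window) ||
      cfg$diagnosis_window[1] > cfg$diagnosis_window[2])
    stop_field("diagnosis_window", "must be an ordered pair of dates")
  prob_vec("same_day_prob_by_status", cfg$same_day_prob_by_status, len = 2)
  if (!all(c("asymptomatic", "symptomatic") %in%
           names(cfg$same_day_prob_by_status)))
    stop_field("same_day_prob_by_status",
               "must name 'asymptomatic' and 'symptomatic'")
  if (any(cfg$same_day_prob_by_status >= 0.5))
    stop_field("same_day_prob_by_status",
               "same-day mass must stay below the median (< 0.5)")
  if (length(cfg$interval_cap_days) != 1 || is.na(cfg$interval_cap_days) ||
      cfg$interval_cap_days < 90)
    stop_field("interval_cap_days", "must be a single value >= 90 days")
  invisible(cfg)
}

# Convert (median, q90) pairs into distribution parameters for the
# continuous part, so that the MIXTURE (same-day point mass at 1 day
# plus the continuous draw) has the stated median and 90th percentile:
# with mass p1 at one day, the continuous part must place its
# (0.5 - p1)/(1 - p1) and (0.9 - p1)/(1 - p1) quantiles at the stated
# values.
fit_interval_dist <- function(interval_dist, same_day_prob) {
  for (status in c("symptomatic", "asymptomatic")) {
    d <- interval_dist[[status]]
    p1 <- unname(same_day_prob[[status]])
    a1 <- (0.5 - p1) / (1 - p1)
    a2 <- (0.9 - p1) / (1 - p1)
    if (d$family == "lnorm") {
      z1 <- stats::qnorm(a1)
      z2 <- stats::qnorm(a2)
      sdlog <- log(d$q90 / d$median) / (z2 - z1)
      d$params <- tibble::tibble(
        quintile = 1:5,
        meanlog = log(d$median) - z1 * sdlog,
        sdlog = sdlog)
    } else {
      pars <- purrr::map2(d$median, d$q90, gamma_from_quantiles,
                          p_med = a1, p_q90 = a2)
      d$params <- tibble::tibble(
        quintile = 1:5,
        shape = purrr::map_dbl(pars, "shape"),
        scale = purrr::map_dbl(pars, "scale"))
    }
    interval_dist[[status]] <- d
  }
  interval_dist
}

# Solve for a gamma (shape, scale) placing its p_med and p_q90
# quantiles at `median` and `q90`.  The quantile ratio is strictly
# decreasing in shape, so a one-dimensional root on log(shape) works.
gamma_from_quantiles <- function(median, q90, p_med = 0.5, p_q90 = 0.9) {
  ratio <- q90 / median
  f <- function(logk) {
    k <- exp(logk)
    stats::qgamma(p_q90, shape = k) / stats::qgamma(p_med, shape = k) - ratio
  }
  logk <- stats::uniroot(f, c(log(1e-3), log(500)), tol = 1e-10)$root
  k <- exp(logk)
  list(shape = k, scale = median / stats::qgamma(p_med, shape = k))
}

#' Quantiles of the configured interval distribution
#'
#' Analytic quantiles of the true-interval mixture (same-day point
#' mass plus continuous part, pre-rounding and pre-covariate-shift)
#' for a given symptom status and quintile; the distribution oracle
#' used by recovery tests.
#'
#' @param config a [sim_config()] object.
#' @param status `"symptomatic"` or `"asymptomatic"`.
#' @param quintile income quintile 1--5.
#' @param probs probabilities.
#' @return numeric vector of interval quantiles in days.
#' @export
interval_dist_quantiles <- function(config, status, quintile,
                                    probs = c(0.25, 0.5, 0.75, 0.9)) {
  status <- match.arg(status, c("symptomatic", "asymptomatic"))
  d <- config$interval_dist[[status]]
  p <- d$params[d$params$quintile == quintile, ]
  p1 <- unname(config$same_day_prob_by_status[[status]])
  pc <- pmax((probs - p1) / (1 - p1), 0)
  q <- if (d$family == "lnorm") {
    stats::qlnorm(pc, p$meanlog, p$sdlog)
  } else {
    stats::qgamma(pc, shape = p$shape, scale = p$scale)
  }
  ifelse(probs <= p1, 1, q)
}

#' @export
print.dx_sim_config <- function(x, ...) {
  cat("<dx_sim_config>\n")
  cat("  patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  diagnosis window:", format(x$diagnosis_window[1]), "to",
      format(x$diagnosis_window[2]), "\n")
  cat("  background rate per 30-day bin:",
      if (length(x$background_rate) == 1) x$background_rate
      else sprintf("per-category (%.3g-%.3g)", min(x$background_rate),
                   max(x$background_rate)),
      "; surge x", x$surge_multiplier, "\n")
  cat("  referral probability:", x$referral_prob, "\n")
  invisible(x)
}
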