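# Independent oracles used to validate the optimized implementations.
# Each is a deliberately naive re-implementation of the rule text with
# plain loops, sharing no code with the package internals.

# Brute-force first-contact scan: for every encounter test eligibility
# directly; for every eligible procedure with a referrer scan every
# visit for the linkage rule; the index date is the minimum over all
# candidate dates.
oracle_index_date <- function(encounters, lookbacks, diagnosis_date) {
  lb <- stats::setNames(lookbacks$lookback_days, lookbacks$category)
  candidates <- as.Date(character())
  visits <- encounters[!encounters$procedure_flag &
                         encounters$source == "billing" &
                         !is.na(encounters$provider_id), ]
  for (i in seq_len(nrow(encounters))) {
    e <- encounters[i, ]
    if (!e$category %in% names(lb)) next
    d <- as.numeric(diagnosis_date - e$date)
    if (d < 0 || d > lb[[e$category]]) next
    candidates <- c(candidates, e$date)
    if (isTRUE(e$procedure_flag) && !is.na(e$referring_provider_id)) {
      best <- as.Date(NA)
      for (j in seq_len(nrow(visits))) {
        v <- visits[j, ]
        gap <- as.numeric(e$date - v$date)
        if (v$provider_id == e$referring_provider_id &&
            gap > 0 && gap < 365) {
          if (is.na(best) || v$date < best) best <- v$date
        }
      }
      if (!is.na(best)) candidates <- c(candidates, best)
    }
  }
  if (length(candidates) == 0) return(as.Date(NA))
  min(candidates)
}

# Rule-text symptom status: screening test or lower GI endoscopy,
# alone or with a consultation, not in the ED.
oracle_status <- function(categories, ed_flags) {
  screening <- c("gfobt", "lower_gi_endoscopy")
  consult <- c("consultation", "family_physician")
  has_screen <- FALSE
  only_allowed <- TRUE
  any_ed <- FALSE
  for (i in seq_along(categories)) {
    if (categories[i] %in% screening) has_screen <- TRUE
    if (!categories[i] %in% c(screening, consult)) only_allowed <- FALSE
    if (ed_flags[i]) any_ed <- TRUE
  }
  if (has_screen && only_allowed && !any_ed) "asymptomatic" else "symptomatic"
}

# Rule-text pathway table
oracle_pathway <- function(status, scope, imaging, ed) {
  if (status == "asymptomatic") return(1L)
  if (scope && !imaging && ed) return(2L)
  if (scope && !imaging && !ed) return(3L)
  if (scope && imaging && ed) return(4L)
  if (scope && imaging && !ed) return(5L)
  if (!scope && imaging && ed) return(6L)
  if (!scope && imaging && !ed) return(7L)
  if (!scope && !imaging && ed) return(8L)
  9L
}

# Exhaustive-search quantile regression: a check-loss minimiser always
# interpolates p observations, so enumerate every p-subset, solve the
# interpolation system, and keep the feasible solution with the lowest
# objective.
oracle_rq <- function(y, X, tau) {
  n <- length(y)
  p <- ncol(X)
  best <- NULL
  best_obj <- Inf
  for (rows in utils::combn(n, p, simplify = FALSE)) {
    Xb <- X[rows, , drop = FALSE]
    if (abs(det(Xb)) < 1e-10) next
    beta <- solve(Xb, y[rows])
    r <- y - X %*% beta
    obj <- sum(r * (tau - (r < 0)))
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- beta
    }
  }
  list(coefficients = drop(best), objective = best_obj)
}

# Small random encounter-set generator for interval-builder property
# tests.  Produces <= 10 encounters with random categories, dates,
# procedure flags and referral links around a fixed diagnosis date.
random_encounter_set <- function(seed) {
  set.seed(seed)
  dx <- as.Date("2015-06-01")
  n <- sample.int(10, 1)
  cats <- c("gfobt", "lower_gi_endoscopy", "consultation", "gi_symptoms",
            "imaging_ct", "family_physician", "other")
  procedure_cats <- c("lower_gi_endoscopy", "imaging_ct")
  category <- sample(cats, n, replace = TRUE)
  enc <- tibble::tibble(
    encounter_id = sprintf("E%02d", seq_len(n)),
    patient_id = "P1",
    date = dx - sample.int(900, n, replace = TRUE) + 1,
    source = sample(c("billing", "ED"), n, replace = TRUE, prob = c(.8, .2)),
    category = category,
    ed_flag = FALSE,
    provider_id = sample(1:4, n, replace = TRUE),
    referring_provider_id = ifelse(
      category %in% procedure_cats & stats::runif(n) < 0.6,
      sample(1:4, n, replace = TRUE), NA_integer_),
    procedure_flag = category %in% procedure_cats)
  enc$ed_flag <- enc$source == "ED"
  lb_cats <- sample(cats, sample(3:6, 1))
  lookbacks <- tibble::tibble(
    category = lb_cats,
    lookback_days = sample(c(90, 240, 360, 540, 810), length(lb_cats),
                           replace = TRUE))
  list(encounters = enc, lookbacks = lookbacks, diagnosis_date = dx)
}

# analysis-ready design matrix used by model tests
design_from_patients <- function(pts, adjusted = TRUE) {
  X <- cbind("(Intercept)" = rep(1, nrow(pts)),
             quintile1 = as.numeric(pts$quintile == 1),
             quintile2 = as.numeric(pts$quintile == 2),
             quintile3 = as.numeric(pts$quintile == 3),
             quintile4 = as.numeric(pts$quintile == 4))
  if (adjusted) {
    X <- cbind(X, age_c = pts$age - 65, female = as.numeric(pts$sex == "F"),
               rural = as.numeric(pts$rural), year_c = pts$dx_year - 2019)
  }
  X
}

# symptomatic config with a controlled quintile-1 shift of the
# conditional 90th percentile (other quintiles identical); delta = 0
# gives the zero-effect generator
coverage_config <- function(seed, delta, n_patients = 20000) {
  sim_config(
    n_patients = n_patients, seed = seed,
    interval_dist = list(
      symptomatic = list(family = "lnorm",
                         median = rep(116, 5),
                         q90 = c(392 + delta, 392, 392, 392, 392)),
      asymptomatic = list(family = "gamma",
                          median = rep(70, 5), q90 = rep(225, 5))))
}
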