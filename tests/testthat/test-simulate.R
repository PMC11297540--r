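test_that("empty cohort keeps all table schemas intact", {
  sim <- simulate_cohort(sim_config(n_patients = 0))
  expect_identical(nrow(sim$persons), 0L)
  expect_identical(nrow(sim$registry), 0L)
  expect_identical(nrow(sim$encounters), 0L)
  expect_identical(nrow(sim$ground_truth), 0L)
  expect_named(sim$persons,
               c("patient_id", "birth_date", "sex", "death_date",
                 "income_quintile", "rio_score", "comorbidity_count"))
  expect_named(sim$encounters,
               c("encounter_id", "patient_id", "date", "source", "code",
                 "ed_flag", "provider_id", "referring_provider_id",
                 "procedure_flag"))
})

test_that("identical config and seed reproduce identical tables", {
  cfg <- sim_config(n_patients = 120, seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  for (tb in c("persons", "registry", "eligibility", "encounters",
               "ground_truth")) {
    expect_identical(s1[[tb]], s2[[tb]])
  }
})

test_that("linked tables are referentially consistent with ground truth", {
  sim <- simulate_cohort(sim_config(n_patients = 150, seed = 4))
  expect_true(all(sim$encounters$patient_id %in% sim$persons$patient_id))
  expect_true(all(sim$registry$diagnosis_date >=
                    sim$config$diagnosis_window[1] &
                    sim$registry$diagnosis_date <=
                    sim$config$diagnosis_window[2]))
  gt <- sim$ground_truth
  expect_identical(nrow(gt), 150L)
  dx <- sim$registry$diagnosis_date[match(gt$patient_id,
                                          sim$registry$patient_id)]
  expect_true(all(gt$true_onset_date <= dx))
  expect_identical(gt$true_interval_days,
                   as.integer(dx - gt$true_onset_date) + 1L)
})

test_that("exclusion injections match their configured rates", {
  # no injections: everyone survives the cohort filter
  rates0 <- c(death_before_diagnosis = 0, same_day_multiple_cancer = 0,
              eligibility_gap = 0, missing_income = 0)
  sim <- simulate_cohort(sim_config(n_patients = 400, seed = 9,
                                    exclusion_rates = rates0))
  res <- apply_exclusions(sim$registry, sim$persons, sim$eligibility)
  expect_identical(nrow(res$cohort), 400L)
  expect_true(all(res$attrition$n_excluded == 0))

  # death-before-diagnosis at 5%: retained fraction within binomial error
  rates <- rates0
  rates["death_before_diagnosis"] <- 0.05
  cfg <- sim_config(n_patients = 10000, seed = 10, exclusion_rates = rates)
  pts <- simulate_patients(cfg)
  retained <- mean(!pts$excl_death)
  expect_lt(abs(retained - 0.95), 3 * sqrt(0.05 * 0.95 / 10000) + 1e-9)
})

test_that("realized quintile frequencies match quintile_probs", {
  cfg <- sim_config(n_patients = 10000, seed = 12)
  pts <- simulate_patients(cfg)
  freq <- as.numeric(table(factor(pts$quintile, levels = 1:5))) / 10000
  for (q in 1:5) {
    p <- cfg$quintile_probs[q]
    expect_lt(abs(freq[q] - p), 3.5 * sqrt(p * (1 - p) / 10000))
  }
})

test_that("no surge means equal rates in recent and baseline windows", {
  cfg <- sim_config(n_patients = 1200, seed = 21, surge_multiplier = 1,
                    referral_prob = 0)
  sim <- simulate_cohort(cfg)
  enc <- categorize_encounters(sim$encounters)
  diagnoses <- dplyr::distinct(sim$registry, patient_id, diagnosis_date)
  prof <- build_category_profiles(enc, diagnoses)
  # categories with no onset-event mechanism are pure Poisson background
  for (cc in c("imaging_ct", "lab_general")) {
    p <- prof[prof$category == cc, ]
    recent <- sum(p$count[p$bin %in% 0:2])
    baseline <- sum(p$count[p$bin %in% 24:26])
    # difference of two Poisson totals with equal rates
    expect_lt(abs(recent - baseline),
              4 * sqrt(recent + baseline + 1))
  }
})

test_that("forced referrals always leave a linkable prior visit", {
  cfg <- sim_config(n_patients = 60, seed = 31, referral_prob = 1)
  sim <- simulate_cohort(cfg)
  enc <- categorize_encounters(sim$encounters)
  procs <- enc[!is.na(enc$referring_provider_id), ]
  expect_gt(nrow(procs), 0)
  for (i in seq_len(nrow(procs))) {
    p <- procs[i, ]
    visits <- enc[enc$patient_id == p$patient_id & !enc$procedure_flag &
                    enc$source == "billing", ]
    hit <- link_referring_visit(p, visits)
    expect_identical(nrow(hit), 1L)
    expect_true(as.numeric(p$date - hit$date) > 0)
    expect_true(as.numeric(p$date - hit$date) < 365)
  }
})

test_that("asymptomatic onset encounters are screening tests outside the ED", {
  cfg <- sim_config(n_patients = 250, seed = 41)
  sim <- simulate_cohort(cfg)
  gt <- sim$ground_truth
  asym <- gt[gt$true_status == "asymptomatic", ]
  enc <- categorize_encounters(sim$encounters)
  for (i in seq_len(nrow(asym))) {
    onset_enc <- enc[enc$patient_id == asym$patient_id[i] &
                       enc$date == asym$true_onset_date[i], ]
    expect_gt(nrow(onset_enc), 0)
    expect_false(any(onset_enc$ed_flag))
    expect_true(any(onset_enc$category %in% c("gfobt", "lower_gi_endoscopy")))
  }
})

test_that("onset after diagnosis is an internal consistency error", {
  cfg <- sim_config(n_patients = 5, seed = 1)
  expect_error(
    generate_encounter_history(cfg, "P000001", as.Date("2015-01-01"),
                               as.Date("2015-02-01"), "symptomatic", 1),
    class = "dx_internal_error")
})
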