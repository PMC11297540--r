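test_that("symptom status follows the screening-first-encounter rule", {
  expect_identical(classify_symptom_status("gfobt", FALSE), "asymptomatic")
  expect_identical(classify_symptom_status("lower_gi_endoscopy", TRUE),
                   "symptomatic")   # scope in the ED
  expect_identical(classify_symptom_status("consultation", FALSE),
                   "symptomatic")   # consultation without a screening test
  expect_identical(
    classify_symptom_status(c("lower_gi_endoscopy", "consultation"),
                            c(FALSE, FALSE)),
    "asymptomatic")
  expect_identical(
    classify_symptom_status(c("gfobt", "gi_symptoms"), c(FALSE, FALSE)),
    "symptomatic")   # non-screening co-encounter
  expect_error(classify_symptom_status(character(0), logical(0)),
               class = "dx_contract_error")
})

test_that("status matches the rule-text oracle over all category subsets", {
  cats <- c("gfobt", "lower_gi_endoscopy", "consultation",
            "family_physician", "gi_symptoms", "imaging_ct", "other")
  for (size in 1:3) {
    for (subset in utils::combn(cats, size, simplify = FALSE)) {
      for (ed in c(TRUE, FALSE)) {
        flags <- rep(ed, size)
        expect_identical(classify_symptom_status(subset, flags),
                         oracle_status(subset, flags),
                         label = paste(paste(subset, collapse = "+"),
                                       "ed =", ed))
      }
    }
  }
})

test_that("the symptomatic grid hits pathway codes 2-9 exactly once", {
  grid <- expand.grid(scope = c(TRUE, FALSE), imaging = c(TRUE, FALSE),
                      ed = c(TRUE, FALSE))
  codes <- assign_pathway(rep("symptomatic", 8), grid$scope, grid$imaging,
                          grid$ed)
  expect_setequal(codes, 2:9)
  expect_identical(anyDuplicated(codes), 0L)
  # asymptomatic dominates every combination
  expect_identical(unique(assign_pathway(rep("asymptomatic", 8), grid$scope,
                                         grid$imaging, grid$ed)), 1L)
})

test_that("index features derive from the built interval", {
  dx <- as.Date("2015-06-01")
  lb <- tibble::tibble(category = c("lower_gi_endoscopy", "gi_symptoms"),
                       lookback_days = c(360, 360))
  enc <- tibble::tibble(
    encounter_id = c("E1", "E2", "E3", "E4"),
    patient_id = "P1",
    date = c(dx - 60, dx - 10, dx, dx - 150),
    source = c("billing", "billing", "billing", "billing"),
    category = c("lower_gi_endoscopy", "lower_gi_endoscopy", "gi_symptoms",
                 "consultation"),
    ed_flag = FALSE,
    provider_id = c(7L, 7L, 7L, 42L),
    referring_provider_id = c(42L, NA, NA, NA),
    procedure_flag = c(TRUE, TRUE, FALSE, FALSE))
  iv <- build_intervals(enc, lb, tibble::tibble(patient_id = "P1",
                                                diagnosis_date = dx))
  pw <- classify_pathways(iv, enc)
  expect_true(pw$referring_first_contact)    # index from the linked visit
  expect_false(pw$diagnosed_on_index)
  expect_identical(pw$scope_count, 2L)       # two scopes inside the interval
  expect_identical(pw$status, "symptomatic") # consultation-only index date
  expect_identical(pw$pathway, 3L)           # scope, no imaging, not ED

  # a one-day interval flags diagnosis on the index date
  enc1 <- enc[3, ]
  iv1 <- build_intervals(enc1, lb, tibble::tibble(patient_id = "P1",
                                                  diagnosis_date = dx))
  pw1 <- classify_pathways(iv1, enc1)
  expect_true(pw1$diagnosed_on_index)
  expect_identical(iv1$interval_days, 1L)
})

test_that("every classified patient gets exactly one coherent pathway", {
  sim <- simulate_cohort(sim_config(n_patients = 400, seed = 61))
  enc <- categorize_encounters(sim$encounters)
  diagnoses <- dplyr::distinct(sim$registry, patient_id, diagnosis_date)
  lb <- build_lookback_table(build_category_profiles(enc, diagnoses))
  iv <- build_intervals(enc, lb, diagnoses)
  pw <- classify_pathways(iv, enc)
  expect_identical(nrow(pw), sum(!iv$unidentifiable))
  expect_identical(anyDuplicated(pw$patient_id), 0L)
  expect_true(all(pw$pathway[pw$status == "asymptomatic"] == 1L))
  expect_true(all(pw$pathway[pw$status == "symptomatic"] %in% 2:9))
  expect_false(any(pw$ed_at_index[pw$status == "asymptomatic"]))
  expect_identical(pw$diagnosed_on_index, pw$patient_id %in%
                     iv$patient_id[!is.na(iv$interval_days) &
                                     iv$interval_days == 1L])
})

test_that("random encounter sets classify identically to the rule text", {
  set.seed(71)
  cats <- c("gfobt", "lower_gi_endoscopy", "consultation",
            "family_physician", "gi_symptoms", "imaging_ct", "other")
  for (i in 1:2000) {
    k <- sample.int(3, 1)
    categories <- sample(cats, k, replace = TRUE)
    flags <- stats::runif(k) < 0.3
    got <- classify_symptom_status(categories, flags)
    expect_identical(got, oracle_status(categories, flags))
    scope <- any(categories == "lower_gi_endoscopy")
    imaging <- any(categories == "imaging_ct")
    expect_identical(assign_pathway(got, scope, imaging, any(flags)),
                     oracle_pathway(got, scope, imaging, any(flags)))
  }
})
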