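#' Run the full diagnostic-interval pipeline
#'
#' Orchestrates simulate -> cohort exclusions -> encounter profiling and
#' SPC lookbacks -> interval construction -> pathway classification ->
#' descriptive tables -> quantile-regression report, from a single
#' simulation configuration.  Optionally persists every output table
#' plus a manifest (configuration hash, seed, row counts) so a rerun
#' with the same configuration reproduces the bundle byte for byte.
#'
#' @param config a [sim_config()] object (the generator is the input
#'   source; to analyse pre-existing tables call the stage functions
#'   directly).
#' @param spc list of lookback parameters: `k`, `persistence`,
#'   `min_ratio`, `min_count`.
#' @param model list of model parameters: `taus`, `B`, `strata`,
#'   `min_n`.
#' @param out_dir output directory; `NULL` skips writing.
#' @return (invisibly when writing) an object of class `dx_pipeline`:
#'   list with `simulation`, `attrition`, `lookbacks`, `intervals`,
#'   `pathways`, `analysis` (per-patient analysis cohort),
#'   `table_characteristics`, `table_features`, `table_intervals`,
#'   `models`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(sim_config(n_patients = 500, seed = 1),
#'                     model = list(taus = 0.5, B = 100))
#' res$attrition
#' }
run_pipeline <- function(config,
                         spc = list(),
                         model = list(),
                         out_dir = NULL) {
  spc <- utils::modifyList(
    list(k = 2, persistence = 2, min_ratio = 1, min_count = 5), spc)
  model <- utils::modifyList(
    list(taus = c(0.5, 0.9), B = 1000, strata = "status", min_n = 50), model)

  message("[simulate] n_patients = ", config$n_patients,
          ", seed = ", config$seed)
  sim <- simulate_cohort(config)
  message("[simulate] encounters: ", nrow(sim$encounters))

  message("[cohort] applying exclusions")
  excl <- apply_exclusions(sim$registry, sim$persons, sim$eligibility)
  attrition <- excl$attrition
  cohort <- excl$cohort

  enc <- categorize_encounters(sim$encounters)
  diagnoses <- cohort[, c("patient_id", "diagnosis_date")]
  enc_cohort <- dplyr::semi_join(enc, diagnoses, by = "patient_id")

  message("[profiles] building 27-bin category profiles")
  profiles <- build_category_profiles(enc_cohort, diagnoses)
  lookbacks <- build_lookback_table(profiles, min_ratio = spc$min_ratio,
                                    min_count = spc$min_count,
                                    k = spc$k, persistence = spc$persistence)
  message("[profiles] selected categories: ",
          paste(lookbacks$category, collapse = ", "))

  message("[intervals] earliest eligible encounter per patient")
  intervals <- build_intervals(enc_cohort, lookbacks, diagnoses)
  n_unident <- sum(intervals$unidentifiable)
  attrition <- append_attrition(attrition,
                                "first contact not identifiable", n_unident)
  message("[intervals] unidentifiable first contact: ", n_unident)

  pathways <- classify_pathways(intervals, enc_cohort)

  analysis <- cohort %>%
    dplyr::inner_join(
      intervals %>% dplyr::filter(!.data$unidentifiable) %>%
        dplyr::select("patient_id", "index_date", "interval_days",
                      "referral_extended"),
      by = "patient_id") %>%
    dplyr::inner_join(
      pathways %>% dplyr::select(-"first_encounter_categories"),
      by = "patient_id") %>%
    dplyr::mutate(
      quintile = .data$income_quintile,
      age = floor(as.numeric(.data$diagnosis_date - .data$birth_date) / 365.25),
      age_group = cut(.data$age, c(-Inf, 50, 60, 70, 80, Inf),
                      labels = c("<=50", "51-60", "61-70", "71-80", ">80")),
      rural = .data$rio_score >= 45,
      dx_year = as.integer(format(.data$diagnosis_date, "%Y")),
      comorbidity_ge4 = dplyr::if_else(.data$comorbidity_count >= 4,
                                       "ge_4", "lt_4"),
      histology = dplyr::if_else(.data$morphology == "8140/3",
                                 "adenocarcinoma", "other"))

  message("[descriptives] stratified tables")
  tbl_chars <- purrr::map_dfr(
    c("age_group", "sex", "rural", "comorbidity_ge4", "histology", "stage"),
    function(v) {
      rlang::inject(stratified_counts(analysis, !!rlang::sym(v), quintile))
    })
  tbl_feats <- purrr::map_dfr(
    c("diagnosed_on_index", "referring_first_contact", "ed_at_index",
      "pathway"),
    function(v) {
      analysis %>%
        dplyr::group_by(.data$status) %>%
        dplyr::group_modify(~ rlang::inject(
          stratified_counts(.x, !!rlang::sym(v), quintile))) %>%
        dplyr::ungroup()
    })
  tbl_intervals <- interval_summary(analysis, interval_days, status, quintile)

  message("[models] quantile regression (taus: ",
          paste(model$taus, collapse = ", "), ", B = ", model$B, ")")
  models <- run_quantile_models(analysis, taus = model$taus,
                                strata = model$strata, B = model$B,
                                seed = config$seed, min_n = model$min_n)

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    n_simulated = config$n_patients,
    n_cohort = nrow(analysis),
    n_encounters = nrow(sim$encounters),
    selected_categories = lookbacks$category,
    taus = model$taus,
    bootstrap_B = model$B)

  result <- structure(
    list(simulation = sim, attrition = attrition, lookbacks = lookbacks,
         intervals = intervals, pathways = pathways, analysis = analysis,
         table_characteristics = tbl_chars, table_features = tbl_feats,
         table_intervals = tbl_intervals, models = models,
         manifest = manifest),
    class = "dx_pipeline")

  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
    return(invisible(result))
  }
  result
}

#' Persist a pipeline result as a CSV/JSON bundle
#'
#' Writes every output table as RFC-4180 CSV (UTF-8, ISO-8601 dates),
#' the model report additionally as JSON, and the manifest as JSON.
#' On failure, files written so far are removed so no partial bundle
#' survives.
#'
#' @param result a `dx_pipeline` object.
#' @param out_dir directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "dx_pipeline"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  put_csv <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(flatten_list_cols(df), path)
    written <<- c(written, path)
  }
  tryCatch({
    put_csv(result$attrition, "attrition.csv")
    put_csv(result$lookbacks, "lookbacks.csv")
    put_csv(result$intervals, "intervals.csv")
    put_csv(result$pathways, "pathways.csv")
    put_csv(result$analysis, "analysis_cohort.csv")
    put_csv(result$table_characteristics, "table_characteristics.csv")
    put_csv(result$table_features, "table_features.csv")
    put_csv(result$table_intervals, "table_intervals.csv")
    put_csv(as.data.frame(result$models), "model_report.csv")
    mj <- file.path(out_dir, "model_report.json")
    jsonlite::write_json(as.data.frame(result$models), mj, digits = NA)
    written <- c(written, mj)
    mf <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(result$manifest, mf, auto_unbox = TRUE, digits = NA)
    written <- c(written, mf)
  }, error = function(e) {
    unlink(written)
    abort(paste("failed to write pipeline outputs:", conditionMessage(e)),
          parent = e)
  })
  invisible(written)
}

# serialize list-columns (id sets) as ;-joined strings for CSV output
flatten_list_cols <- function(df) {
  is_list <- vapply(df, is.list, logical(1))
  for (nm in names(df)[is_list]) {
    df[[nm]] <- vapply(df[[nm]], function(x) {
      paste(x, collapse = ";")
    }, character(1))
  }
  df
}

#' @export
print.dx_pipeline <- function(x, ...) {
  cat("<dx_pipeline>\n")
  cat("  cohort:", x$manifest$n_cohort, "of", x$manifest$n_simulated,
      "simulated patients\n")
  cat("  selected categories:",
      paste(x$manifest$selected_categories, collapse = ", "), "\n")
  cat("  model rows:", nrow(x$models), "\n")
  invisible(x)
}
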