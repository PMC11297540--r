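#' Assign encounter categories from a code map
#'
#' Maps every encounter's service code to exactly one analysis
#' category.  Codes absent from the map fall into `"other"`; no
#' de-duplication happens at this stage (two same-day encounters with
#' different codes both survive, with their own categories).
#'
#' @param encounters tibble with at least `code`.
#' @param codemap tibble with `code`, `category`
#'   (default [default_codemap()]).
#' @return `encounters` with a `category` column.
#' @export
categorize_encounters <- function(encounters, codemap = default_codemap()) {
  if (is.null(codemap) || nrow(codemap) == 0) {
    abort("empty codemap: at least one code -> category mapping is required",
          class = "dx_config_error")
  }
  check_columns(encounters, "code", "encounters")
  check_columns(codemap, c("code", "category"), "codemap")
  encounters %>%
    dplyr::left_join(codemap, by = "code") %>%
    dplyr::mutate(category = dplyr::coalesce(.data$category, "other"))
}

#' Pre-diagnosis encounter frequency profiles
#'
#' Pools, per category, the number of encounters in each 30-day bin
#' before diagnosis.  Bin 0 covers days 1--30 pre-diagnosis, bin
#' `n_bins - 1` the oldest window (with 27 bins: days 781--810, i.e.
#' the 24--27-month baseline lives in bins 24--26).  Encounters on or
#' after the diagnosis date contribute to no bin.
#'
#' @param encounters categorized encounters (`patient_id`, `date`,
#'   `category`).
#' @param diagnoses tibble with `patient_id`, `diagnosis_date`.
#' @param n_bins number of 30-day bins (default 27, a 2-year-plus
#'   lookback horizon).
#' @return tibble with columns `category`, `bin` (0-based), `count`,
#'   complete over all `n_bins` bins for every observed category, with
#'   attribute `n_patients`.
#' @export
build_category_profiles <- function(encounters, diagnoses, n_bins = 27) {
  check_columns(encounters, c("patient_id", "date", "category"), "encounters")
  check_columns(diagnoses, c("patient_id", "diagnosis_date"), "diagnoses")
  binned <- encounters %>%
    dplyr::inner_join(diagnoses[, c("patient_id", "diagnosis_date")],
                      by = "patient_id") %>%
    dplyr::mutate(d = as.numeric(.data$diagnosis_date - .data$date)) %>%
    dplyr::filter(.data$d >= 1, .data$d <= n_bins * 30) %>%
    dplyr::mutate(bin = as.integer(floor((.data$d - 1) / 30)))
  profiles <- binned %>%
    dplyr::count(.data$category, .data$bin, name = "count") %>%
    tidyr::complete(category = unique(encounters$category),
                    bin = 0:(n_bins - 1),
                    fill = list(count = 0L)) %>%
    dplyr::arrange(.data$category, .data$bin)
  attr(profiles, "n_patients") <- dplyr::n_distinct(diagnoses$patient_id)
  profiles
}

#' Select cancer-associated encounter categories
#'
#' A category is cancer-associated when encounters of that category
#' occur more frequently in the 0--3 months before diagnosis than in
#' the 24--27-month baseline: mean count over bins 0--2 strictly
#' greater than `min_ratio` times the mean over bins 24--26, with at
#' least `min_count` encounters in bins 0--2.
#'
#' @param profiles output of [build_category_profiles()].
#' @param min_ratio required recent/baseline ratio (strict inequality).
#' @param min_count minimum total count in bins 0--2.
#' @return tibble with `category`, `mean_recent`, `mean_baseline`,
#'   `ratio`, `selected`.
#' @export
select_cancer_associated <- function(profiles, min_ratio = 1.0, min_count = 5) {
  check_columns(profiles, c("category", "bin", "count"), "profiles")
  profiles %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(
      mean_recent = mean(.data$count[.data$bin %in% 0:2]),
      total_recent = sum(.data$count[.data$bin %in% 0:2]),
      mean_baseline = mean(.data$count[.data$bin %in% 24:26]),
      .groups = "drop") %>%
    dplyr::mutate(
      ratio = .data$mean_recent / .data$mean_baseline,
      selected = .data$mean_recent > min_ratio * .data$mean_baseline &
        .data$total_recent >= min_count)
}

#' Category lookback window by statistical process control
#'
#' Runs a Shewhart-style count chart on one category's binned
#' pre-diagnosis profile.  The upper control limit is
#' \eqn{\mu + k \max(\sqrt{\mu}, 1)} (Poisson-motivated sigma with a
#' floor of one count); because bin counts are integers, a bin signals
#' only when its count strictly exceeds the smallest integer at or
#' above the limit.  Scanning from the oldest bin towards diagnosis,
#' the crossing bin is the largest bin index `b` such that bins
#' `b, b-1, ..., b-persistence+1` all signal **and** the elevation is
#' sustained (at least `sustained_frac` of bins `b..0` signal) -- a
#' lookback window asserts elevated cancer-related contact over its
#' whole span, so an isolated distant pair of noisy bins must not set
#' it.  The lookback is `(b + 1) * 30` days; without any qualifying
#' crossing it falls back to 90 days (the 0--3 month selection
#' window).
#'
#' The baseline mean \eqn{\mu} is first estimated from the oldest six
#' bins and then, in standard Phase-I fashion, re-estimated from all
#' bins older than the detected crossing (iterated to a fixed point):
#' a three-bin baseline is too noisy for reliable changepoint
#' placement at realistic per-bin counts.
#'
#' @param counts integer vector of length `>= 27`: per-bin counts,
#'   bin 0 first.  A tibble row-set from [build_category_profiles()]
#'   for a single category is also accepted.
#' @param k control-limit multiplier (default 2, a liberal two-sigma
#'   limit).
#' @param persistence number of consecutive elevated bins required to
#'   declare a crossing.
#' @param sustained_frac minimum fraction of bins between the crossing
#'   and diagnosis that must signal.
#' @return one-row tibble: `lookback_days`, `baseline_mean`, `ucl`
#'   (both from the final baseline), `crossing_bin` (NA when the
#'   fallback applies).
#' @export
#' @examples
#' counts <- c(rep(20, 8), rep(4, 19))   # elevated bins 0-7
#' spc_lookback(counts)
spc_lookback <- function(counts, k = 2.0, persistence = 2,
                         sustained_frac = 0.8) {
  if (is.data.frame(counts)) {
    check_columns(counts, c("bin", "count"), "profile")
    counts <- counts$count[order(counts$bin)]
  }
  if (length(counts) < 27) {
    abort("profile must supply at least 27 bins", class = "dx_schema_error")
  }
  nb <- length(counts)
  declare <- function(mu) {
    ucl <- mu + k * max(sqrt(mu), 1)
    above <- counts > ceiling(ucl - 1e-9)
    crossing <- NA_integer_
    for (b in (nb - 1):(persistence - 1)) {      # 0-based bins, oldest first
      run <- above[(b - persistence + 2):(b + 1)]
      if (all(run) && mean(above[1:(b + 1)]) >= sustained_frac) {
        crossing <- b
        break
      }
    }
    list(crossing = crossing, ucl = ucl)
  }
  mu <- mean(counts[(nb - 5):nb])                # oldest six bins
  res <- declare(mu)
  for (i in 1:3) {                               # Phase-I trimming
    b <- res$crossing
    if (is.na(b) || b > nb - 4) break
    mu2 <- mean(counts[(b + 2):nb])
    res2 <- declare(mu2)
    if (isTRUE(res2$crossing == b)) { mu <- mu2; res <- res2; break }
    mu <- mu2
    res <- res2
  }
  crossing <- res$crossing
  lookback <- if (is.na(crossing)) 90 else (crossing + 1) * 30
  tibble::tibble(lookback_days = as.numeric(lookback),
                 baseline_mean = mu, ucl = res$ucl,
                 crossing_bin = crossing)
}

#' Build the category lookback table
#'
#' Applies [select_cancer_associated()] then [spc_lookback()] to every
#' selected category, returning the table used to gate encounter
#' eligibility in [build_intervals()].
#'
#' @inheritParams select_cancer_associated
#' @inheritParams spc_lookback
#' @return tibble with one row per selected category: `category`,
#'   `lookback_days`, `baseline_mean`, `ucl`, `crossing_bin`,
#'   `mean_recent`, `mean_baseline`, `ratio`.
#' @export
build_lookback_table <- function(profiles, min_ratio = 1.0, min_count = 5,
                                 k = 2.0, persistence = 2) {
  sel <- select_cancer_associated(profiles, min_ratio, min_count)
  chosen <- sel$category[sel$selected]
  spc <- purrr::map_dfr(chosen, function(cc) {
    dplyr::bind_cols(
      tibble::tibble(category = cc),
      spc_lookback(profiles[profiles$category == cc, ], k, persistence))
  })
  if (nrow(spc) == 0) {
    spc <- tibble::tibble(category = character(), lookback_days = numeric(),
                          baseline_mean = numeric(), ucl = numeric(),
                          crossing_bin = integer())
  }
  dplyr::left_join(spc,
                   sel[, c("category", "mean_recent", "mean_baseline", "ratio")],
                   by = "category")
}
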