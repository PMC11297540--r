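#' Fit a conditional-quantile regression by check-loss minimisation
#'
#' Estimates coefficients minimising the check loss
#' \eqn{\sum_i \rho_\tau(y_i - x_i'\beta)},
#' \eqn{\rho_\tau(u) = u(\tau - 1\{u < 0\})}, solved exactly as a
#' linear program via a Frisch--Newton primal-dual interior-point
#' method (compiled).  The subgradient optimality condition
#' \eqn{\#\{r_i < 0\} \le n\tau \le \#\{r_i \le 0\}} is verified on
#' the returned solution.
#'
#' @param y numeric outcome vector (e.g. interval days).
#' @param X design matrix with named columns, including the intercept.
#' @param tau quantile level in (0, 1).
#' @param eps relative duality-gap tolerance.
#' @return object of class `dx_qfit`: list with `coefficients`
#'   (named), `tau`, `n`, `residuals`, `objective`, `converged`,
#'   `subgradient_ok`.
#' @export
#' @examples
#' y <- c(2, 5, 9, 1, 7, 3, 8)
#' fit <- fit_quantile(y, matrix(1, 7, 1, dimnames = list(NULL, "(Intercept)")),
#'                     tau = 0.5)
#' fit$coefficients   # the sample median
fit_quantile <- function(y, X, tau, eps = 1e-10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!(tau > 0 && tau < 1)) {
    abort("tau must lie strictly inside (0, 1)", class = "dx_contract_error")
  }
  if (nrow(X) <= ncol(X)) {
    abort("need more observations than model terms",
          class = "dx_contract_error")
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[-qr_x$pivot[seq_len(qr_x$rank)]]
    abort(sprintf("design matrix is rank deficient; collinear term(s): %s",
                  paste(dropped, collapse = ", ")),
          class = "dx_design_error")
  }
  fit <- qrfn_fit(X, y, tau, eps = eps)
  # a final relative duality gap below 1e-7 is solved for all practical
  # purposes even when the target eps was not reached within maxit
  converged <- fit$converged || fit$rel_gap < 1e-7
  beta <- drop(fit$coefficients)
  names(beta) <- colnames(X)
  r <- y - drop(X %*% beta)
  n <- length(y)
  ztol <- 1e-6 * (1 + stats::sd(y))
  sub_ok <- sum(r < -ztol) <= n * tau && n * tau <= sum(r <= ztol)
  if (!converged) {
    warn("quantile-regression solver did not converge; solution flagged")
  }
  structure(list(coefficients = beta, tau = tau, n = n,
                 residuals = r,
                 objective = check_loss(r, tau),
                 converged = converged,
                 iterations = fit$iterations,
                 subgradient_ok = sub_ok),
            class = "dx_qfit")
}

#' Check loss of a residual vector
#'
#' @param r residuals.
#' @param tau quantile level.
#' @return \eqn{\sum_i \rho_\tau(r_i)}.
#' @export
check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

#' Pair-bootstrap confidence intervals for quantile regression
#'
#' Nonparametric bootstrap resampling rows of `(y, X)` with
#' replacement, refitting, and taking percentile bounds.  Resamples
#' that lose column rank (or fail to converge) are redrawn and
#' counted.  Deterministic given `seed`.
#'
#' @inheritParams fit_quantile
#' @param B number of bootstrap resamples (at least 100).
#' @param seed integer seed; `NULL` continues the current RNG stream.
#' @param level confidence level.
#' @return tibble `term`, `estimate`, `conf.low`, `conf.high`,
#'   `se_boot`, `p_value`, with attributes `draws` (B x p matrix) and
#'   `redraws`.  The p-value is a normal approximation using the
#'   bootstrap standard error.
#' @export
bootstrap_ci <- function(y, X, tau, B = 1000, seed = NULL, level = 0.95) {
  if (B < 100) {
    abort("B must be at least 100 for percentile intervals",
          class = "dx_contract_error")
  }
  fit <- fit_quantile(y, X, tau)
  if (!is.null(seed)) set.seed(seed)
  bt <- qrfn_boot(as.matrix(X), y, tau, B = as.integer(B))
  draws <- bt$draws
  colnames(draws) <- names(fit$coefficients)
  a <- (1 - level) / 2
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  se <- apply(draws, 2, stats::sd)
  est <- fit$coefficients
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    conf.low = qs[1, ],
    conf.high = qs[2, ],
    se_boot = unname(se),
    p_value = 2 * stats::pnorm(-abs(unname(est)) / unname(se)))
  attr(out, "draws") <- draws
  attr(out, "redraws") <- bt$redraws
  attr(out, "converged") <- fit$converged
  out
}

# Design matrix for the income-inequality models: quintile dummies with
# quintile 5 (highest income) as reference; adjusted models add age
# centred at 65, sex (male reference), rural residence and diagnosis
# year centred at 2019.  Comorbidity and stage are causal-pathway
# variables and never enter.
build_design <- function(data, adjusted) {
  check_columns(data, "quintile", "data")
  X <- cbind("(Intercept)" = rep(1, nrow(data)),
             quintile1 = as.numeric(data$quintile == 1),
             quintile2 = as.numeric(data$quintile == 2),
             quintile3 = as.numeric(data$quintile == 3),
             quintile4 = as.numeric(data$quintile == 4))
  if (adjusted) {
    check_columns(data, c("age", "sex", "rural", "dx_year"), "data")
    X <- cbind(X,
               age_c = data$age - 65,
               female = as.numeric(data$sex == "F"),
               rural = as.numeric(data$rural),
               year_c = data$dx_year - 2019)
  }
  X
}

#' Quantile-regression report for income-quintile inequalities
#'
#' Fits, per stratum and per quantile level, unadjusted (income
#' quintiles only, quintile 5 reference) and adjusted (plus age
#' centred at 65, sex with male reference, rural residence, diagnosis
#' year centred at 2019) quantile regressions of the diagnostic
#' interval, with pair-bootstrap confidence intervals.  Comorbidity
#' and stage are treated as causal-pathway variables and never
#' adjusted for; to examine stage, stratify on it via `strata`.
#'
#' @param data analysis cohort: one row per patient with
#'   `interval_days` (or the column named by `outcome`), `quintile`,
#'   `age`, `sex`, `rural`, `dx_year`, and the strata columns.
#' @param outcome name of the outcome column (days).
#' @param taus quantile levels (default 50th and 90th percentiles; the
#'   10th is available but off by default).
#' @param strata character vector of stratifying columns (default
#'   symptom `status`; add `"stage"` for stage-stratified runs).
#' @param models which of `"unadjusted"`, `"adjusted"` to fit.
#' @param B bootstrap resamples per fit.
#' @param seed integer seed governing all bootstrap randomness.
#' @param level confidence level.
#' @param min_n strata smaller than this are skipped with a warning.
#' @return tibble of class `dx_quantile_report`: one row per
#'   (stratum, tau, model, term) with `estimate`, `conf.low`,
#'   `conf.high`, `se_boot`, `p_value`, `n`, `converged`.
#' @export
run_quantile_models <- function(data, outcome = "interval_days",
                                taus = c(0.5, 0.9),
                                strata = "status",
                                models = c("unadjusted", "adjusted"),
                                B = 1000, seed = 1, level = 0.95,
                                min_n = 50) {
  check_columns(data, c(outcome, "quintile", strata), "data")
  models <- match.arg(models, c("unadjusted", "adjusted"),
                      several.ok = TRUE)
  set.seed(seed)
  strata_tbl <- data %>%
    dplyr::distinct(dplyr::across(dplyr::all_of(strata))) %>%
    dplyr::arrange(dplyr::across(dplyr::all_of(strata)))

  rows <- list()
  for (i in seq_len(nrow(strata_tbl))) {
    sub <- dplyr::semi_join(data, strata_tbl[i, , drop = FALSE], by = strata)
    label <- paste(unlist(strata_tbl[i, ]), collapse = "/")
    if (nrow(sub) < min_n) {
      warn(sprintf("stratum '%s' has n=%d < %d; skipped",
                   label, nrow(sub), min_n))
      next
    }
    y <- sub[[outcome]]
    for (model in models) {
      X <- build_design(sub, adjusted = model == "adjusted")
      for (tau in taus) {
        ci <- bootstrap_ci(y, X, tau, B = B, level = level)
        rows[[length(rows) + 1]] <- ci %>%
          dplyr::mutate(stratum = label, tau = tau, model = model,
                        n = nrow(sub), converged = attr(ci, "converged"),
                        .before = 1)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "strata") <- strata
  structure(out, class = c("dx_quantile_report", class(out)))
}

#' @export
print.dx_qfit <- function(x, ...) {
  cat(sprintf("<dx_qfit> tau = %.2f, n = %d, objective = %.4f%s\n",
              x$tau, x$n, x$objective,
              if (x$converged) "" else " (NOT converged)"))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quantile-regression fit
#'
#' @param x a `dx_qfit`.
#' @param ... unused.
#' @return tibble `term`, `estimate`.
#' @export
tidy.dx_qfit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' One-row summary of a quantile-regression fit
#'
#' @param x a `dx_qfit`.
#' @param ... unused.
#' @return tibble `tau`, `n`, `objective`, `converged`,
#'   `subgradient_ok`.
#' @export
glance.dx_qfit <- function(x, ...) {
  tibble::tibble(tau = x$tau, n = x$n, objective = x$objective,
                 converged = x$converged, subgradient_ok = x$subgradient_ok)
}
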