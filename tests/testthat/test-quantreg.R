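icol <- function(n) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

test_that("intercept-only median fit equals the sample median", {
  set.seed(14)
  y <- rnorm(101)   # odd n: the check-loss minimiser is unique
  fit <- fit_quantile(y, icol(101), tau = 0.5)
  expect_equal(unname(fit$coefficients), median(y))
  expect_true(fit$subgradient_ok)
})

test_that("intercept-only fits land on the empirical quantile bracket", {
  set.seed(15)
  y <- rexp(200)
  for (tau in c(0.1, 0.5, 0.9)) {
    fit <- fit_quantile(y, icol(200), tau = tau)
    b <- unname(fit$coefficients)
    # optimal solutions lie between adjacent order statistics around n*tau
    lo <- sort(y)[max(1, floor(200 * tau))]
    hi <- sort(y)[min(200, ceiling(200 * tau) + 1)]
    expect_gte(b, lo - 1e-8)
    expect_lte(b, hi + 1e-8)
  }
})

test_that("location and scale equivariance hold to solver tolerance", {
  set.seed(16)
  n <- 400
  X <- cbind("(Intercept)" = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- 2 + X[, 2] + rexp(n)
  for (tau in c(0.5, 0.9)) {
    base <- fit_quantile(y, X, tau)
    shifted <- fit_quantile(y + 17.5, X, tau)
    expect_equal(shifted$coefficients["(Intercept)"],
                 base$coefficients["(Intercept)"] + 17.5, tolerance = 1e-6)
    expect_equal(shifted$coefficients[-1], base$coefficients[-1],
                 tolerance = 1e-6)
    scaled <- fit_quantile(3 * y, X, tau)
    expect_equal(unname(scaled$coefficients), unname(3 * base$coefficients),
                 tolerance = 1e-6)
  }
})

test_that("small problems match the exhaustive basis-solution oracle", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 12
    X <- cbind("(Intercept)" = 1, g = rbinom(n, 1, 0.5))
    if (length(unique(X[, 2])) < 2) next
    y <- round(rexp(n, 0.05), 1)
    tau <- sample(c(0.25, 0.5, 0.75, 0.9), 1)
    fit <- fit_quantile(y, X, tau)
    want <- oracle_rq(y, X, tau)
    expect_equal(fit$objective, want$objective, tolerance = 1e-8)
  }
})

test_that("fits agree with an independent quantile-regression implementation", {
  set.seed(18)
  n <- 3000
  X <- cbind("(Intercept)" = 1, a = rnorm(n), b = rbinom(n, 1, 0.3),
             c = sample(-5:5, n, TRUE))
  y <- pmax(1, round(50 + 10 * X[, "b"] + rlnorm(n, 3, 1)))
  for (tau in c(0.1, 0.5, 0.9)) {
    fit <- fit_quantile(y, X, tau)
    ref <- quantreg::rq.fit.br(X, y, tau = tau)
    r <- y - drop(X %*% ref$coefficients)
    expect_equal(fit$objective, sum(r * (tau - (r < 0))), tolerance = 1e-7)
    expect_equal(unname(fit$coefficients), unname(ref$coefficients),
                 tolerance = 1e-3)
    expect_true(fit$subgradient_ok)
  }
})

test_that("the reported objective is a local (and LP global) minimum", {
  set.seed(19)
  n <- 500
  X <- cbind("(Intercept)" = 1, x = rnorm(n), z = rbinom(n, 1, 0.5))
  y <- 5 + X[, 2] - 2 * X[, 3] + rcauchy(n)
  fit <- fit_quantile(y, X, tau = 0.5)
  for (i in 1:100) {
    pert <- fit$coefficients + rnorm(3) * 0.05
    r <- y - drop(X %*% pert)
    expect_gte(check_loss(r, 0.5), fit$objective - 1e-9)
  }
})

test_that("design and argument contracts are enforced", {
  X <- cbind("(Intercept)" = 1, dup1 = rep(1:0, 10), dup2 = rep(1:0, 10))
  y <- rnorm(20)
  expect_error(fit_quantile(y, X, 0.5), "dup2", class = "dx_design_error")
  expect_error(fit_quantile(y, X[, 1:2], 1.5), class = "dx_contract_error")
  expect_error(fit_quantile(rnorm(2), X[1:2, 1:2], 0.5),
               class = "dx_contract_error")
  expect_error(bootstrap_ci(y, X[, 1:2], 0.5, B = 50),
               class = "dx_contract_error")
})

test_that("bootstrap intervals are seed-deterministic", {
  set.seed(20)
  n <- 300
  X <- cbind("(Intercept)" = 1, g = rbinom(n, 1, 0.5))
  y <- 10 + 3 * X[, 2] + rexp(n, 0.1)
  a <- bootstrap_ci(y, X, 0.5, B = 200, seed = 123)
  b <- bootstrap_ci(y, X, 0.5, B = 200, seed = 123)
  c <- bootstrap_ci(y, X, 0.5, B = 200, seed = 321)
  expect_identical(a$conf.low, b$conf.low)
  expect_identical(a$conf.high, b$conf.high)
  expect_false(identical(a$conf.low, c$conf.low))
  expect_true(all(a$conf.low <= a$estimate & a$estimate <= a$conf.high))
})

test_that("tidy and glance summarise fits in broom style", {
  y <- c(2, 5, 9, 1, 7, 3, 8)
  fit <- fit_quantile(y, icol(7), 0.5)
  td <- tidy(fit)
  expect_identical(td$term, "(Intercept)")
  expect_equal(td$estimate, 5)
  gl <- glance(fit)
  expect_identical(gl$n, 7L)
  expect_true(gl$converged)
  expect_equal(gl$objective, check_loss(y - 5, 0.5))
})

test_that("stratified model reports recover generator quintile effects", {
  cfg <- coverage_config(seed = 424, delta = 15, n_patients = 100000)
  pts <- simulate_patients(cfg)
  sym <- pts[pts$status == "symptomatic", ]
  sym$interval_days <- sym$true_interval_days
  rep_ <- run_quantile_models(sym, taus = 0.9, strata = "status",
                              models = "adjusted", B = 150, seed = 7)
  q1 <- rep_[rep_$term == "quintile1", ]
  expect_lt(abs(q1$estimate - 15), 20)   # within Monte-Carlo error
  expect_true(q1$conf.low < 15 & 15 < q1$conf.high)

  # monotone recovery as the injected shift grows
  est <- vapply(c(0, 30, 60), function(delta) {
    p <- simulate_patients(coverage_config(seed = 500 + delta, delta = delta,
                                           n_patients = 100000))
    s <- p[p$status == "symptomatic", ]
    X <- design_from_patients(s)
    fit_quantile(s$true_interval_days, X, 0.9)$coefficients["quintile1"]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("small strata are skipped with a warning", {
  cfg <- coverage_config(seed = 9, delta = 0, n_patients = 300)
  pts <- simulate_patients(cfg)
  pts$interval_days <- pts$true_interval_days
  pts$status[1:10] <- "rare"
  expect_warning(
    run_quantile_models(pts[pts$status %in% c("symptomatic", "rare"), ],
                        taus = 0.5, B = 100, seed = 1, min_n = 50),
    "skipped")
})
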