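test_that("contrast vector matches the brute-force triple loop", {
  set.seed(31)
  x <- rnorm(90, 25, 4)
  cb <- crossbasis(x, max_lag = 7, var_df = 3, lag_df = 3)
  vk <- attr(cb, "var_knots"); L <- attr(cb, "lag_basis")
  beta <- rnorm(9)
  f <- function(temp, l) {
    v <- ncs_basis(temp, vk)[1, ]
    sum(outer(v, L[l + 1, ]) * matrix(beta, 3, 3, byrow = TRUE))
  }
  for (w in list(c(0, 7), c(1, 5), c(3, 3))) {
    cv <- contrast_vector(cb, 31.2, 24.8, w)
    direct <- sum(vapply(w[1]:w[2],
                         function(l) f(31.2, l) - f(24.8, l), numeric(1)))
    expect_equal(sum(cv * beta), direct, tolerance = 1e-10)
  }
  expect_equal(contrast_vector(cb, 25, 25, c(0, 7)), rep(0, 9))
  expect_error(contrast_vector(cb, 30, 25, c(0, 9)), "within 0")
})

test_that("lag-stratified linear contrast reduces to the sum-of-betas formula", {
  set.seed(32)
  x <- rnorm(120, 25, 4)
  cb <- crossbasis(x, max_lag = 5, var_type = "lin", lag_type = "strata")
  cv <- contrast_vector(cb, 32.4, 26.3, c(0, 2))
  expect_equal(cv, c(rep(32.4 - 26.3, 3), rep(0, 3)))
  beta <- rnorm(6)
  expect_equal(sum(cv * beta),
               (beta[1] + beta[2] + beta[3]) * (32.4 - 26.3),
               tolerance = 1e-14)
})

test_that("cumulative RR at the reference is exactly 1", {
  fit <- fixture_fit()
  expect_equal(cumulative_rr(fit, 26.3, 26.3, c(0, 14)),
               c(rr = 1, ci_low = 1, ci_high = 1))
})

test_that("delta-method CI matches an MVN parametric bootstrap", {
  fit <- fixture_fit()
  cv <- contrast_vector(fit$crossbasis, 32.4, 26.3, c(0, 2))
  b <- coef(fit, "crossbasis"); V <- vcov(fit, "crossbasis")
  rr <- cumulative_rr(fit, 32.4, 26.3, c(0, 2))
  set.seed(2024)
  draws <- MASS::mvrnorm(1e5, b, V) %*% cv
  boot <- exp(quantile(draws, c(.025, .975), names = FALSE))
  expect_lt(abs(boot[1] - rr["ci_low"]) / rr["ci_low"], 0.005)
  expect_lt(abs(boot[2] - rr["ci_high"]) / rr["ci_high"], 0.005)
})

test_that("log RRs are additive over contrasts and lags", {
  fit <- fixture_fit()
  w <- c(0, 14)
  rab <- cumulative_rr(fit, 32, 28, w)["rr"]
  rbc <- cumulative_rr(fit, 28, 22, w)["rr"]
  rac <- cumulative_rr(fit, 32, 22, w)["rr"]
  expect_equal(unname(rab * rbc), unname(rac), tolerance = 1e-10)

  lc <- lag_structure(fit, 31, 26)
  cum <- cumulative_rr(fit, 31, 26, c(0, 14))
  expect_equal(sum(log(lc$rr)), log(unname(cum["rr"])), tolerance = 1e-10)
})

test_that("doubling a linear contrast squares the relative risk", {
  sim <- fixture_sim()
  fit <- suppressWarnings(
    dlnm_nb(sim, model_spec(max_lag = 7, var_type = "lin", var_df = 1,
                            lag_df = 3)))
  r1 <- cumulative_rr(fit, 27.3, 26.3, c(0, 7))["rr"]
  r2 <- cumulative_rr(fit, 28.3, 26.3, c(0, 7))["rr"]
  expect_equal(unname(r2), unname(r1)^2, tolerance = 1e-10)
})

test_that("null cross-basis coefficients give flat unit curves", {
  fit <- fixture_fit()
  fit0 <- fit
  fit0$coefficients[fit0$blocks$crossbasis] <- 0
  cur <- overall_curve(fit0, temps = seq(16, 34, 2))
  expect_equal(cur$rr, rep(1, nrow(cur)))
  lc <- lag_structure(fit0, 32, 26)
  expect_equal(lc$rr, rep(1, 15))
})

test_that("window 0-0 curve equals the single-lag curve at lag 0", {
  fit <- fixture_fit()
  temps <- seq(18, 33, 3)
  cur <- overall_curve(fit, temps = temps, ref = 26.3, lag_window = c(0, 0))
  lag0 <- vapply(temps, function(x)
    cumulative_rr(fit, x, 26.3, c(0, 0))["rr"], numeric(1))
  expect_equal(cur$rr, unname(lag0), tolerance = 1e-12)
})

test_that("percentile effects are two cumulative_rr calls at series quantiles", {
  fit <- fixture_fit()
  pe <- percentile_effects(fit, cold_window = c(0, 14))
  q <- quantile(fit$temps[fit$mask], c(.01, .5, .99), names = FALSE, type = 7)
  hot <- cumulative_rr(fit, q[3], q[2], c(0, 2))
  cold <- cumulative_rr(fit, q[1], q[2], c(0, 14))
  expect_equal(pe$rr, unname(c(hot["rr"], cold["rr"])))
  expect_equal(pe$ci_low, unname(c(hot["ci_low"], cold["ci_low"])))
  expect_equal(pe$temp, c(q[3], q[1]))

  # explicit data: 101 sorted values whose 1st/50th/99th percentiles are
  # exactly the canonical anchors (type-7 quantiles hit order statistics)
  v <- c(seq(15.0, 15.8, length.out = 2),
         seq(15.9, 26.3, length.out = 49),
         seq(26.4, 32.4, length.out = 49), 33.5)
  dat <- data.frame(tavg = v)
  pe2 <- percentile_effects(fit, data = dat, cold_window = c(0, 14))
  expect_equal(pe2$temp, c(32.4, 15.8))
  expect_equal(pe2$ref_temp, rep(26.3, 2))
})

test_that("zeroed coefficients give unit percentile effects", {
  fit <- fixture_fit()
  fit0 <- fit
  fit0$coefficients[fit0$blocks$crossbasis] <- 0
  pe <- percentile_effects(fit0, cold_window = c(0, 14))
  expect_equal(pe$rr, c(1, 1))
  expect_false(any(pe$significant))
})

test_that("CI width shrinks with the series length", {
  widths <- function(years, seed) {
    sim <- simulate_daily(sim_config(n_years = years, seed = seed),
                          true_surface("J"))
    fit <- suppressWarnings(
      dlnm_nb(sim, model_spec(max_lag = 14, lag_df = 4)))
    rr <- cumulative_rr(fit, 32.4, 26.3, c(0, 2))
    log(rr["ci_high"]) - log(rr["ci_low"])
  }
  short <- vapply(1:8, function(s) widths(4, 300 + s), numeric(1))
  long <- vapply(1:8, function(s) widths(16, 400 + s), numeric(1))
  expect_lt(mean(long), mean(short))
})
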