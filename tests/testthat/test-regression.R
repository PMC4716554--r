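test_that("assembled design has the expected block structure", {
  sim <- simulate_daily(sim_config(n_years = 5, seed = 8),
                        true_surface("null"))
  asm <- assemble_design(sim, hue2016())
  expect_equal(length(asm$blocks$time), 25L)       # 5 df/yr over 5 years
  expect_equal(length(asm$blocks$crossbasis), 20L) # 4 x 5
  expect_equal(ncol(asm$design), 1 + 20 + 6 + 25 + 3 + 3)
  expect_equal(sum(asm$mask), nrow(sim) - 28L)

  minimal <- model_spec(max_lag = 7, var_df = 3, lag_df = 3,
                        humidity_df = 0, dewpoint_df = 0, dow = FALSE,
                        time_df_per_year = 1)
  asm2 <- assemble_design(sim, minimal)
  expect_named(asm2$blocks, c("intercept", "crossbasis", "time"))

  expect_error(assemble_design(sim[, setdiff(names(sim), "humidity")],
                               hue2016()), "missing required")
  bad <- sim; bad$deaths_all[5] <- -1L
  expect_error(assemble_design(bad, hue2016()), "non-negative")
})

test_that("intercept-only NB fit recovers a constant mean exactly", {
  y <- rep(3L, 200)
  X <- matrix(1, 200, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- suppressWarnings(fit_negbin(X, y))
  expect_equal(exp(unname(fit$coefficients[1])), 3, tolerance = 1e-6)
  expect_gt(fit$theta, 1e3)   # Poisson limit for equidispersed data
  expect_error(fit_negbin(X, rep(0L, 200)), "all counts are zero")
})

test_that("reported AIC equals -2 x pmf-summed loglik + 2(p + 1)", {
  fit <- fixture_fit()
  y <- fit$response[fit$mask]
  mu <- fit$fitted_masked
  ll <- nb2_loglik(y, mu, fit$theta)
  expect_equal(fit$aic, -2 * ll + 2 * (length(fit$coefficients) + 1),
               tolerance = 1e-6)
  expect_equal(AIC(fit), fit$aic)
})

test_that("NB fit recovers known coefficients within 3 SE", {
  n <- 3000
  hits <- 0; reps <- 100
  for (s in seq_len(reps)) {
    set.seed(s)
    x1 <- rnorm(n); x2 <- runif(n)
    X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
    beta <- c(1.2, 0.3, -0.5)
    y <- rnbinom(n, mu = exp(drop(X %*% beta)), size = 10)
    fit <- suppressWarnings(fit_negbin(X, y))
    se <- sqrt(diag(fit$vcov))
    hits <- hits + all(abs(fit$coefficients - beta) <= 3 * se)
  }
  expect_gte(hits / reps, 0.95)
})

test_that("NB coefficients approach the Poisson fit on equidispersed data", {
  set.seed(99)
  n <- 2000
  x <- rnorm(n)
  y <- rpois(n, exp(1 + 0.4 * x))
  X <- cbind("(Intercept)" = 1, x = x)
  nb <- suppressWarnings(fit_negbin(X, y))
  po <- glm(y ~ x, family = poisson())
  expect_lt(max(abs(nb$coefficients - coef(po))), 1e-3)
})

test_that("AIC prefers the model containing the true term", {
  n <- 3000; wins <- 0; reps <- 20
  for (s in seq_len(reps)) {
    set.seed(1000 + s)
    x <- rnorm(n)
    y <- rnbinom(n, mu = exp(1 + 0.25 * x), size = 8)
    X0 <- cbind("(Intercept)" = rep(1, n))
    X1 <- cbind(X0, x = x)
    a0 <- suppressWarnings(fit_negbin(X0, y))$aic
    a1 <- suppressWarnings(fit_negbin(X1, y))$aic
    wins <- wins + (a1 <= a0)
  }
  expect_gte(wins / reps, 0.9)
})

test_that("shifting temperature and knots leaves fit and RRs unchanged", {
  sim <- fixture_sim()
  fit1 <- fixture_fit()
  shift <- 50
  sim2 <- sim
  sim2$tavg <- sim2$tavg + shift
  vk <- attr(fit1$crossbasis, "var_knots")
  spec2 <- model_spec(max_lag = 14, lag_df = 4, var_df = 4,
                      var_knots = knot_spec(vk$interior + shift,
                                            vk$boundary + shift))
  fit2 <- suppressWarnings(dlnm_nb(sim2, spec2))
  expect_equal(fit2$aic, fit1$aic, tolerance = 1e-6)
  rr1 <- cumulative_rr(fit1, 32.4, 26.3, c(0, 2))
  rr2 <- cumulative_rr(fit2, 32.4 + shift, 26.3 + shift, c(0, 2))
  expect_equal(rr2, rr1, tolerance = 1e-6)
})

test_that("diagnostics are self-consistent on data from the fitted model", {
  fit <- fixture_fit()
  d <- diagnostics(fit)
  expect_length(d$deviance, fit$n_used)
  expect_gt(d$dispersion_ratio, 0.8)
  expect_lt(d$dispersion_ratio, 1.2)

  # refit on counts simulated from the model itself
  y2 <- simulate(fit, seed = 1)[[1]]
  sim2 <- fixture_sim()
  sim2$deaths_all[fit$mask] <- y2
  fit2 <- suppressWarnings(dlnm_nb(sim2, fit$spec))
  d2 <- diagnostics(fit2)
  expect_gt(d2$dispersion_ratio, 0.8)
  expect_lt(d2$dispersion_ratio, 1.2)
})

test_that("unstructured counts show no residual autocorrelation", {
  set.seed(4)
  n <- 1000
  y <- rnbinom(n, mu = 3.4, size = 8)
  X <- cbind("(Intercept)" = rep(1, n))
  fit <- suppressWarnings(fit_negbin(X, y))
  mu <- fit$fitted
  pear <- (y - mu) / sqrt(mu + mu^2 / fit$theta)
  ac <- acf(pear, lag.max = 30, plot = FALSE)$acf[-1]
  expect_gte(sum(abs(ac) <= 2 / sqrt(n)), 28)
})
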