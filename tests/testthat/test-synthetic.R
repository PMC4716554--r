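test_that("simulated weather reproduces the target temperature climate", {
  means <- sds <- numeric(50)
  for (s in 1:50) {
    w <- simulate_weather(sim_config(seed = 6000 + s))
    means[s] <- mean(w$tavg); sds[s] <- sd(w$tavg)
  }
  expect_lt(abs(mean(means) - 25.7), 0.2)
  expect_lt(abs(mean(sds) - 4.1), 0.3)
})

test_that("weather generation is deterministic given the seed", {
  w1 <- simulate_weather(sim_config(seed = 77))
  w2 <- simulate_weather(sim_config(seed = 77))
  expect_identical(w1, w2)
  s1 <- simulate_daily(sim_config(seed = 77), true_surface("U"))
  s2 <- simulate_daily(sim_config(seed = 77), true_surface("U"))
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("zero-noise zero-amplitude weather is constant at the mean", {
  cfg <- sim_config(seed = 1, seasonal_amplitude = 0, temp_sd = 1e-9,
                    ar1 = 0)
  w <- simulate_weather(cfg)
  expect_lt(diff(range(w$tavg)), 1e-6)
  expect_equal(mean(w$tavg), 25.7, tolerance = 1e-6)
})

test_that("weather respects physical orderings", {
  w <- simulate_weather(sim_config(seed = 3))
  expect_true(all(w$tmin < w$tavg & w$tavg < w$tmax))
  expect_true(all(w$dewpoint < w$tavg))
  expect_true(all(w$humidity > 0 & w$humidity <= 100))
})

test_that("null-surface counts are NB with the configured baseline", {
  mm <- numeric(60)
  for (s in 1:60) {
    cfg <- sim_config(n_years = 1, seed = 7000 + s,
                      dow_effects = rep(0, 7))
    sim <- simulate_daily(cfg, true_surface("null"), stratified = FALSE)
    mm[s] <- mean(sim$deaths_all)
  }
  # MC standard error of the grand mean
  se <- sd(mm) / sqrt(length(mm))
  expect_lt(abs(mean(mm) - 3.4), 3 * se + 0.02)
})

test_that("counts are overdispersed at the configured theta", {
  over <- 0
  for (s in 1:40) {
    cfg <- sim_config(seed = 8000 + s, nb_theta = 5, dow_effects = rep(0, 7))
    sim <- simulate_daily(cfg, true_surface("null"), stratified = FALSE)
    over <- over + (var(sim$deaths_all) / mean(sim$deaths_all) > 1.5)
  }
  expect_gte(over / 40, 0.95)
})

test_that("stratified counts partition the all-cause count", {
  sim <- simulate_daily(sim_config(n_years = 2, seed = 5), true_surface("U"))
  expect_true(all(sim$deaths_male + sim$deaths_female == sim$deaths_all))
  expect_true(all(sim$deaths_0_64 + sim$deaths_65plus == sim$deaths_all))
  expect_true(all(sim$deaths_nonext <= sim$deaths_all))
  expect_true(all(sim$deaths_cvd + sim$deaths_resp + sim$deaths_cancer
                  <= sim$deaths_nonext))
})

test_that("closed-form cumulative RR agrees with lag-by-lag summation", {
  for (shape in c("J", "U", "L", "linear", "displacement")) {
    surf <- true_surface(shape)
    for (at in c(15.8, 20, 30, 32.4)) {
      direct <- exp(sum(vapply(0:28, function(l)
        surf$f(at, l) - surf$f(26.3, l), numeric(1))))
      expect_equal(true_cumulative_rr(surf, at, 26.3, c(0, 28)), direct,
                   tolerance = 1e-12)
    }
    expect_equal(true_cumulative_rr(surf, 26.3), 1)
  }
})

test_that("displacement cancels over the full window but not the acute one", {
  surf <- true_surface("displacement")
  acute <- true_cumulative_rr(surf, 32.4, 26.3, c(0, 2))
  full <- true_cumulative_rr(surf, 32.4, 26.3, c(0, 28))
  expect_gt(acute, 1)
  expect_lt(abs(log(full)), abs(log(acute)))
})

test_that("surface calibration matches the declared cumulative log RRs", {
  surf <- true_surface("U")
  expect_equal(log(true_cumulative_rr(surf, 32.4, 26.3, c(0, 28))),
               surf$hot_logrr, tolerance = 1e-10)
  expect_equal(log(true_cumulative_rr(surf, 15.8, 26.3, c(0, 28))),
               surf$cold_logrr, tolerance = 1e-10)
})

test_that("spline-family surfaces evaluate through their coefficients", {
  surf <- recovery_surface()
  vk <- surf$var_knots
  L <- cbind(1, ncs_basis(0:28, surf$lag_knots))
  at <- 30.5; l <- 4
  v <- ncs_basis(at, vk)[1, ] - ncs_basis(26.3, vk)[1, ]
  expect_equal(surf$f(at, l), drop(v %*% surf$beta %*% L[l + 1, ]),
               tolerance = 1e-12)
  expect_equal(surf$f(26.3, 10), 0)
})

test_that("sim_config validates its calibration constraint", {
  expect_error(sim_config(seasonal_amplitude = 6, temp_sd = 4.1),
               "amplitude too large")
  expect_error(sim_config(ar1 = 1), "ar1")
})
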