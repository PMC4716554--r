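#' Known exposure-lag-response surfaces for simulation
#'
#' Defines the true log-RR surface f(x, l) that the simulator feeds into
#' the daily death rate, anchored at three temperature percentiles of the
#' simulated climate (defaults 15.8 / 26.3 / 32.4 degrees C for the 1st /
#' 50th / 99th).  f(ref, l) = 0 for every lag.  Available shapes:
#' \describe{
#'   \item{null}{no temperature effect.}
#'   \item{linear}{log-linear in temperature, acute lag weights.}
#'   \item{J}{heat effect only: quadratic ramp above the reference with
#'     exponentially decaying lag weights (acute).}
#'   \item{L}{cold effect only: linear ramp below the reference with
#'     delayed bell-shaped lag weights.}
#'   \item{U}{both J and L components.}
#'   \item{displacement}{acute heat excess on lags 0-2 followed by a
#'     compensating deficit on lags 3-10 (mortality displacement /
#'     harvesting).}
#' }
#' \code{hot_logrr} and \code{cold_logrr} are the cumulative log RRs over
#' lags 0..max_lag of the hot (99th vs 50th percentile) and cold (1st vs
#' 50th) contrasts; the lag weights of each component sum to 1, so these
#' calibrate the surface directly.
#'
#' @param shape surface shape, see above.
#' @param hot_logrr,cold_logrr cumulative log RRs (defaults log(1.35) and
#'   log(1.8) where the shape has the component, else 0).
#' @param hot_lag_decay e-folding time (days) of the acute heat weights.
#' @param cold_lag_onset,cold_lag_decay centre and width (days) of the
#'   delayed cold weights.
#' @param displacement_depth cumulative log RR of the deficit component
#'   (<= 0), displacement shape only.
#' @param temp_p1,temp_ref,temp_p99 anchor temperatures (degrees C).
#' @param max_lag lag range the cumulative calibration refers to.
#' @return An object of class \code{"true_surface"} with a vectorised
#'   element \code{f(x, l)}.
#' @seealso [true_cumulative_rr()], [simulate_mortality()]
#' @export
true_surface <- function(shape = c("null", "linear", "J", "U", "L",
                                   "displacement"),
                         hot_logrr = NULL, cold_logrr = NULL,
                         hot_lag_decay = 4, cold_lag_onset = 4,
                         cold_lag_decay = 6, displacement_depth = log(0.75),
                         temp_p1 = 15.8, temp_ref = 26.3, temp_p99 = 32.4,
                         max_lag = 28L) {
  shape <- match.arg(shape)
  if (is.null(hot_logrr))
    hot_logrr <- if (shape %in% c("J", "U", "linear", "displacement"))
      log(1.35) else 0
  if (is.null(cold_logrr))
    cold_logrr <- if (shape %in% c("L", "U")) log(1.8) else 0
  if (displacement_depth > 0)
    stop("'displacement_depth' must be <= 0")
  lags <- 0:max_lag
  w_hot <- exp(-lags / hot_lag_decay); w_hot <- w_hot / sum(w_hot)
  w_cold <- exp(-0.5 * ((lags - cold_lag_onset) / cold_lag_decay)^2)
  w_cold <- w_cold / sum(w_cold)
  # displacement: excess confined to lags 0-2, deficit to lags 3-10
  w_acu <- ifelse(lags <= 2, exp(-lags), 0); w_acu <- w_acu / sum(w_acu)
  w_def <- ifelse(lags >= 3 & lags <= 10,
                  exp(-0.5 * ((lags - 6) / 2.5)^2), 0)
  w_def <- w_def / sum(w_def)
  hot_ramp <- function(x) (pmax(x - temp_ref, 0) / (temp_p99 - temp_ref))^2
  cold_ramp <- function(x) pmax(temp_ref - x, 0) / (temp_ref - temp_p1)
  lin_ramp <- function(x) (x - temp_ref) / (temp_p99 - temp_ref)
  f <- switch(shape,
    null = function(x, l) 0 * x + 0 * l,
    linear = function(x, l) hot_logrr * lin_ramp(x) * w_hot[l + 1L],
    J = function(x, l) hot_logrr * hot_ramp(x) * w_hot[l + 1L],
    L = function(x, l) cold_logrr * cold_ramp(x) * w_cold[l + 1L],
    U = function(x, l) hot_logrr * hot_ramp(x) * w_hot[l + 1L] +
      cold_logrr * cold_ramp(x) * w_cold[l + 1L],
    displacement = function(x, l)
      hot_ramp(x) * (hot_logrr * w_acu[l + 1L] +
                     displacement_depth * w_def[l + 1L]))
  structure(
    list(shape = shape, f = f, max_lag = as.integer(max_lag),
         hot_logrr = hot_logrr, cold_logrr = cold_logrr,
         temp_p1 = temp_p1, temp_ref = temp_ref, temp_p99 = temp_p99,
         displacement_depth = displacement_depth),
    class = "true_surface")
}

#' Exposure-lag-response surface from cross-basis coefficients
#'
#' Builds a [true_surface()] whose f(x, l) is itself a tensor-product
#' spline: \eqn{f(x,l) = \sum_{j,k} \beta_{jk} [V_j(x) - V_j(ref)] B_k(l)}.
#' Useful for recovery experiments where the data-generating surface lies
#' exactly in the model family with known basis dimensions.
#'
#' @param var_knots [knot_spec()] of the temperature basis.
#' @param beta var_df x lag_df coefficient matrix.
#' @param max_lag lag range.
#' @param lag_knots optional [knot_spec()] for the lag basis (default
#'   equally spaced lags for the implied df).
#' @param lag_intercept whether the lag df counts an intercept column.
#' @param temp_ref reference temperature where f is zero.
#' @param temp_p1,temp_p99 anchor percentiles carried along for reporting.
#' @return A \code{"true_surface"}.
#' @export
crossbasis_surface <- function(var_knots, beta, max_lag = 28L,
                               lag_knots = NULL, lag_intercept = TRUE,
                               temp_ref = 26.3, temp_p1 = 15.8,
                               temp_p99 = 32.4) {
  beta <- as.matrix(beta)
  var_df <- var_knots$df
  lag_df <- ncol(beta)
  if (nrow(beta) != var_df)
    stop("nrow(beta) must equal the var-basis df")
  if (is.null(lag_knots) && (!lag_intercept || lag_df > 1L))
    lag_knots <- place_lag_knots(max_lag,
                                 if (lag_intercept) lag_df - 1L else lag_df)
  L <- eval_lag_basis(max_lag, lag_df, "ncs", lag_knots, lag_intercept)
  # scalar-lag evaluation, vectorised over x
  f <- function(x, l) {
    V <- eval_var_basis(x, "ncs", var_knots)
    Vr <- eval_var_basis(rep(temp_ref, 1L), "ncs", var_knots)
    Vd <- sweep(V, 2, as.vector(Vr))
    drop(Vd %*% beta %*% L[l + 1L, ])
  }
  structure(
    list(shape = "crossbasis", f = f, max_lag = as.integer(max_lag),
         var_knots = var_knots, lag_knots = lag_knots, beta = beta,
         var_df = var_df, lag_df = lag_df,
         temp_p1 = temp_p1, temp_ref = temp_ref, temp_p99 = temp_p99),
    class = "true_surface")
}

#' True cumulative relative risk of a surface
#'
#' Closed-form evaluation of the cumulative RR
#' exp(sum over the window of f(at, l) - f(ref, l)) from a
#' [true_surface()]; the oracle that recovery tests compare fitted RRs
#' against.
#'
#' @param surface a \code{"true_surface"}.
#' @param at_temp temperature of interest (degrees C).
#' @param ref_temp reference (default the surface's own reference).
#' @param lag_window integer pair, default 0..max_lag.
#' @return A single RR.
#' @export
true_cumulative_rr <- function(surface, at_temp, ref_temp = NULL,
                               lag_window = NULL) {
  stopifnot(inherits(surface, "true_surface"))
  if (is.null(ref_temp)) ref_temp <- surface$temp_ref
  if (is.null(lag_window)) lag_window <- c(0L, surface$max_lag)
  lags <- lag_window[1]:lag_window[2]
  lr <- sum(vapply(lags, function(l)
    surface$f(at_temp, l) - surface$f(ref_temp, l), numeric(1)))
  exp(lr)
}

#' Simulation configuration for daily weather and mortality
#'
#' Parameters of the synthetic data generator, calibrated to a humid
#' tropical-monsoon climate with overdispersed low daily death counts:
#' mean daily average temperature 25.7 degrees C with marginal SD 4.1
#' (annual sinusoid plus AR(1) noise, jointly calibrated so the implied
#' marginal SD equals \code{temp_sd} exactly), mean 3.4 all-cause deaths
#' per day.  Maximum and minimum temperature are offset from the average
#' (+4.2 / -4.0 on average), dew point sits a positive depression below
#' the average temperature, and relative humidity follows from the
#' depression via the Magnus approximation, clipped to (0, 100].
#'
#' @param n_years length of the series (default 5).
#' @param temp_mean,temp_sd mean and marginal SD of daily average
#'   temperature (degrees C).
#' @param seasonal_amplitude amplitude of the annual sinusoid (degrees C);
#'   must satisfy amplitude^2/2 < temp_sd^2.
#' @param ar1 lag-1 autocorrelation of the temperature noise, in [0, 1).
#' @param baseline_daily_deaths expected deaths/day at the reference
#'   temperature on a Monday.
#' @param nb_theta NB2 dispersion of daily counts.
#' @param dow_effects 7 log-rate offsets, Monday..Sunday.
#' @param trend_slope log-rate change per year.
#' @param strata thinning proportions for stratified counts: elements
#'   \code{external}, \code{cardiovascular}, \code{respiratory},
#'   \code{cancer} (of all-cause; the remainder is other non-external),
#'   \code{male}, \code{age65plus}.
#' @param start_date first day of the series.
#' @param seed integer seed making the whole generated dataset
#'   reproducible; NULL uses the current RNG state.
#' @return An object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_years = 5, temp_mean = 25.7, temp_sd = 4.1,
                       seasonal_amplitude = 4.8, ar1 = 0.7,
                       baseline_daily_deaths = 3.4, nb_theta = 8,
                       dow_effects = c(0, 0, 0, 0, 0, 0.05, 0.05),
                       trend_slope = 0,
                       strata = list(external = 0.059,
                                     cardiovascular = 0.3564,
                                     respiratory = 0.0294,
                                     cancer = 0.1728,
                                     male = 0.5349, age65plus = 0.655),
                       start_date = as.Date("2009-01-01"), seed = NULL) {
  stopifnot(n_years > 0, temp_sd > 0, ar1 >= 0, ar1 < 1,
            baseline_daily_deaths > 0, nb_theta > 0,
            length(dow_effects) == 7)
  if (seasonal_amplitude^2 / 2 >= temp_sd^2)
    stop("seasonal_amplitude too large for the requested marginal temp_sd")
  structure(
    list(n_years = n_years, temp_mean = temp_mean, temp_sd = temp_sd,
         seasonal_amplitude = seasonal_amplitude, ar1 = ar1,
         baseline_daily_deaths = baseline_daily_deaths,
         nb_theta = nb_theta, dow_effects = dow_effects,
         trend_slope = trend_slope, strata = strata,
         start_date = as.Date(start_date),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config")
}

#' Simulate daily weather
#'
#' Daily average temperature = mean + annual sinusoid (peak near the
#' summer solstice) + AR(1) noise whose innovation variance is chosen so
#' the marginal SD equals \code{temp_sd}; maximum / minimum temperature,
#' dew point and Magnus-derived relative humidity as described in
#' [sim_config()].
#'
#' @param config a [sim_config()].
#' @return A [daily_series()] with the weather columns.
#' @export
simulate_weather <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- round(config$n_years * 365.25)
  dates <- config$start_date + 0:(n - 1L)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$seasonal_amplitude * cos(2 * pi * (doy - 172) / 365.25)
  resid_sd <- sqrt(config$temp_sd^2 - config$seasonal_amplitude^2 / 2)
  innov_sd <- resid_sd * sqrt(1 - config$ar1^2)
  noise <- if (config$ar1 > 0)
    as.vector(stats::arima.sim(list(ar = config$ar1), n, sd = innov_sd))
  else stats::rnorm(n, 0, innov_sd)
  tavg <- config$temp_mean + seasonal + noise
  tmax <- tavg + pmax(stats::rnorm(n, 4.2, 1.0), 0.3)
  tmin <- tavg - pmax(stats::rnorm(n, 4.0, 1.0), 0.3)
  depression <- pmax(stats::rnorm(n, 3.6, 1.5), 0.1)
  dewpoint <- tavg - depression
  humidity <- pmin(pmax(magnus_rh(tavg, dewpoint), 1e-6), 100)
  daily_series(data.frame(date = dates, tmax = tmax, tavg = tavg,
                          tmin = tmin, dewpoint = dewpoint,
                          humidity = humidity))
}

# Relative humidity (%) from temperature and dew point, Magnus formula.
magnus_rh <- function(t, td, a = 17.625, b = 243.04) {
  100 * exp(a * td / (b + td) - a * t / (b + t))
}

#' Simulate daily death counts from a known surface
#'
#' Data-generating analogue of the fitted model:
#' log mu_t = log(baseline) + sum_l f(x_{t-l}, l) + dow_t + trend, with
#' Y_t ~ NB2(mu_t, theta).  Lags reaching before the series start are
#' truncated (those leading days are excluded from fitting anyway).
#' Stratified counts are produced by multinomial thinning so strata are
#' consistent by construction: cause of death (external vs non-external,
#' the latter split into cardiovascular / respiratory / cancer / other),
#' sex, and age group each partition the all-cause count.
#'
#' @param weather a [daily_series()] from [simulate_weather()].
#' @param surface a [true_surface()].
#' @param config the same [sim_config()]; its seed (offset) governs the
#'   count draws.
#' @param stratified also generate stratified count columns.
#' @return The weather series with count columns appended.
#' @export
simulate_mortality <- function(weather, surface, config,
                               stratified = TRUE) {
  stopifnot(inherits(config, "sim_config"), inherits(surface, "true_surface"))
  if (!is.null(config$seed)) set.seed(config$seed + 500000L)
  n <- nrow(weather)
  x <- weather$tavg
  max_lag <- surface$max_lag
  fmat <- vapply(0:max_lag, function(l) surface$f(x, l), numeric(n))
  cum <- numeric(n)
  for (l in 0:max_lag) {
    idx <- (l + 1L):n
    cum[idx] <- cum[idx] + fmat[idx - l, l + 1L]
  }
  dow <- as.integer(format(weather$date, "%u"))
  tt <- (seq_len(n) - 1) / 365.25
  eta <- log(config$baseline_daily_deaths) + cum +
    config$dow_effects[dow] + config$trend_slope * tt
  mu <- exp(eta)
  if (any(!is.finite(mu)) || max(mu) > 1e6)
    stop("surface produced overflowing daily rates")
  deaths <- stats::rnbinom(n, mu = mu, size = config$nb_theta)
  out <- weather
  out$deaths_all <- deaths
  if (stratified) {
    p <- config$strata
    ext <- stats::rbinom(n, deaths, p$external)
    nonext <- deaths - ext
    # cause split within non-external
    pn <- c(p$cardiovascular, p$respiratory, p$cancer)
    pn <- pn / (1 - p$external)  # proportions of all-cause -> of non-external
    cvd <- resp <- canc <- integer(n)
    pos <- which(nonext > 0)
    if (length(pos)) {
      draws <- vapply(pos, function(i)
        stats::rmultinom(1, nonext[i], c(pn, 1 - sum(pn)))[, 1], integer(4))
      cvd[pos] <- draws[1, ]; resp[pos] <- draws[2, ]; canc[pos] <- draws[3, ]
    }
    male <- stats::rbinom(n, deaths, p$male)
    old <- stats::rbinom(n, deaths, p$age65plus)
    out$deaths_nonext <- nonext
    out$deaths_cvd <- cvd
    out$deaths_resp <- resp
    out$deaths_cancer <- canc
    out$deaths_male <- male
    out$deaths_female <- deaths - male
    out$deaths_0_64 <- deaths - old
    out$deaths_65plus <- old
  }
  out <- daily_series(out)
  attr(out, "true_mu") <- mu
  out
}

#' Simulate a complete daily dataset
#'
#' Convenience wrapper: [simulate_weather()] then [simulate_mortality()].
#'
#' @inheritParams simulate_mortality
#' @param config a [sim_config()].
#' @param surface a [true_surface()]; default the null surface.
#' @return A [daily_series()] with weather and count columns.
#' @export
simulate_daily <- function(config = sim_config(),
                           surface = true_surface("null"),
                           stratified = TRUE) {
  simulate_mortality(simulate_weather(config), surface, config, stratified)
}
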