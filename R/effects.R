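# Empirical percentiles of the temperature series actually analyzed
# (complete-case rows), linear interpolation between order statistics.
analyzed_percentiles <- function(model, p) {
  stats::quantile(model$temps[model$mask], probs = p / 100,
                  names = FALSE, type = 7)
}

#' Contrast vector for a cumulative temperature effect
#'
#' Builds the vector c over the cross-basis coefficients such that
#' \eqn{c^T \beta} is the log relative risk of \code{at_temp} versus
#' \code{ref_temp} cumulated over \code{lag_window}:
#' \deqn{c^T\beta = \sum_{l=l_0}^{l_1} [f(\mathrm{at}, l) - f(\mathrm{ref}, l)]}
#' with \eqn{f(x,l) = \sum_{j,k} \beta_{jk} V_j(x) B_k(l)}.
#'
#' @param cb a [crossbasis()] (or the one stored in a fitted model).
#' @param at_temp,ref_temp temperatures in degrees C.
#' @param lag_window integer pair (l0, l1), inclusive, within the lag
#'   range.
#' @return Numeric vector of length \code{ncol(cb)}.
#' @export
contrast_vector <- function(cb, at_temp, ref_temp, lag_window) {
  max_lag <- attr(cb, "max_lag")
  lag_window <- as.integer(round(lag_window))
  if (length(lag_window) != 2L || lag_window[1] > lag_window[2] ||
      lag_window[1] < 0L || lag_window[2] > max_lag)
    stop("'lag_window' must be (l0, l1) within 0..", max_lag)
  V <- eval_var_basis(c(at_temp, ref_temp), attr(cb, "var_type"),
                      attr(cb, "var_knots"))
  vdiff <- V[1, ] - V[2, ]
  L <- attr(cb, "lag_basis")
  lsum <- colSums(L[(lag_window[1]:lag_window[2]) + 1L, , drop = FALSE])
  # flatten in the cross-basis column order: (j - 1) * lag_df + k
  as.vector(t(outer(vdiff, lsum)))
}

#' Cumulative relative risk of a temperature contrast
#'
#' Point estimate and delta-method confidence interval of the relative
#' risk of \code{at} versus \code{ref} degrees C cumulated over a lag
#' window: RR = exp(c'b), CI = exp(c'b +/- z sqrt(c'Vc)) with V the
#' cross-basis block of the coefficient covariance.
#'
#' @param model a fitted [dlnm_nb()].
#' @param at,ref temperatures in degrees C.
#' @param lag_window integer pair, default the full lag range.
#' @param conf_level confidence level (default 0.95, z = 1.96).
#' @return Named numeric vector \code{c(rr, ci_low, ci_high)}.
#' @export
cumulative_rr <- function(model, at, ref, lag_window = NULL,
                          conf_level = 0.95) {
  cb <- model$crossbasis
  if (is.null(lag_window)) lag_window <- c(0L, attr(cb, "max_lag"))
  cv <- contrast_vector(cb, at, ref, lag_window)
  b <- coef(model, "crossbasis")
  V <- vcov(model, "crossbasis")
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("cross-basis covariance block is not positive semi-definite")
  est <- sum(cv * b)
  se <- sqrt(max(drop(cv %*% V %*% cv), 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(rr = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se))
}

#' Cumulative exposure-response curve
#'
#' Vectorises [cumulative_rr()] over a temperature grid at a fixed
#' reference (default the median of the analyzed temperature series) and
#' lag window, giving the overall cumulative temperature-mortality curve.
#'
#' @inheritParams cumulative_rr
#' @param temps temperature grid; default 50 points over the analyzed
#'   range.
#' @return A data frame of class \code{"effect_curve"} with columns
#'   \code{temp}, \code{rr}, \code{ci_low}, \code{ci_high}; the reference
#'   and window are attached as attributes.
#' @export
overall_curve <- function(model, temps = NULL, ref = NULL,
                          lag_window = NULL, conf_level = 0.95) {
  if (is.null(ref)) ref <- analyzed_percentiles(model, 50)
  if (is.null(temps)) {
    r <- range(model$temps[model$mask], na.rm = TRUE)
    temps <- seq(r[1], r[2], length.out = 50)
  }
  if (is.null(lag_window))
    lag_window <- c(0L, attr(model$crossbasis, "max_lag"))
  est <- t(vapply(temps, function(x)
    cumulative_rr(model, x, ref, lag_window, conf_level), numeric(3)))
  structure(data.frame(temp = temps, rr = est[, 1],
                       ci_low = est[, 2], ci_high = est[, 3]),
            ref_temp = ref, lag_window = lag_window,
            class = c("effect_curve", "data.frame"))
}

#' Single-lag relative-risk structure of a temperature contrast
#'
#' Relative risk of \code{at} versus \code{ref} at each individual lag
#' 0..max_lag, the lag-structure display used to diagnose acute effects
#' and mortality displacement (single-lag RRs dipping below 1 after an
#' acute excess).
#'
#' @inheritParams cumulative_rr
#' @return A data frame of class \code{"lag_curve"} with columns
#'   \code{lag}, \code{rr}, \code{ci_low}, \code{ci_high}.
#' @export
lag_structure <- function(model, at, ref, conf_level = 0.95) {
  max_lag <- attr(model$crossbasis, "max_lag")
  est <- t(vapply(0:max_lag, function(l)
    cumulative_rr(model, at, ref, c(l, l), conf_level), numeric(3)))
  structure(data.frame(lag = 0:max_lag, rr = est[, 1],
                       ci_low = est[, 2], ci_high = est[, 3]),
            at_temp = at, ref_temp = ref,
            class = c("lag_curve", "data.frame"))
}

#' High and low temperature effects at percentile contrasts
#'
#' The standard heat/cold summary: the cumulative RR of the hot-percentile
#' temperature versus the reference percentile over a short lag window
#' (default 99th vs 50th, lags 0-2), and of the cold percentile versus the
#' reference over a long window (default 1st vs 50th, lags 0-28).
#' Percentiles are computed from the analyzed (complete-case) temperature
#' series, or from \code{data} when supplied.
#'
#' @inheritParams cumulative_rr
#' @param p_cold,p_ref,p_hot percentiles (0-100).
#' @param hot_window,cold_window lag windows (clipped to the fitted lag
#'   range).
#' @param data optional daily series from which to take the temperature
#'   percentiles instead.
#' @return Data frame with one row per effect (\code{"hot"},
#'   \code{"cold"}): percentile, temperature, reference, window and RR
#'   with CI, plus a \code{significant} flag (CI excludes 1).
#' @export
percentile_effects <- function(model, p_cold = 1, p_ref = 50, p_hot = 99,
                               hot_window = c(0, 2), cold_window = c(0, 28),
                               data = NULL, conf_level = 0.95) {
  if (is.null(data)) {
    q <- analyzed_percentiles(model, c(p_cold, p_ref, p_hot))
  } else {
    tcol <- temperature_column(model$spec$temperature)
    q <- stats::quantile(data[[tcol]], probs = c(p_cold, p_ref, p_hot) / 100,
                         na.rm = TRUE, names = FALSE, type = 7)
  }
  max_lag <- attr(model$crossbasis, "max_lag")
  hot_window <- pmin(as.integer(hot_window), max_lag)
  cold_window <- pmin(as.integer(cold_window), max_lag)
  hot <- cumulative_rr(model, q[3], q[2], hot_window, conf_level)
  cold <- cumulative_rr(model, q[1], q[2], cold_window, conf_level)
  out <- data.frame(
    effect = c("hot", "cold"),
    percentile = c(p_hot, p_cold), temp = c(q[3], q[1]),
    ref_percentile = p_ref, ref_temp = q[2],
    lag_from = c(hot_window[1], cold_window[1]),
    lag_to = c(hot_window[2], cold_window[2]),
    rr = c(hot["rr"], cold["rr"]),
    ci_low = c(hot["ci_low"], cold["ci_low"]),
    ci_high = c(hot["ci_high"], cold["ci_high"]))
  out$significant <- out$ci_low > 1 | out$ci_high < 1
  out
}

#' @export
plot.effect_curve <- function(x, xlab = "Temperature (°C)",
                              ylab = "Cumulative RR", main = NULL, ...) {
  lw <- attr(x, "lag_window")
  if (is.null(main))
    main <- sprintf("Cumulative temperature effect, lag %d–%d",
                    lw[1], lw[2])
  graphics::plot(x$temp, x$rr, type = "n",
                 ylim = range(x$ci_low, x$ci_high, 1),
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::polygon(c(x$temp, rev(x$temp)), c(x$ci_low, rev(x$ci_high)),
                    col = "grey85", border = NA)
  graphics::lines(x$temp, x$rr, col = "red3", lwd = 2)
  graphics::abline(h = 1, lty = 2)
  graphics::abline(v = attr(x, "ref_temp"), lty = 3)
  invisible(x)
}

#' @export
plot.lag_curve <- function(x, xlab = "Lag (days)", ylab = "RR at single lag",
                           main = NULL, ...) {
  if (is.null(main))
    main <- sprintf("Lag structure: %.1f vs %.1f °C",
                    attr(x, "at_temp"), attr(x, "ref_temp"))
  graphics::plot(x$lag, x$rr, type = "n",
                 ylim = range(x$ci_low, x$ci_high, 1),
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::polygon(c(x$lag, rev(x$lag)), c(x$ci_low, rev(x$ci_high)),
                    col = "grey85", border = NA)
  graphics::lines(x$lag, x$rr, col = "red3", lwd = 2)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
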