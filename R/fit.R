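#' Model specification for a temperature-mortality DLNM
#'
#' Describes one negative binomial DLNM configuration: which temperature
#' indicator enters the cross-basis, the cross-basis dimensions, and the
#' confounder smooths.  The full design is
#' intercept + cross-basis + day-of-week indicators + NCS(time) +
#' NCS(humidity) + NCS(dew point).
#'
#' @param temperature temperature indicator used as exposure: daily
#'   \code{"average"}, \code{"maximum"} or \code{"minimum"}.
#' @param max_lag maximum lag in days (default 28).
#' @param var_df df of the temperature dimension of the cross-basis.
#' @param lag_df df of the lag dimension (counts the lag-intercept column;
#'   see [crossbasis()]).
#' @param time_df_per_year df per year of the time NCS controlling
#'   seasonality and long-term trend; the total df is
#'   \code{round(time_df_per_year * n_years)}.
#' @param humidity_df,dewpoint_df df of the confounder NCS terms; 0
#'   disables a term.
#' @param dow logical, include day-of-week indicators (reference Monday).
#' @param var_knots,lag_knots,var_type,lag_type,lag_intercept passed to
#'   [crossbasis()].
#' @return An object of class \code{"model_spec"}.
#' @seealso [hue2016()], [dlnm_nb()]
#' @export
model_spec <- function(temperature = c("average", "maximum", "minimum"),
                       max_lag = 28L, var_df = 4L, lag_df = 5L,
                       time_df_per_year = 5, humidity_df = 3L,
                       dewpoint_df = 3L, dow = TRUE,
                       var_knots = NULL, lag_knots = NULL,
                       var_type = "ncs", lag_type = "ncs",
                       lag_intercept = TRUE) {
  temperature <- match.arg(temperature)
  stopifnot(max_lag >= 0, var_df >= 1, lag_df >= 1, time_df_per_year > 0,
            humidity_df >= 0, dewpoint_df >= 0)
  structure(
    list(temperature = temperature, max_lag = as.integer(max_lag),
         var_df = as.integer(var_df), lag_df = as.integer(lag_df),
         time_df_per_year = time_df_per_year,
         humidity_df = as.integer(humidity_df),
         dewpoint_df = as.integer(dewpoint_df), dow = isTRUE(dow),
         var_knots = var_knots, lag_knots = lag_knots,
         var_type = var_type, lag_type = lag_type,
         lag_intercept = isTRUE(lag_intercept)),
    class = "model_spec")
}

#' The published tropical-monsoon-city model configuration
#'
#' Ready-made [model_spec()] matching the final all-cause model of a
#' five-year tropical-monsoon-city temperature-mortality analysis: daily
#' average temperature, an NCS-NCS cross-basis with 4 df on the
#' temperature dimension and 5 df on the lag dimension, maximum lag 28
#' days, 5 df per year of time spline, and 3-df humidity and dew point
#' smooths with day-of-week indicators.
#'
#' @return A [model_spec()].
#' @export
hue2016 <- function() model_spec()

#' @export
print.model_spec <- function(x, ...) {
  cat("DLNM model specification\n")
  cat("  exposure:    ", x$temperature, " temperature, ", x$var_type,
      " basis, df ", x$var_df, "\n", sep = "")
  cat("  lag:         0..", x$max_lag, " days, ", x$lag_type,
      " basis, df ", x$lag_df, "\n", sep = "")
  cat("  time spline: ", x$time_df_per_year, " df/year\n", sep = "")
  cat("  confounders: humidity df ", x$humidity_df, ", dew point df ",
      x$dewpoint_df, if (x$dow) ", day of week", "\n", sep = "")
  invisible(x)
}

temperature_column <- function(indicator) {
  switch(indicator, average = "tavg", maximum = "tmax", minimum = "tmin")
}

#' Assemble the DLNM design matrix
#'
#' Builds the full design for one [model_spec()] from a daily series:
#' intercept, cross-basis columns, six day-of-week indicators (Monday
#' reference), the time NCS, and the humidity and dew point NCS terms.
#' Rows with an incomplete lag window or a missing covariate or count are
#' masked, not dropped, so row indices stay aligned with the input days.
#'
#' @param data a [daily_series()] (or data frame with its columns).
#' @param spec a [model_spec()].
#' @param outcome name of the death-count column to model.
#' @return List with \code{design} (matrix, named columns), \code{response}
#'   (integer vector), \code{mask} (logical rows used), \code{crossbasis},
#'   \code{blocks} (named list of column index vectors) and \code{temps}
#'   (the exposure series).
#' @export
assemble_design <- function(data, spec, outcome = "deaths_all") {
  stopifnot(inherits(spec, "model_spec"))
  tcol <- temperature_column(spec$temperature)
  need <- c("date", tcol, outcome,
            if (spec$humidity_df > 0) "humidity",
            if (spec$dewpoint_df > 0) "dewpoint")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  y <- data[[outcome]]
  if (any(y < 0 | (is.finite(y) & y != round(y)), na.rm = TRUE))
    stop("death counts must be non-negative integers")
  n <- nrow(data)
  dates <- as.Date(data$date)
  cb <- crossbasis(data[[tcol]], max_lag = spec$max_lag,
                   var_df = spec$var_df, lag_df = spec$lag_df,
                   var_knots = spec$var_knots, lag_knots = spec$lag_knots,
                   var_type = spec$var_type, lag_type = spec$lag_type,
                   lag_intercept = spec$lag_intercept, dates = dates)
  blocks <- list(intercept = 1L)
  design <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  cb_cols <- ncol(design) + seq_len(ncol(cb))
  cbm <- unclass(cb); attributes(cbm)[setdiff(names(attributes(cbm)),
                                              c("dim", "dimnames"))] <- NULL
  colnames(cbm) <- paste0("cb.", colnames(cb))
  design <- cbind(design, cbm)
  blocks$crossbasis <- cb_cols
  if (spec$dow) {
    wd <- factor(format(dates, "%u"), levels = as.character(1:7),
                 labels = c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun"))
    D <- stats::model.matrix(~wd)[, -1, drop = FALSE]
    colnames(D) <- paste0("dow.", sub("^wd", "", colnames(D)))
    blocks$dow <- ncol(design) + seq_len(ncol(D))
    design <- cbind(design, D)
  }
  n_years <- n / 365.25
  time_df <- max(1L, as.integer(round(spec$time_df_per_year * n_years)))
  tt <- seq_len(n)
  Tm <- ncs_basis(tt, place_knots(tt, time_df, "time"))
  colnames(Tm) <- paste0("time.", seq_len(ncol(Tm)))
  blocks$time <- ncol(design) + seq_len(ncol(Tm))
  design <- cbind(design, Tm)
  conf_block <- function(col, df, label) {
    v <- data[[col]]
    B <- matrix(NA_real_, n, df)
    ok <- is.finite(v)
    B[ok, ] <- ncs_basis(v[ok], place_knots(v, df, label))
    colnames(B) <- paste0(label, ".", seq_len(df))
    B
  }
  if (spec$humidity_df > 0) {
    H <- conf_block("humidity", spec$humidity_df, "humidity")
    blocks$humidity <- ncol(design) + seq_len(ncol(H))
    design <- cbind(design, H)
  }
  if (spec$dewpoint_df > 0) {
    Dp <- conf_block("dewpoint", spec$dewpoint_df, "dewpoint")
    blocks$dewpoint <- ncol(design) + seq_len(ncol(Dp))
    design <- cbind(design, Dp)
  }
  mask <- attr(cb, "complete") & !is.na(y) &
    rowSums(is.na(design)) == 0L
  list(design = design, response = as.integer(y), mask = mask,
       crossbasis = cb, blocks = blocks, temps = data[[tcol]])
}

#' Fit a negative binomial regression on an assembled design
#'
#' Maximises the NB2 log-likelihood (log link, variance mu + mu^2/theta)
#' jointly over coefficients and dispersion on the masked rows.  The AIC
#' counts the dispersion parameter: AIC = -2 loglik + 2 (p + 1).
#'
#' @param design numeric design matrix including an intercept column.
#' @param response integer counts.
#' @param mask logical vector of rows to use.
#' @return List with \code{coefficients}, \code{vcov}, \code{theta},
#'   \code{theta_se}, \code{loglik}, \code{aic}, \code{n_used},
#'   \code{fitted} (on masked rows), \code{converged}.
#' @export
fit_negbin <- function(design, response, mask = rep(TRUE, length(response))) {
  X <- design[mask, , drop = FALSE]
  y <- response[mask]
  if (!length(y)) stop("no usable rows after masking")
  if (all(y == 0)) stop("degenerate response: all counts are zero")
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X))
    warning("design is rank deficient (rank ", qr_X$rank, " < ",
            ncol(X), " columns)")
  dd <- cbind(data.frame(y = y), as.data.frame(X))
  fit <- tryCatch(
    MASS::glm.nb(y ~ . - 1, data = dd,
                 control = stats::glm.control(maxit = 100)),
    error = identity)
  if (inherits(fit, "condition")) {
    # theta iteration diverges on un- or under-dispersed counts; the NB
    # then degenerates to its Poisson limit, fitted at a fixed huge theta
    fit <- tryCatch(
      stats::glm(y ~ . - 1, data = dd,
                 family = MASS::negative.binomial(theta = 1e8)),
      error = function(e) stop("negative binomial fit failed: ",
                               conditionMessage(e), call. = FALSE))
    fit$theta <- 1e8
    fit$SE.theta <- NA_real_
    # ML covariance (dispersion fixed at 1), as glm.nb would report
    fit$ml_vcov <- summary(fit, dispersion = 1)$cov.scaled
  }
  if (!fit$converged)
    stop("negative binomial fit did not converge after ",
         fit$control$maxit, " IRLS iterations")
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  V <- if (is.null(fit$ml_vcov)) stats::vcov(fit) else fit$ml_vcov
  if (nrow(V) == ncol(X)) dimnames(V) <- list(colnames(X), colnames(X))
  mu <- stats::fitted(fit)
  ll <- sum(stats::dnbinom(y, mu = mu, size = fit$theta, log = TRUE))
  list(coefficients = beta, vcov = V,
       theta = fit$theta, theta_se = fit$SE.theta,
       loglik = ll, aic = -2 * ll + 2 * (length(beta) + 1),
       n_used = length(y), fitted = mu,
       converged = fit$converged)
}

#' Fit a temperature-mortality DLNM
#'
#' The central fitting function: assembles the design of a [model_spec()]
#' on a daily series and fits the negative binomial DLNM.  The returned
#' object supports \code{print}, \code{summary}, \code{coef}, \code{vcov},
#' \code{logLik}/\code{AIC}, \code{predict} (cumulative relative-risk
#' curves), \code{plot}, \code{residuals}, \code{fitted} and
#' \code{simulate}, plus the effect summaries [cumulative_rr()],
#' [overall_curve()], [lag_structure()] and [percentile_effects()].
#'
#' @param data a [daily_series()].
#' @param spec a [model_spec()]; default [hue2016()].
#' @param outcome death-count column to model.
#' @return An object of class \code{"dlnm_nb"}.
#' @examples
#' sim <- simulate_daily(sim_config(n_years = 3, seed = 1),
#'                       true_surface("J"))
#' fit <- dlnm_nb(sim, model_spec(max_lag = 14, time_df_per_year = 5))
#' fit
#' percentile_effects(fit, cold_window = c(0, 14))
#' @export
dlnm_nb <- function(data, spec = hue2016(), outcome = "deaths_all") {
  asm <- assemble_design(data, spec, outcome)
  fit <- fit_negbin(asm$design, asm$response, asm$mask)
  cbi <- asm$blocks$crossbasis
  if (anyNA(fit$coefficients[cbi]))
    stop("cross-basis coefficients are aliased; reduce the basis df")
  structure(
    list(coefficients = fit$coefficients, vcov = fit$vcov,
         theta = fit$theta, theta_se = fit$theta_se,
         loglik = fit$loglik, aic = fit$aic, n_used = fit$n_used,
         converged = fit$converged, spec = spec, outcome = outcome,
         crossbasis = asm$crossbasis, blocks = asm$blocks,
         design = asm$design, response = asm$response, mask = asm$mask,
         temps = asm$temps, fitted_masked = fit$fitted),
    class = "dlnm_nb")
}

#' @export
print.dlnm_nb <- function(x, ...) {
  cat("Negative binomial DLNM fit (outcome: ", x$outcome, ")\n", sep = "")
  cat("  days used:", x$n_used, "  dispersion theta:",
      format(x$theta, digits = 4), "\n")
  cat("  AIC:", format(x$aic, digits = 7), "\n")
  print(x$spec)
  invisible(x)
}

#' @export
coef.dlnm_nb <- function(object, block = NULL, ...) {
  if (is.null(block)) object$coefficients
  else object$coefficients[object$blocks[[block]]]
}

#' @export
vcov.dlnm_nb <- function(object, block = NULL, ...) {
  if (is.null(block)) object$vcov
  else object$vcov[object$blocks[[block]], object$blocks[[block]],
                   drop = FALSE]
}

#' @export
logLik.dlnm_nb <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n_used, class = "logLik")
}

#' @export
fitted.dlnm_nb <- function(object, ...) {
  out <- rep(NA_real_, length(object$response))
  out[object$mask] <- object$fitted_masked
  out
}

#' @export
residuals.dlnm_nb <- function(object,
                              type = c("deviance", "pearson", "response"),
                              ...) {
  type <- match.arg(type)
  y <- object$response[object$mask]
  mu <- object$fitted_masked
  th <- object$theta
  r <- switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu + mu^2 / th),
    deviance = {
      d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) -
                  (y + th) * log((y + th) / (mu + th)))
      sign(y - mu) * sqrt(pmax(d, 0))
    })
  out <- rep(NA_real_, length(object$response))
  out[object$mask] <- r
  out
}

#' @export
simulate.dlnm_nb <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted_masked
  out <- replicate(nsim, stats::rnbinom(length(mu), mu = mu,
                                        size = object$theta),
                   simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}

#' @export
summary.dlnm_nb <- function(object, ...) {
  eff <- tryCatch(percentile_effects(object), error = function(e) NULL)
  structure(list(fit = object, effects = eff), class = "summary.dlnm_nb")
}

#' @export
print.summary.dlnm_nb <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$effects)) {
    cat("Percentile temperature contrasts:\n")
    print(x$effects, digits = 3)
  }
  invisible(x)
}

#' Predict cumulative relative-risk curves
#'
#' @param object a fitted [dlnm_nb()] model.
#' @param temps temperature grid (default 50 points over the analyzed
#'   range).
#' @param ref reference temperature (default median of the analyzed
#'   series).
#' @param lag_window integer pair (l0, l1), default the full lag range.
#' @param ... unused.
#' @return An [overall_curve()] data frame.
#' @export
predict.dlnm_nb <- function(object, temps = NULL, ref = NULL,
                            lag_window = NULL, ...) {
  overall_curve(object, temps = temps, ref = ref, lag_window = lag_window)
}

#' @export
plot.dlnm_nb <- function(x, which = c("overall", "lags"), ...) {
  which <- match.arg(which)
  if (which == "overall") plot(overall_curve(x), ...)
  else {
    pct <- analyzed_percentiles(x, c(99, 50))
    plot(lag_structure(x, at = pct[1], ref = pct[2]), ...)
  }
}
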