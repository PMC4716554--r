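#' Residual diagnostics for a fitted DLNM
#'
#' Generic model checking for the negative binomial time-series fit:
#' deviance and Pearson residual series, residual autocorrelation at lags
#' 1..30, and the Pearson dispersion ratio (sum of squared Pearson
#' residuals over residual df; near 1 when the NB2 variance function
#' matches the data).
#'
#' @param model a fitted [dlnm_nb()].
#' @param acf_lags number of autocorrelation lags (default 30).
#' @return An object of class \code{"dlnm_diagnostics"}: list with
#'   \code{deviance}, \code{pearson} (residuals on masked rows),
#'   \code{acf} (named vector, lags 1..acf_lags), \code{dispersion_ratio},
#'   \code{n_used}.
#' @export
diagnostics <- function(model, acf_lags = 30L) {
  stopifnot(inherits(model, "dlnm_nb"))
  dev <- residuals(model, "deviance")[model$mask]
  pea <- residuals(model, "pearson")[model$mask]
  df_res <- model$n_used - length(model$coefficients)
  ac <- stats::acf(dev, lag.max = acf_lags, plot = FALSE,
                   na.action = stats::na.pass)$acf[-1]
  names(ac) <- seq_len(acf_lags)
  structure(
    list(deviance = dev, pearson = pea, acf = ac,
         dispersion_ratio = sum(pea^2) / df_res, n_used = model$n_used),
    class = "dlnm_diagnostics")
}

#' @export
print.dlnm_diagnostics <- function(x, ...) {
  band <- 2 / sqrt(x$n_used)
  cat("DLNM residual diagnostics (", x$n_used, " days)\n", sep = "")
  cat("  Pearson dispersion ratio:", format(x$dispersion_ratio, digits = 3),
      "\n")
  cat("  residual ACF lags outside +/-", format(band, digits = 2), ":",
      sum(abs(x$acf) > band), "of", length(x$acf), "\n")
  invisible(x)
}
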