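# Internal basis evaluators used by the cross-basis and the effect
# summaries.  NA values are allowed here (they mark unavailable lags) and
# propagate to NA basis rows; user-facing ncs_basis() rejects them instead.
eval_var_basis <- function(x, type, knots) {
  if (type == "lin")
    return(matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, "v1")))
  out <- matrix(NA_real_, length(x), knots$df)
  ok <- is.finite(x)
  if (any(ok)) out[ok, ] <- ncs_basis(x[ok], knots)
  colnames(out) <- paste0("v", seq_len(ncol(out)))
  out
}

# Lag basis over integer lags 0..max_lag.  With lag_intercept = TRUE the
# stated lag df counts a constant-in-lag column, so the NCS part has
# df - 1 columns; a 1-df lag basis is then the plain cumulative term.
eval_lag_basis <- function(max_lag, df, type, knots, lag_intercept) {
  lags <- 0:max_lag
  if (type == "strata") {
    L <- diag(max_lag + 1L)
  } else if (lag_intercept) {
    L <- if (df == 1L) matrix(1, max_lag + 1L, 1L)
    else cbind(1, ncs_basis(lags, knots))
  } else {
    L <- ncs_basis(lags, knots)
  }
  dimnames(L) <- list(paste0("lag", lags), paste0("l", seq_len(ncol(L))))
  L
}

#' Lagged exposure matrix
#'
#' Builds the matrix Q with Q[t, l + 1] = series[t - l] for lags
#' l = 0..max_lag.  Entries whose lag reaches before the start of the
#' series are NA, so the first \code{max_lag} rows are incomplete.
#'
#' @param series numeric vector (NAs allowed; they propagate).
#' @param max_lag non-negative integer.
#' @return Numeric matrix with \code{length(series)} rows and
#'   \code{max_lag + 1} columns named \code{lag0..lagL}.
#' @export
lag_matrix <- function(series, max_lag) {
  max_lag <- as.integer(max_lag)
  if (max_lag < 0L) stop("'max_lag' must be non-negative")
  n <- length(series)
  if (n <= max_lag)
    stop("series must be longer than 'max_lag'")
  Q <- vapply(0:max_lag, function(l)
    c(rep(NA_real_, l), series[seq_len(n - l)]), numeric(n))
  dimnames(Q) <- list(NULL, paste0("lag", 0:max_lag))
  Q
}

#' Cross-basis of a daily exposure series
#'
#' Constructs the tensor-product cross-basis of a distributed lag
#' non-linear model: the basis over the exposure dimension (natural cubic
#' spline, or plain linear) crossed with the basis over the lag dimension
#' (NCS on integer lags with a lag-intercept column, or one indicator per
#' lag).  Column (j, k) at day t is
#' \deqn{\sum_{l=0}^{L} V_j(x_{t-l}) \, B_k(l)}
#' where V is the exposure basis and B the lag basis.  Rows whose lag
#' window reaches before the series start, or spans an NA in the series,
#' are flagged incomplete (attribute \code{"complete"}) rather than
#' silently dropped.
#'
#' @param x numeric exposure series (daily); NAs mark gaps and make every
#'   row whose window spans them incomplete.
#' @param max_lag maximum lag in days.
#' @param var_df df of the exposure basis (ignored when \code{var_knots}
#'   given, or when \code{var_type = "lin"} which always has 1 df).
#' @param lag_df df of the lag basis, counting the lag-intercept column
#'   when \code{lag_intercept = TRUE}.
#' @param var_knots,lag_knots optional explicit [knot_spec()]s overriding
#'   the defaults (exposure knots at equally spaced quantiles of \code{x};
#'   lag knots equally spaced on the raw lag scale).
#' @param var_type \code{"ncs"} or \code{"lin"} (identity, 1 column).
#' @param lag_type \code{"ncs"} or \code{"strata"} (one indicator per lag;
#'   df becomes \code{max_lag + 1}).
#' @param lag_intercept logical; whether the stated \code{lag_df} includes
#'   a constant-in-lag column (the default convention here).
#' @param dates optional \code{Date} vector aligned with \code{x}; must be
#'   contiguous daily dates (pad gaps with NA rows first).
#' @return An object of class \code{"crossbasis"}: the n x (var_df*lag_df)
#'   basis matrix with attributes \code{complete}, \code{var_knots},
#'   \code{var_type}, \code{lag_basis}, \code{max_lag}, \code{var_df},
#'   \code{lag_df}, \code{dates}.
#' @examples
#' x <- 20 + 5 * sin(seq(0, 6 * pi, length.out = 200))
#' cb <- crossbasis(x, max_lag = 7, var_df = 3, lag_df = 3)
#' dim(cb)         # 200 x 9
#' sum(!attr(cb, "complete"))  # the 7 leading rows are incomplete
#' @export
crossbasis <- function(x, max_lag, var_df = 4L, lag_df = 5L,
                       var_knots = NULL, lag_knots = NULL,
                       var_type = c("ncs", "lin"),
                       lag_type = c("ncs", "strata"),
                       lag_intercept = TRUE, dates = NULL) {
  var_type <- match.arg(var_type)
  lag_type <- match.arg(lag_type)
  max_lag <- as.integer(max_lag)
  if (!is.null(dates)) {
    if (length(dates) != length(x))
      stop("'dates' and 'x' lengths differ")
    if (length(dates) > 1L && any(diff(as.integer(as.Date(dates))) != 1L))
      stop("'dates' must be contiguous daily dates; pad gaps with NA rows")
  }
  if (var_type == "lin") {
    var_df <- 1L
    if (is.null(var_knots))
      var_knots <- knot_spec(numeric(0), range(x, na.rm = TRUE))
  } else if (is.null(var_knots)) {
    var_knots <- place_knots(x, var_df, "exposure")
  } else {
    if (!inherits(var_knots, "knot_spec")) stop("'var_knots' must be a knot_spec")
    var_df <- var_knots$df
  }
  if (lag_type == "strata") {
    lag_df <- max_lag + 1L
    lag_knots <- NULL
  } else {
    lag_df <- as.integer(lag_df)
    ncs_df <- if (lag_intercept) lag_df - 1L else lag_df
    if (lag_df < 1L || (!lag_intercept && lag_df < 1L))
      stop("'lag_df' must be at least 1")
    if (is.null(lag_knots)) {
      if (ncs_df > 0L) lag_knots <- place_lag_knots(max_lag, ncs_df)
    } else {
      if (!inherits(lag_knots, "knot_spec")) stop("'lag_knots' must be a knot_spec")
      if (!isTRUE(all.equal(lag_knots$boundary, c(0, max_lag))))
        stop("lag knot boundary must be (0, max_lag)")
      lag_df <- lag_knots$df + if (lag_intercept) 1L else 0L
    }
  }
  L <- eval_lag_basis(max_lag, lag_df, lag_type, lag_knots, lag_intercept)
  Q <- lag_matrix(x, max_lag)
  n <- length(x)
  complete <- rowSums(is.na(Q)) == 0L
  CB <- matrix(0, n, var_df * lag_df)
  for (l in 0:max_lag) {
    V <- eval_var_basis(Q[, l + 1L], var_type, var_knots)
    contrib <- V[, rep(seq_len(var_df), each = lag_df), drop = FALSE] *
      matrix(L[l + 1L, ], n, var_df * lag_df, byrow = TRUE)
    CB <- CB + contrib
  }
  CB[!complete, ] <- NA_real_
  colnames(CB) <- paste0("v", rep(seq_len(var_df), each = lag_df),
                         ".l", rep(seq_len(lag_df), var_df))
  structure(CB,
            complete = complete, var_knots = var_knots, var_type = var_type,
            lag_basis = L, lag_knots = lag_knots, lag_intercept = lag_intercept,
            lag_type = lag_type, max_lag = max_lag,
            var_df = var_df, lag_df = lag_df,
            dates = dates, class = c("crossbasis", "matrix"))
}

#' @export
print.crossbasis <- function(x, ...) {
  cat("Cross-basis matrix:", nrow(x), "days x", ncol(x), "terms\n",
      " exposure basis:", attr(x, "var_type"), "df", attr(x, "var_df"), "\n",
      " lag basis:     ", attr(x, "lag_type"), "df", attr(x, "lag_df"),
      "over lags 0..", attr(x, "max_lag"), "\n",
      " complete rows: ", sum(attr(x, "complete")), "of", nrow(x), "\n")
  invisible(x)
}

# Column of the cross-basis holding exposure-basis j crossed with
# lag-basis k (column-order contract used throughout).
cb_column_index <- function(cb, j, k) {
  (j - 1L) * attr(cb, "lag_df") + k
}
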