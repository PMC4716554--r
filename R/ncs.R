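#' Knot specification for a natural cubic spline basis
#'
#' Bundles the interior and boundary knots of a natural cubic spline (NCS).
#' An NCS without intercept on \code{k} interior knots has \code{k + 1}
#' basis columns, so \code{df = length(interior) + 1}.
#'
#' @param interior numeric vector of interior knots, strictly increasing and
#'   strictly inside the boundary pair; may be empty (linear basis).
#' @param boundary numeric pair bracketing the interior knots.
#' @param variable optional label for the variable being splined.
#' @return An object of class \code{"knot_spec"} with elements
#'   \code{interior}, \code{boundary}, \code{df} and \code{variable}.
#' @seealso [place_knots()], [ncs_basis()]
#' @export
knot_spec <- function(interior = numeric(0), boundary, variable = "") {
  interior <- as.numeric(interior)
  boundary <- as.numeric(boundary)
  if (length(boundary) != 2L || any(!is.finite(boundary)) ||
      boundary[1] >= boundary[2])
    stop("'boundary' must be two finite increasing values")
  if (length(interior)) {
    if (any(!is.finite(interior)))
      stop("interior knots must be finite")
    if (is.unsorted(interior, strictly = TRUE))
      stop("interior knots must be strictly increasing")
    if (min(interior) <= boundary[1] || max(interior) >= boundary[2])
      stop("interior knots must lie strictly inside the boundary knots")
  }
  structure(
    list(interior = interior, boundary = boundary,
         df = length(interior) + 1L, variable = as.character(variable)),
    class = "knot_spec")
}

#' @export
print.knot_spec <- function(x, ...) {
  cat("Knot specification", if (nzchar(x$variable)) paste0("(", x$variable, ")"),
      "\n  df:", x$df,
      "\n  boundary:", format(x$boundary),
      "\n  interior:",
      if (length(x$interior)) format(x$interior) else "(none)", "\n")
  invisible(x)
}

#' Place spline knots at equally spaced quantiles
#'
#' Default knot placement for exposure, time and confounder dimensions:
#' boundary knots at the observed range and \code{df - 1} interior knots at
#' the \code{k/df} empirical quantiles (linear interpolation between order
#' statistics, the package-wide quantile rule).
#'
#' @param values numeric vector of observed values (NAs dropped).
#' @param df positive integer, number of basis columns.
#' @param variable optional label.
#' @return A [knot_spec()].
#' @examples
#' place_knots(0:100, df = 4)  # interior knots at 25, 50, 75
#' @export
place_knots <- function(values, df, variable = "") {
  values <- values[!is.na(values)]
  if (!length(values) || any(!is.finite(values)))
    stop("'values' must be non-empty and finite")
  df <- as.integer(df)
  if (df < 1L) stop("'df' must be a positive integer")
  if (df > length(unique(values)))
    stop("insufficient distinct values for the requested df")
  interior <- if (df > 1L)
    stats::quantile(values, probs = seq_len(df - 1L) / df,
                    names = FALSE, type = 7)
  else numeric(0)
  if (length(interior) && is.unsorted(interior, strictly = TRUE))
    stop("insufficient distinct values: tied quantile knots")
  knot_spec(interior, range(values), variable)
}

#' Place lag-dimension knots at equally spaced lags
#'
#' Knots for the lag dimension of a cross-basis: boundary at (0, max_lag)
#' and interior knots equally spaced on the raw lag scale.
#'
#' @param max_lag non-negative integer, maximum lag in days.
#' @param df positive integer, basis columns of the NCS part.
#' @return A [knot_spec()].
#' @export
place_lag_knots <- function(max_lag, df) {
  if (max_lag < 1L) stop("'max_lag' must be at least 1 to spline over lags")
  df <- as.integer(df)
  if (df < 1L) stop("'df' must be a positive integer")
  interior <- if (df > 1L)
    seq(0, max_lag, length.out = df + 1L)[2:df]
  else numeric(0)
  knot_spec(interior, c(0, max_lag), "lag")
}

#' Evaluate a natural cubic spline basis
#'
#' Returns the df-column NCS basis (no intercept column) defined by a
#' [knot_spec()], evaluated at \code{x}.  Beyond the boundary knots every
#' basis function continues linearly (the natural condition), so prediction
#' grids may slightly exceed the observed range.
#'
#' @param x numeric vector of evaluation points (all finite).
#' @param knots a [knot_spec()].
#' @return Numeric matrix, \code{length(x)} rows and \code{knots$df}
#'   columns, with the knot specification attached as attribute
#'   \code{"knots"}.
#' @export
ncs_basis <- function(x, knots) {
  if (!inherits(knots, "knot_spec")) stop("'knots' must be a knot_spec")
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite x at rows: ", paste(utils::head(bad, 10), collapse = ", "))
  b <- if (length(knots$interior))
    splines::ns(x, knots = knots$interior, Boundary.knots = knots$boundary)
  else
    splines::ns(x, df = 1L, Boundary.knots = knots$boundary)
  b <- unclass(b)[, , drop = FALSE]
  dimnames(b) <- list(NULL, paste0("s", seq_len(ncol(b))))
  attributes(b)$knots <- knots
  b
}
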