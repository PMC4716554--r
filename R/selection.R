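#' Candidate grid for AIC model selection
#'
#' Candidates for the four staged selection steps: (1) df per year of the
#' time spline, (2) temperature indicator, (3) temperature-dimension df of
#' the cross-basis, (4) lag-dimension df.
#'
#' @param time_df_per_year numeric candidates (default 3..10).
#' @param indicators subset of \code{c("maximum","average","minimum")}.
#' @param var_df integer candidates (default 2..6).
#' @param lag_df integer candidates (default 2..6).
#' @param max_lag maximum lag used throughout (default 28).
#' @return An object of class \code{"selection_grid"}.
#' @export
selection_grid <- function(time_df_per_year = 3:10,
                           indicators = c("maximum", "average", "minimum"),
                           var_df = 2:6, lag_df = 2:6, max_lag = 28L) {
  indicators <- match.arg(indicators, several.ok = TRUE)
  stopifnot(length(time_df_per_year) > 0, length(var_df) > 0,
            length(lag_df) > 0)
  structure(list(time_df_per_year = sort(time_df_per_year),
                 indicators = indicators,
                 var_df = sort(as.integer(var_df)),
                 lag_df = sort(as.integer(lag_df)),
                 max_lag = as.integer(max_lag)),
            class = "selection_grid")
}

# Midpoint default used for not-yet-selected components in the staged
# strategy; "average" for the indicator when available.
grid_midpoint <- function(v) v[ceiling(length(v) / 2)]
default_indicator <- function(ind)
  if ("average" %in% ind) "average" else ind[1]

spec_from <- function(grid, time_df, indicator, var_df, lag_df, base) {
  model_spec(temperature = indicator, max_lag = grid$max_lag,
             var_df = var_df, lag_df = lag_df,
             time_df_per_year = time_df,
             humidity_df = base$humidity_df, dewpoint_df = base$dewpoint_df,
             dow = base$dow, lag_intercept = base$lag_intercept)
}

try_aic <- function(data, spec, outcome) {
  fit <- tryCatch(suppressWarnings(dlnm_nb(data, spec, outcome)),
                  error = identity)
  if (inherits(fit, "condition"))
    list(aic = NA_real_, reason = conditionMessage(fit))
  else list(aic = fit$aic, reason = "")
}

#' AIC-driven model selection for the temperature-mortality DLNM
#'
#' Objective-oriented model choice by the AIC rule (smaller is better)
#' over the time-spline df, temperature indicator, and cross-basis
#' dimensions.  The \code{"sequential"} strategy fixes one component per
#' step in the order time df, indicator, temperature df, lag df, holding
#' not-yet-selected components at the midpoint of their candidate range
#' (indicator: average temperature).  The \code{"exhaustive"} strategy
#' fits the full Cartesian grid.  Ties break toward the smaller df, then
#' toward average temperature.
#'
#' @param data a [daily_series()].
#' @param grid a [selection_grid()].
#' @param strategy \code{"sequential"} or \code{"exhaustive"}.
#' @param outcome death-count column selected on (default all-cause).
#' @param base a [model_spec()] supplying the non-searched components
#'   (confounder dfs, day of week, lag-intercept convention).
#' @return An object of class \code{"dlnm_selection"}: list with
#'   \code{spec} (the chosen [model_spec()]), \code{trace} (data frame of
#'   every fit attempted: step, component, candidate, aic, reason),
#'   \code{strategy} and \code{fit} (the refitted chosen model).
#' @export
select_model <- function(data, grid = selection_grid(),
                         strategy = c("sequential", "exhaustive"),
                         outcome = "deaths_all", base = model_spec()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(grid, "selection_grid"))
  trace <- data.frame(step = integer(), component = character(),
                      candidate = character(), aic = numeric(),
                      reason = character())
  add <- function(step, component, candidate, res) {
    trace[nrow(trace) + 1L, ] <<- list(step, component,
                                       as.character(candidate),
                                       res$aic, res$reason)
  }
  pick <- function(cands, aics) {
    # candidates are pre-ordered by parsimony preference
    if (all(is.na(aics))) stop("all candidate fits failed")
    cands[which.min(aics)]
  }
  if (strategy == "sequential") {
    ind0 <- default_indicator(grid$indicators)
    var0 <- grid_midpoint(grid$var_df)
    lag0 <- grid_midpoint(grid$lag_df)
    aics <- vapply(grid$time_df_per_year, function(tdf) {
      res <- try_aic(data, spec_from(grid, tdf, ind0, var0, lag0, base),
                     outcome)
      add(1L, "time_df_per_year", tdf, res)
      res$aic
    }, numeric(1))
    time_sel <- pick(grid$time_df_per_year, aics)
    ord <- order(match(grid$indicators,
                       c("average", "maximum", "minimum")))
    inds <- grid$indicators[ord]
    aics <- vapply(inds, function(ind) {
      res <- try_aic(data, spec_from(grid, time_sel, ind, var0, lag0, base),
                     outcome)
      add(2L, "indicator", ind, res)
      res$aic
    }, numeric(1))
    ind_sel <- pick(inds, aics)
    aics <- vapply(grid$var_df, function(v) {
      res <- try_aic(data, spec_from(grid, time_sel, ind_sel, v, lag0, base),
                     outcome)
      add(3L, "var_df", v, res)
      res$aic
    }, numeric(1))
    var_sel <- pick(grid$var_df, aics)
    aics <- vapply(grid$lag_df, function(ld) {
      res <- try_aic(data, spec_from(grid, time_sel, ind_sel, var_sel, ld,
                                     base), outcome)
      add(4L, "lag_df", ld, res)
      res$aic
    }, numeric(1))
    lag_sel <- pick(grid$lag_df, aics)
    chosen <- spec_from(grid, time_sel, ind_sel, var_sel, lag_sel, base)
  } else {
    cands <- expand.grid(
      lag_df = grid$lag_df, var_df = grid$var_df,
      indicator = grid$indicators[order(match(grid$indicators,
        c("average", "maximum", "minimum")))],
      time_df = grid$time_df_per_year,
      stringsAsFactors = FALSE)
    # order rows so that which.min's first-minimum tie-break prefers
    # smaller dfs, then average temperature
    cands <- cands[order(cands$var_df + cands$lag_df, cands$var_df,
                         cands$lag_df, match(cands$indicator,
                           c("average", "maximum", "minimum")),
                         cands$time_df), ]
    aics <- vapply(seq_len(nrow(cands)), function(i) {
      sp <- spec_from(grid, cands$time_df[i], cands$indicator[i],
                      cands$var_df[i], cands$lag_df[i], base)
      res <- try_aic(data, sp, outcome)
      add(1L, "exhaustive",
          sprintf("time=%g,%s,var=%d,lag=%d", cands$time_df[i],
                  cands$indicator[i], cands$var_df[i], cands$lag_df[i]),
          res)
      res$aic
    }, numeric(1))
    if (all(is.na(aics))) stop("all candidate fits failed")
    best <- which.min(aics)
    chosen <- spec_from(grid, cands$time_df[best], cands$indicator[best],
                        cands$var_df[best], cands$lag_df[best], base)
  }
  structure(list(spec = chosen, trace = trace, strategy = strategy,
                 fit = dlnm_nb(data, chosen, outcome)),
            class = "dlnm_selection")
}

#' @export
print.dlnm_selection <- function(x, ...) {
  cat("AIC model selection (", x$strategy, " strategy, ",
      nrow(x$trace), " fits attempted)\n", sep = "")
  cat("Chosen configuration (AIC ", format(x$fit$aic, digits = 7), "):\n",
      sep = "")
  print(x$spec)
  invisible(x)
}
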