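#' Study configuration
#'
#' Options controlling [run_study()]: the model (a preset [model_spec()]
#' or an AIC selection), the percentile contrasts, the lag windows of the
#' cumulative curves, and which strata to analyse.
#'
#' @param spec a [model_spec()] used when \code{select = FALSE}.
#' @param select run [select_model()] on the all-cause counts first.
#' @param grid,strategy passed to [select_model()] when selecting.
#' @param p_cold,p_ref,p_hot percentiles of the analyzed temperature
#'   series defining the cold / reference / hot contrasts.
#' @param hot_window,cold_window cumulative lag windows of the hot and
#'   cold effects.
#' @param windows list of lag windows for the cumulative overall curves.
#' @param curve_refit refit the model per curve window with max lag equal
#'   to the window end (lag-basis df interacts with the maximum lag);
#'   FALSE re-summarises the single full-lag fit instead.
#' @param strata death-count columns to analyse beyond all-cause; NULL
#'   means every \code{deaths_*} column present.
#' @param min_total_deaths strata with fewer total deaths are skipped
#'   with a warning.
#' @param conf_level confidence level of all intervals.
#' @return An object of class \code{"study_config"}.
#' @export
study_config <- function(spec = hue2016(), select = FALSE,
                         grid = selection_grid(),
                         strategy = "sequential",
                         p_cold = 1, p_ref = 50, p_hot = 99,
                         hot_window = c(0, 2), cold_window = c(0, 28),
                         windows = list(c(0, 1), c(0, 2), c(0, 3), c(0, 4),
                                        c(0, 7), c(0, 14), c(0, 21),
                                        c(0, 28)),
                         curve_refit = TRUE, strata = NULL,
                         min_total_deaths = 50L, conf_level = 0.95) {
  structure(list(spec = spec, select = isTRUE(select), grid = grid,
                 strategy = strategy, p_cold = p_cold, p_ref = p_ref,
                 p_hot = p_hot, hot_window = hot_window,
                 cold_window = cold_window, windows = windows,
                 curve_refit = isTRUE(curve_refit), strata = strata,
                 min_total_deaths = min_total_deaths,
                 conf_level = conf_level),
            class = "study_config")
}

spec_as_list <- function(spec)
  spec[c("temperature", "max_lag", "var_df", "lag_df", "time_df_per_year",
         "humidity_df", "dewpoint_df", "dow")]

#' Run the full temperature-mortality study
#'
#' End-to-end orchestration on a compliant daily series: descriptive
#' summary, model choice on all-cause mortality (preset or AIC
#' selection), a re-fit of the chosen predictor structure for every
#' stratum outcome, percentile-contrast hot and cold effects per stratum,
#' cumulative overall curves across the configured lag windows, and
#' single-lag curves for the hot and cold contrasts — all with CIs, plus
#' a machine-readable manifest of every fit.  The chosen predictor
#' structure is held fixed across strata (never re-selected per stratum).
#'
#' @param data a [daily_series()] with weather and count columns.
#' @param config a [study_config()].
#' @return An object of class \code{"study_report"}: list with
#'   \code{summary}, \code{spec}, \code{selection} (NULL for a preset),
#'   \code{effects} (per-stratum hot/cold RR table), \code{curves}
#'   (named list of [overall_curve()]s), \code{lag_curves} (hot and cold
#'   [lag_structure()]s), \code{fits}, \code{manifest}.
#' @export
run_study <- function(data, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  data <- daily_series(data)
  summ <- describe_daily(data)
  selection <- NULL
  if (config$select) {
    selection <- select_model(data, config$grid, config$strategy,
                              outcome = "deaths_all", base = config$spec)
    spec <- selection$spec
  } else spec <- config$spec
  strata <- config$strata
  if (is.null(strata))
    strata <- grep("^deaths_", names(data), value = TRUE)
  strata <- union("deaths_all", strata)
  fits <- list()
  effects <- list()
  for (st in strata) {
    tot <- sum(data[[st]], na.rm = TRUE)
    if (tot < config$min_total_deaths) {
      warning("stratum '", st, "' skipped: only ", tot, " deaths")
      next
    }
    fit <- tryCatch(suppressWarnings(dlnm_nb(data, spec, outcome = st)),
                    error = function(e) {
                      warning("stratum '", st, "' failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    fits[[st]] <- fit
    ef <- percentile_effects(fit, config$p_cold, config$p_ref, config$p_hot,
                             config$hot_window, config$cold_window,
                             conf_level = config$conf_level)
    ef <- cbind(outcome = st, ef)
    effects[[st]] <- ef
  }
  if (!length(fits)) stop("no stratum could be fitted")
  effects <- do.call(rbind, c(effects, make.row.names = FALSE))
  all_fit <- fits[["deaths_all"]]
  curves <- list()
  for (w in config$windows) {
    key <- sprintf("lag%d-%d", w[1], w[2])
    cfit <- all_fit
    if (config$curve_refit && w[2] < spec$max_lag) {
      spec_w <- spec
      spec_w$max_lag <- as.integer(w[2])
      spec_w$lag_df <- min(spec$lag_df, w[2] + 1L)
      cfit <- tryCatch(suppressWarnings(dlnm_nb(data, spec_w, "deaths_all")),
                       error = function(e) all_fit)
    }
    curves[[key]] <- overall_curve(cfit, lag_window = pmin(w, spec$max_lag),
                                   conf_level = config$conf_level)
  }
  pct <- analyzed_percentiles(all_fit,
                              c(config$p_cold, config$p_ref, config$p_hot))
  lag_curves <- list(
    hot = lag_structure(all_fit, pct[3], pct[2], config$conf_level),
    cold = lag_structure(all_fit, pct[1], pct[2], config$conf_level))
  manifest <- list(
    spec = spec_as_list(spec),
    selected = config$select,
    n_days = nrow(data),
    fits = lapply(fits, function(f)
      list(outcome = f$outcome, aic = f$aic, n_used = f$n_used,
           theta = f$theta, converged = f$converged)),
    selection_trace_rows = if (is.null(selection)) 0L
                           else nrow(selection$trace))
  structure(list(summary = summ, spec = spec, selection = selection,
                 effects = effects, curves = curves,
                 lag_curves = lag_curves, fits = fits,
                 manifest = manifest, config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Temperature-mortality study report\n")
  cat("  days:", x$manifest$n_days, "  strata fitted:",
      length(x$fits), "\n")
  if (!is.null(x$selection))
    cat("  model chosen by", x$selection$strategy, "AIC selection\n")
  cat("\nPercentile-contrast effects:\n")
  print(x$effects[, c("outcome", "effect", "temp", "ref_temp", "lag_from",
                      "lag_to", "rr", "ci_low", "ci_high", "significant")],
        digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a study report to disk
#'
#' Persists the report as plain-text artifacts: \code{summary.csv},
#' \code{effects.csv}, \code{curves.csv} (long format across windows),
#' \code{lag_curves.csv}, \code{selection_trace.csv} (if selection ran)
#' and \code{manifest.json}.  Output is deterministic given the input.
#'
#' @param report a [run_study()] result.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wr(as.data.frame(report$summary), "summary.csv")
  wr(report$effects, "effects.csv")
  curves <- do.call(rbind, lapply(names(report$curves), function(k)
    cbind(window = k, as.data.frame(report$curves[[k]]))))
  wr(curves, "curves.csv")
  lagc <- do.call(rbind, lapply(names(report$lag_curves), function(k)
    cbind(contrast = k, as.data.frame(report$lag_curves[[k]]))))
  wr(lagc, "lag_curves.csv")
  if (!is.null(report$selection))
    wr(report$selection$trace, "selection_trace.csv")
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}

#' Read a simulation configuration from YAML
#'
#' Round-trips [sim_config()] through a YAML file; fields absent from the
#' file keep their defaults.
#'
#' @param path YAML file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown sim_config fields: ", paste(bad, collapse = ", "))
  if (!is.null(y$start_date)) y$start_date <- as.Date(y$start_date)
  do.call(sim_config, y)
}

#' Write a simulation configuration to YAML
#'
#' @param config a [sim_config()].
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  y <- unclass(config)
  y$start_date <- format(y$start_date)
  y <- y[!vapply(y, is.null, logical(1))]
  yaml::write_yaml(y, path)
  invisible(path)
}
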