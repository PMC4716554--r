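#' Daily weather-mortality series
#'
#' Validates and classes a data frame of aligned daily records: column
#' \code{date} (Date, contiguous once gaps are padded), weather columns
#' \code{tmax}, \code{tavg}, \code{tmin} (degrees C), \code{dewpoint}
#' (degrees C), \code{humidity} (%, in (0, 100]), and death-count columns
#' \code{deaths_all} plus optional stratified counts (\code{deaths_cvd},
#' \code{deaths_resp}, \code{deaths_cancer}, \code{deaths_nonext},
#' \code{deaths_male}, \code{deaths_female}, \code{deaths_0_64},
#' \code{deaths_65plus}).  Date gaps are padded with NA rows and recorded
#' in attribute \code{"gaps"}; a gap therefore breaks every lag window
#' that spans it rather than silently bridging misaligned days.
#'
#' @param df data frame with at least a \code{date} column.
#' @return The padded, date-sorted data frame with class
#'   \code{"daily_series"}.
#' @export
daily_series <- function(df) {
  if (!"date" %in% names(df)) stop("'date' column is required")
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable dates")
  if (anyDuplicated(df$date)) stop("duplicated dates")
  df <- df[order(df$date), , drop = FALSE]
  full <- seq(min(df$date), max(df$date), by = "day")
  gaps <- as.Date(setdiff(full, df$date), origin = "1970-01-01")
  if (length(gaps)) {
    pad <- df[rep(NA_integer_, length(gaps)), , drop = FALSE]
    pad$date <- gaps
    df <- rbind(df, pad)
    df <- df[order(df$date), , drop = FALSE]
  }
  rownames(df) <- NULL
  for (cc in grep("^deaths_", names(df), value = TRUE)) {
    v <- df[[cc]]
    if (any(v < 0 | v != round(v), na.rm = TRUE))
      stop("counts in '", cc, "' must be non-negative integers")
    df[[cc]] <- as.integer(v)
  }
  if ("humidity" %in% names(df) &&
      any(df$humidity <= 0 | df$humidity > 100, na.rm = TRUE))
    stop("humidity must lie in (0, 100]")
  if (all(c("tmin", "tavg", "tmax") %in% names(df))) {
    bad <- with(df, which(tmin > tavg | tavg > tmax))
    if (length(bad))
      warning(length(bad), " rows violate tmin <= tavg <= tmax")
  }
  structure(df, gaps = gaps, class = c("daily_series", "data.frame"))
}

#' Read a daily weather-mortality CSV
#'
#' Expects the [daily_series()] column layout with ISO-8601 dates.
#'
#' @param path CSV file path.
#' @return A [daily_series()].
#' @export
read_daily_csv <- function(path) {
  daily_series(utils::read.csv(path, stringsAsFactors = FALSE))
}

icd_norm <- function(code) toupper(substr(trimws(code), 1, 3))
icd_valid <- function(code3) grepl("^[A-Z][0-9]{2}$", code3)
icd_in <- function(code3, from, to) code3 >= from & code3 <= to

#' Aggregate line-listed deaths to daily counts
#'
#' Turns individual death records (date of death, sex, age, ICD-10 code)
#' into zero-filled daily counts: all-cause, non-external (A00-R99),
#' cardiovascular (I00-I99), respiratory (J00-J99), cancer (C00-D48),
#' sex, and age groups 0-64 / >= 65.  Code-range membership compares the
#' first three characters in alphanumeric order with both endpoints
#' inclusive.  Records with unparseable ICD codes are counted in
#' all-cause only, with a warning.
#'
#' @param records data frame with columns \code{date_of_death},
#'   \code{sex} ("male"/"female", or "m"/"f", case-insensitive),
#'   \code{age} (years), \code{icd10}.
#' @param date_range Date pair; days without deaths are zero-filled
#'   across this range (default the record range).
#' @return A [daily_series()] of count columns.
#' @export
aggregate_deaths <- function(records, date_range = NULL) {
  d <- as.Date(records$date_of_death)
  if (anyNA(d)) stop("unparseable date_of_death")
  if (is.null(date_range)) date_range <- range(d)
  days <- seq(as.Date(date_range[1]), as.Date(date_range[2]), by = "day")
  inside <- d >= days[1] & d <= days[length(days)]
  if (!all(inside)) stop("records outside 'date_range'")
  code <- icd_norm(records$icd10)
  ok <- icd_valid(code)
  if (!all(ok))
    warning(sum(!ok), " records with unparseable ICD-10 codes counted ",
            "in all-cause only")
  sex <- tolower(trimws(as.character(records$sex)))
  male <- sex %in% c("male", "m")
  female <- sex %in% c("female", "f")
  old <- records$age >= 65
  tab <- function(keep) {
    out <- integer(length(days))
    t <- table(factor(as.character(d[keep]), levels = as.character(days)))
    out + as.integer(t)
  }
  counts <- data.frame(
    date = days,
    deaths_all = tab(rep(TRUE, length(d))),
    deaths_nonext = tab(ok & icd_in(code, "A00", "R99")),
    deaths_cvd = tab(ok & icd_in(code, "I00", "I99")),
    deaths_resp = tab(ok & icd_in(code, "J00", "J99")),
    deaths_cancer = tab(ok & icd_in(code, "C00", "D48")),
    deaths_male = tab(male),
    deaths_female = tab(female),
    deaths_0_64 = tab(!old),
    deaths_65plus = tab(old))
  daily_series(counts)
}

#' Descriptive summary of a daily series
#'
#' Mean, SD, minimum, quartiles and maximum of every numeric column
#' (linear-interpolation quantiles), plus the pairwise correlation matrix
#' of the weather variables.
#'
#' @param data a [daily_series()].
#' @return Data frame of class \code{"daily_summary"} (one row per
#'   numeric column) with the weather correlation matrix in attribute
#'   \code{"correlations"}.
#' @export
describe_daily <- function(data) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  rows <- lapply(num, function(cc) {
    v <- data[[cc]][!is.na(data[[cc]])]
    q <- stats::quantile(v, c(.25, .5, .75), names = FALSE, type = 7)
    data.frame(variable = cc, mean = mean(v), sd = stats::sd(v),
               min = min(v), p25 = q[1], p50 = q[2], p75 = q[3],
               max = max(v))
  })
  out <- do.call(rbind, rows)
  wcols <- intersect(c("tmax", "tavg", "tmin", "dewpoint", "humidity"),
                     num)
  wcols <- wcols[vapply(wcols, function(cc)          # constants carry no
    stats::sd(data[[cc]], na.rm = TRUE) > 0, logical(1))]  # correlation
  cors <- if (length(wcols) > 1)
    stats::cor(data[wcols], use = "pairwise.complete.obs") else NULL
  structure(out, correlations = cors,
            class = c("daily_summary", "data.frame"))
}

#' @export
print.daily_summary <- function(x, digits = 3, ...) {
  cat("Daily series summary\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  if (!is.null(attr(x, "correlations"))) {
    cat("\nWeather correlations:\n")
    print(round(attr(x, "correlations"), 2))
  }
  invisible(x)
}
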