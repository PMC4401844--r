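#' Read and validate a daily mortality/temperature series
#'
#' Reads a CSV with one row per day and columns `date` (ISO-8601), `tmean`
#' (daily mean temperature, degrees C), `deaths_all` and optionally further
#' death streams (`deaths_cvd`, `deaths_resp`, `deaths_65plus`,
#' `deaths_under65`) and `deaths_flu` (influenza-coded deaths).
#'
#' @param path path to the CSV file, or a `data.frame` already in memory.
#' @return A validated `data.frame` with a `Date` column `date`, numeric
#'   `tmean` and integer-valued death columns, ordered by date.
#' @export
read_daily_series <- function(path) {
  daily <- if (is.data.frame(path)) path else read.csv(path, stringsAsFactors = FALSE)
  validate_daily_series(daily)
}

#' @rdname read_daily_series
#' @param daily a daily `data.frame` to validate in place.
#' @export
validate_daily_series <- function(daily) {
  req <- c("date", "tmean")
  miss <- setdiff(req, names(daily))
  if (length(miss)) stop("daily series lacks required columns: ", paste(miss, collapse = ", "))
  if (!inherits(daily$date, "Date")) daily$date <- as.Date(daily$date)
  if (anyNA(daily$date)) stop("unparseable dates in daily series")
  daily <- daily[order(daily$date), , drop = FALSE]
  gaps <- diff(as.integer(daily$date))
  if (any(gaps != 1L)) {
    bad <- daily$date[which(gaps != 1L)]
    stop("daily series has gaps or duplicate dates after: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (anyNA(daily$tmean)) {
    stop("missing daily temperature on: ",
         paste(utils::head(daily$date[is.na(daily$tmean)], 10), collapse = ", "),
         " (impute upstream; no silent imputation is done)")
  }
  dcols <- death_streams(daily, include_flu = TRUE)
  if (!length(setdiff(dcols, "deaths_flu")))
    stop("daily series needs at least one death-count column (e.g. deaths_all)")
  for (cc in dcols) {
    x <- daily[[cc]]
    if (anyNA(x) || any(x < 0)) stop("negative or missing counts in ", cc)
  }
  if ("deaths_flu" %in% names(daily) && "deaths_all" %in% names(daily) &&
      any(daily$deaths_flu > daily$deaths_all))
    stop("deaths_flu exceeds deaths_all on some days")
  rownames(daily) <- NULL
  daily
}

death_streams <- function(df, include_flu = FALSE) {
  out <- grep("^deaths_", names(df), value = TRUE)
  if (!include_flu) out <- setdiff(out, "deaths_flu")
  out
}

#' Daily degree-day exposures about a common threshold
#'
#' Splits daily mean temperature into cold-degrees (degrees below the
#' threshold) and heat-degrees (degrees above it), the V-shaped exposure
#' summary with apex at the minimum-mortality temperature.
#'
#' @param tmean numeric vector of daily mean temperatures (degrees C).
#' @param threshold common cold/heat threshold in degrees C (default 18).
#' @return `data.frame` with columns `cold` and `heat`; for every day
#'   `cold + heat == abs(tmean - threshold)` and `min(cold, heat) == 0`.
#' @export
degree_exposures <- function(tmean, threshold = 18) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (anyNA(tmean) || any(!is.finite(tmean)))
    stop("non-finite daily temperatures at positions: ",
         paste(utils::head(which(!is.finite(tmean)), 10), collapse = ", "))
  data.frame(cold = pmax(0, threshold - tmean), heat = pmax(0, tmean - threshold))
}

#' Build the sequential weekly series
#'
#' Collapses a daily series into consecutive 7-day weeks numbered from a
#' start date, assigns autumn-anchored analysis years (a new year begins at
#' the first week starting on or after 1 October), numbers weeks within each
#' year (1..53), and attaches weekly degree-day exposures including the
#' 14-day (this week + previous week) lagged cold measure used by the
#' week-level model.
#'
#' @param daily validated daily series (see [read_daily_series()]).
#' @param start_date first day of week 1; defaults to the first date in
#'   `daily`. Days before it are ignored; a trailing partial week is
#'   discarded with a warning.
#' @param threshold degree-day threshold in degrees C.
#' @return `data.frame` with one row per week: `week_index`, `start_date`,
#'   `year_label` (calendar year in which the analysis year starts),
#'   `week_in_year`, `stratum` (`"YYYY-MM"` of the week's start date), the
#'   summed death streams, `week_cold`, `week_heat`, `week_cold_lagged`
#'   (`NA` for week 1).
#' @export
build_weekly_series <- function(daily, start_date = NULL, threshold = 18) {
  daily <- validate_daily_series(daily)
  if (is.null(start_date)) start_date <- daily$date[1]
  start_date <- as.Date(start_date)
  if (start_date < daily$date[1])
    stop("daily series begins after the requested start date")
  daily <- daily[daily$date >= start_date, , drop = FALSE]
  n <- nrow(daily)
  if (n < 7L) stop("daily series shorter than one week from the start date")
  n_weeks <- n %/% 7L
  dropped <- n - 7L * n_weeks
  if (dropped > 0L)
    warning(sprintf("discarding trailing partial week of %d day(s)", dropped))
  keep <- daily[seq_len(7L * n_weeks), , drop = FALSE]
  wk <- rep(seq_len(n_weeks), each = 7L)

  expo <- degree_exposures(keep$tmean, threshold)
  sum_by_week <- function(x) as.vector(rowsum(x, wk))
  weeks <- data.frame(
    week_index = seq_len(n_weeks),
    start_date = keep$date[seq(1L, by = 7L, length.out = n_weeks)]
  )
  for (cc in death_streams(keep, include_flu = TRUE))
    weeks[[cc]] <- sum_by_week(keep[[cc]])
  weeks$week_cold <- sum_by_week(expo$cold) / 7
  weeks$week_heat <- sum_by_week(expo$heat) / 7
  # lagged cold: mean over the 14 days of this week and the previous one
  weeks$week_cold_lagged <- c(NA_real_, (weeks$week_cold[-n_weeks] + weeks$week_cold[-1]) / 2)

  yr <- assign_years(weeks$start_date)
  weeks$year_label <- yr$year_label
  weeks$week_in_year <- yr$week_in_year
  m <- as.POSIXlt(weeks$start_date)
  weeks$stratum <- sprintf("%04d-%02d", m$year + 1900L, m$mon + 1L)
  attr(weeks, "threshold") <- threshold
  weeks
}

#' Assign autumn-anchored analysis years to sequential week start dates
#'
#' A new analysis year begins at the first week whose start date falls on or
#' after 1 October; with consecutive 7-day weeks exactly one week per
#' calendar year starts during 1-7 October. Years are labelled by the
#' calendar year in which they start, and contain 52 or 53 weeks.
#'
#' @param start_dates `Date` vector of consecutive week start dates.
#' @return `data.frame` with `year_label` and `week_in_year`.
#' @export
assign_years <- function(start_dates) {
  start_dates <- as.Date(start_dates)
  lt <- as.POSIXlt(start_dates)
  cal_year <- lt$year + 1900L
  boundary <- lt$mon == 9L & lt$mday <= 7L  # week starting 1-7 October
  # label years by counting October boundaries; weeks before the first
  # boundary form a stub year starting the previous autumn
  idx <- cumsum(boundary)
  first_year <- if (any(boundary)) cal_year[which(boundary)[1]] else cal_year[1] - 1L
  year_label <- first_year + (idx - 1L)
  week_in_year <- stats::ave(idx, idx, FUN = seq_along)
  data.frame(year_label = year_label, week_in_year = as.integer(week_in_year))
}

#' Step-change indicator matrix
#'
#' One column per declared discontinuity (administrative boundary or
#' cause-coding change); column `j` is 0 for analysis years before the step
#' year and 1 from the step year onward.
#'
#' @param year_labels integer vector of analysis-year labels (one per year).
#' @param step_years integer vector of years at which steps take effect.
#' @return numeric matrix with `length(step_years)` columns named
#'   `step_<year>`; zero columns if `step_years` is empty.
#' @export
step_indicators <- function(year_labels, step_years) {
  step_years <- as.integer(step_years)
  if (anyDuplicated(step_years)) stop("duplicate step years")
  if (length(step_years) && (any(step_years <= min(year_labels) |
                                   step_years > max(year_labels)))) {
    off <- step_years[step_years <= min(year_labels) | step_years > max(year_labels)]
    if (any(step_years > max(year_labels)))
      stop("step year(s) outside series range: ", paste(off, collapse = ", "))
    warning("step at or before first year is collinear with the intercept: ",
            paste(off, collapse = ", "))
  }
  m <- vapply(step_years, function(sy) as.numeric(year_labels >= sy),
              numeric(length(year_labels)))
  m <- matrix(m, nrow = length(year_labels),
              dimnames = list(NULL, if (length(step_years)) paste0("step_", step_years)))
  m
}

#' Aggregate the weekly series into 52-week annual records
#'
#' Drops every week numbered 53 within its analysis year, excludes truncated
#' years with fewer than 52 weeks (with a warning), and returns one row per
#' retained year: summed deaths per stream over the 52 retained weeks,
#' annual cold/heat (mean of the daily degree-day exposures over the 364
#' retained days, computed exactly as the mean of the 52 retained weekly
#' means), the influenza proportion (influenza-coded / all deaths over the
#' same retained days, when `deaths_flu` and `deaths_all` are present), and
#' step indicator columns.
#'
#' @param weeks weekly series from [build_weekly_series()].
#' @param steps integer vector of step years (default none).
#' @return `data.frame` with `year_index`, `year_label`, death streams,
#'   `annual_cold`, `annual_heat`, `flu_prop` (if computable) and `step_*`
#'   columns.
#' @export
aggregate_annual <- function(weeks, steps = integer()) {
  complete <- table(weeks$year_label)
  bad <- as.integer(names(complete)[complete < 52L])
  if (length(bad))
    warning("excluding truncated year(s) with <52 weeks: ", paste(bad, collapse = ", "))
  keep <- weeks$year_label %in% setdiff(unique(weeks$year_label), bad) &
    weeks$week_in_year <= 52L
  w <- weeks[keep, , drop = FALSE]
  labs <- sort(unique(w$year_label))
  g <- match(w$year_label, labs)
  annual <- data.frame(year_index = seq_along(labs), year_label = labs)
  for (cc in death_streams(w, include_flu = TRUE))
    annual[[cc]] <- as.vector(rowsum(w[[cc]], g))
  annual$annual_cold <- as.vector(rowsum(w$week_cold, g)) / 52
  annual$annual_heat <- as.vector(rowsum(w$week_heat, g)) / 52
  if (all(c("deaths_flu", "deaths_all") %in% names(annual)))
    annual$flu_prop <- annual$deaths_flu / annual$deaths_all
  si <- step_indicators(annual$year_label, steps)
  if (ncol(si)) annual <- cbind(annual, si)
  attr(annual, "threshold") <- attr(weeks, "threshold")
  annual
}

#' Build the annual analysis table straight from a daily series
#'
#' Convenience wrapper: [build_weekly_series()] then [aggregate_annual()].
#'
#' @inheritParams build_weekly_series
#' @inheritParams aggregate_annual
#' @export
build_annual_series <- function(daily, start_date = NULL, threshold = 18,
                                steps = integer()) {
  aggregate_annual(build_weekly_series(daily, start_date, threshold), steps = steps)
}
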