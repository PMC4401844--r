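#' Build the weekly comparator design
#'
#' Response and exposures for the conventional week-level analysis:
#' exposures are the 14-day lagged cold (`week_cold_lagged`, the mean of
#' daily cold-degrees over the week and the previous one, reflecting the
#' known cold-mortality lag) and unlagged `week_heat` (heat effects act
#' within days); strata are the calendar year x month of the week's start
#' date.  The first week (undefined lag) is dropped, as are weeks numbered
#' 53 in their analysis year, so the weekly and annual analyses cover
#' identical days.
#'
#' @param weeks weekly series from [build_weekly_series()].
#' @param stream death-count column to model.
#' @return list with `y`, `X` (columns `cold`, `heat`) and `strata`.
#' @export
build_weekly_design <- function(weeks, stream = "deaths_all") {
  if (!stream %in% names(weeks)) stop("no column ", stream, " in weekly table")
  keep <- !is.na(weeks$week_cold_lagged) & weeks$week_in_year <= 52L
  w <- weeks[keep, , drop = FALSE]
  list(y = w[[stream]],
       X = cbind(cold = w$week_cold_lagged, heat = w$week_heat),
       strata = w$stratum)
}

#' Fit the weekly conditional quasi-Poisson comparator model
#'
#' The conventional short-time-scale analysis against which the annual
#' design is compared: weekly death counts regressed on lagged cold and
#' heat, with all confounding that is constant within a calendar
#' year x month absorbed by stratification
#' ([fit_conditional_poisson()]; equivalent to a time-stratified
#' case-crossover).  Unlike the annual design, this estimator captures the
#' full acute effect, including deaths displaced by only weeks or months.
#'
#' @inheritParams build_weekly_design
#' @param family `"quasipoisson"` (default) or `"poisson"`.
#' @return object of class `c("tm_weekly", "tm_fit")`.
#' @export
fit_weekly <- function(weeks, stream = "deaths_all", family = "quasipoisson") {
  d <- build_weekly_design(weeks, stream)
  fit <- fit_conditional_poisson(d$y, d$X, d$strata, family = family)
  fit$stream <- stream
  fit$threshold <- attr(weeks, "threshold")
  fit$call <- match.call()
  class(fit) <- c("tm_weekly", "tm_fit")
  fit
}
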