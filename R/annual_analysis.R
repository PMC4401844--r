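#' Assemble the annual design matrix and response
#'
#' Columns: intercept, annual cold, annual heat, natural-spline trend basis
#' of the year index (`spline_df` columns), influenza proportion (optional),
#' and any step indicator columns present in `annual` (or the subset named
#' in `steps`).
#'
#' @param annual annual table from [build_annual_series()] /
#'   [aggregate_annual()].
#' @param stream name of the death-count column to model (default
#'   `"deaths_all"`).
#' @param spline_df trend degrees of freedom (default 5: one per ten years
#'   of a 57-year series).
#' @param include_flu adjust for the annual influenza proportion?
#' @param steps step-indicator columns to include: `NULL` (all `step_*`
#'   columns present) or a character/integer vector of step years.
#' @return list with `y` (response counts) and `X` (named design matrix);
#'   rank deficiency is an error naming the collinear columns.
#' @export
build_annual_design <- function(annual, stream = "deaths_all", spline_df = 5,
                                include_flu = TRUE, steps = NULL) {
  if (!stream %in% names(annual)) stop("no column ", stream, " in annual table")
  step_cols <- grep("^step_", names(annual), value = TRUE)
  if (!is.null(steps)) {
    want <- if (is.numeric(steps)) paste0("step_", steps) else steps
    missing_steps <- setdiff(want, step_cols)
    if (length(missing_steps))
      stop("step column(s) not present in annual table: ",
           paste(missing_steps, collapse = ", "))
    step_cols <- want
  }
  T <- nrow(annual)
  n_terms <- 3L + spline_df + include_flu + length(step_cols)
  if (T < n_terms + 3L)
    stop("too few years (", T, ") for ", n_terms, " model terms")
  X <- cbind("(Intercept)" = 1, cold = annual$annual_cold, heat = annual$annual_heat,
             trend_basis(annual$year_index, spline_df))
  if (include_flu) {
    if (is.null(annual$flu_prop))
      stop("include_flu = TRUE but annual table has no flu_prop column")
    X <- cbind(X, flu = annual$flu_prop)
  }
  if (length(step_cols)) X <- cbind(X, as.matrix(annual[step_cols]))
  check_full_rank(X)
  list(y = annual[[stream]], X = X)
}

#' Fit the annual temperature-mortality model
#'
#' The primary analysis: a quasi-Poisson regression of annual deaths (over
#' 52-week autumn-anchored years) on annual cold and annual heat, adjusted
#' for secular trend (natural cubic spline of year index), the annual
#' influenza proportion, and declared step changes.  Because the years are
#' anchored in early October, deaths displaced by less than roughly a year
#' cancel within a year, so the cold/heat coefficients estimate only the
#' mortality excess *not* recovered by short-term displacement.
#'
#' @inheritParams build_annual_design
#' @param family model family passed to [fit_count_model()].
#' @return object of class `c("tm_annual", "tm_fit")`; the percent-increase
#'   table for cold and heat is in `$percent`.
#' @export
fit_annual <- function(annual, stream = "deaths_all", spline_df = 5,
                       family = "quasipoisson", include_flu = TRUE, steps = NULL) {
  d <- build_annual_design(annual, stream, spline_df, include_flu, steps)
  fit <- fit_count_model(d$y, d$X, family = family)
  fit$annual <- annual
  fit$stream <- stream
  fit$spline_df <- spline_df
  fit$include_flu <- include_flu
  fit$threshold <- attr(annual, "threshold")
  fit$call <- match.call()
  class(fit) <- c("tm_annual", "tm_fit")
  fit
}

default_sensitivity_variants <- function(year_labels = integer()) {
  v <- list(
    list(label = "main", family = "quasipoisson"),
    list(label = "simple regression", family = "simple"),
    list(label = "negative binomial", family = "negbin"),
    list(label = "3-knot spline (df=2)", spline_df = 2),
    list(label = "9-knot spline (df=8)", spline_df = 8),
    list(label = "threshold 15C", threshold = 15),
    list(label = "threshold 21C", threshold = 21),
    list(label = "no influenza adjustment", include_flu = FALSE)
  )
  extra <- list(c(1957, 1958), 1964, c(1975, 1976))
  for (ys in extra) {
    if (all(ys %in% year_labels))
      v <- c(v, list(list(label = paste("extra step", paste(ys, collapse = "+")),
                          extra_steps = ys)))
  }
  v
}

#' Sensitivity grid over model variants
#'
#' Refits the annual model over a grid of variants: distributional family
#' (quasi-Poisson, simple log-count regression, negative binomial), trend
#' flexibility (spline df), temperature threshold (which requires the daily
#' series, because the degree-day exposures must be rebuilt), additional
#' step indicators, and influenza control.
#'
#' @param daily daily series (data frame or CSV path).
#' @param start_date,threshold,steps as in [build_annual_series()];
#'   `threshold` is the main-model threshold, variants may override it.
#' @param stream death stream to model.
#' @param spline_df,family,include_flu main-model settings.
#' @param variants list of variant descriptions; each a list with a `label`
#'   and any of `family`, `spline_df`, `threshold`, `include_flu`,
#'   `extra_steps` overriding the main model.  The default grid covers the
#'   standard set (and includes the main model first).
#' @return `data.frame` of class `"tm_sensitivity"`: one row per variant
#'   with cold/heat percent increases, 95% CIs and AIC.
#' @export
sensitivity_grid <- function(daily, start_date = NULL, threshold = 18,
                             steps = c(1965, 1966), stream = "deaths_all",
                             spline_df = 5, family = "quasipoisson",
                             include_flu = TRUE, variants = NULL) {
  daily <- read_daily_series(daily)
  annual_cache <- list()
  get_annual <- function(thr, st) {
    key <- paste(thr, paste(st, collapse = ","))
    if (is.null(annual_cache[[key]]))
      annual_cache[[key]] <<- build_annual_series(daily, start_date, thr, st)
    annual_cache[[key]]
  }
  base_annual <- get_annual(threshold, steps)
  if (is.null(variants)) variants <- default_sensitivity_variants(base_annual$year_label)

  rows <- lapply(variants, function(v) {
    thr <- v$threshold %||% threshold
    st <- sort(unique(c(steps, v$extra_steps)))
    ann <- get_annual(thr, st)
    fit <- tryCatch(
      fit_annual(ann, stream = stream,
                 spline_df = v$spline_df %||% spline_df,
                 family = v$family %||% family,
                 include_flu = v$include_flu %||% include_flu),
      error = function(e) {
        warning("variant '", v$label, "' skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(fit)) return(NULL)
    pc <- fit$percent
    gp <- function(term, col) if (term %in% pc$term) pc[pc$term == term, col] else NA_real_
    data.frame(label = v$label,
               cold_pct = gp("cold", "pct"), cold_lo = gp("cold", "pct_lo"),
               cold_hi = gp("cold", "pct_hi"),
               heat_pct = gp("heat", "pct"), heat_lo = gp("heat", "pct_lo"),
               heat_hi = gp("heat", "pct_hi"),
               aic = model_aic(fit))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tm_sensitivity", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tm_sensitivity <- function(x, digits = 2, ...) {
  cat("Sensitivity grid: percent increase in annual deaths per degree C\n\n")
  fmt <- function(p, lo, hi) sprintf("%5.1f (%5.1f to %5.1f)", p, lo, hi)
  tab <- data.frame(variant = x$label,
                    cold = fmt(x$cold_pct, x$cold_lo, x$cold_hi),
                    heat = fmt(x$heat_pct, x$heat_lo, x$heat_hi),
                    AIC = ifelse(is.na(x$aic), "NA", sprintf("%.1f", x$aic)))
  print(tab, right = FALSE, row.names = FALSE)
  invisible(x)
}
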