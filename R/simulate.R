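#' Simulation configurations
#'
#' `temp_sim_config()` describes a London-like daily temperature process:
#' seasonal cosine plus stationary AR(1) noise.  Defaults are calibrated so
#' that a 57-year series has mean annual cold-degrees (18 C threshold)
#' around 7.4 C (range roughly 6.2-9.0) and mean annual heat-degrees around
#' 0.2 C (range 0-0.6), matching a temperate maritime climate.
#'
#' `harvest_config()` is the ground truth of the mortality-displacement
#' mechanism: acute log-linear effects per degree C (`beta_cold` acting
#' through the trailing `lag_cold`-day mean of cold-degrees, `beta_heat`
#' through the trailing `lag_heat`-day mean of heat), the displaced fraction
#' `f` of attributable deaths, and the displacement horizon `D`: each
#' displaced death is removed from baseline mortality at a lag uniform on
#' `1..D` days.  `f = 0` means no harvesting; `f = 1` means every
#' attributable death would have occurred within `D` days anyway.
#'
#' `mort_sim_config()` assembles the mortality process: baseline daily
#' deaths `b0`, a smooth secular trend on the log scale (a function of years
#' since series start), multiplicative step changes taking effect at the
#' October analysis-year boundary, winter-peaked influenza epidemics with
#' random per-season intensity, and the harvesting mechanism.
#'
#' @param start first day of the series (ideally a 1-7 October date so week
#'   1 opens an analysis year).
#' @param n_years number of complete autumn-anchored analysis years.
#' @param a0 mean temperature level (degrees C).
#' @param a1 seasonal amplitude (degrees C).
#' @param phase day of year of the seasonal maximum.
#' @param rho AR(1) coefficient of the daily anomaly (|rho| < 1).
#' @param sd innovation standard deviation (degrees C).
#' @return a config list of the matching class.
#' @export
temp_sim_config <- function(start = "1949-10-02", n_years = 57,
                            a0 = 11, a1 = 7, phase = 197, rho = 0.8, sd = 2.2) {
  stopifnot(abs(rho) < 1, sd >= 0, n_years >= 1)
  structure(list(start = as.Date(start), n_years = n_years, a0 = a0, a1 = a1,
                 phase = phase, rho = rho, sd = sd),
            class = "temp_sim_config")
}

#' @rdname temp_sim_config
#' @param beta_cold,beta_heat acute log-rate effects per degree C.
#' @param lag_cold,lag_heat lag-window lengths in days (trailing means).
#' @param f displaced fraction in `[0, 1]`.
#' @param D displacement horizon in days (`>= 1`).
#' @export
harvest_config <- function(beta_cold = 0.017, beta_heat = 0.013,
                           lag_cold = 14, lag_heat = 3, f = 0, D = 60) {
  stopifnot(f >= 0, f <= 1, D >= 1, lag_cold >= 1, lag_heat >= 1)
  structure(list(beta_cold = beta_cold, beta_heat = beta_heat,
                 lag_cold = as.integer(lag_cold), lag_heat = as.integer(lag_heat),
                 f = f, D = as.integer(D)),
            class = "harvest_config")
}

default_trend <- function(u) -0.25 * stats::plogis((u - 25) / 6)

#' @rdname temp_sim_config
#' @param b0 baseline expected daily deaths (`b0 = 170` gives roughly 62000
#'   deaths/year, a large-city scale).
#' @param trend function of years-since-start returning the log-scale
#'   secular trend (default: a smooth logistic decline of about 22% over
#'   the second half of a 57-year series); `NULL` for none.
#' @param steps `data.frame(year, factor)` of multiplicative step changes
#'   applied from the October boundary of each `year`; `NULL` for none.
#' @param flu `NULL` for no influenza, or a list with `rate_mean` (mean
#'   peak log-rate increment per season), `shape` (gamma shape of season
#'   intensities), `peak_doy` (day of year of the epidemic peak) and
#'   `peak_sd` (bump width in days).
#' @param harvest a [harvest_config()].
#' @param threshold degree-day threshold used by the data-generating
#'   mechanism (degrees C).
#' @param expectation if `TRUE`, return the exact expected deaths rather
#'   than Poisson draws (noise-free series for exact recovery checks).
#' @export
mort_sim_config <- function(b0 = 170, trend = default_trend, steps = NULL,
                            flu = list(rate_mean = 0.04, shape = 0.7,
                                       peak_doy = 10, peak_sd = 21),
                            harvest = harvest_config(), threshold = 18,
                            expectation = FALSE) {
  stopifnot(b0 > 0, inherits(harvest, "harvest_config"))
  if (!is.null(steps)) stopifnot(all(c("year", "factor") %in% names(steps)),
                                 all(steps$factor > 0))
  structure(list(b0 = b0, trend = trend, steps = steps, flu = flu,
                 harvest = harvest, threshold = threshold,
                 expectation = expectation),
            class = "mort_sim_config")
}

# dates covering exactly n_years complete analysis years of 7-day weeks
sim_dates <- function(start, n_years) {
  start <- as.Date(start)
  ws <- start + 7 * (0:((n_years + 2) * 53))
  lt <- as.POSIXlt(ws)
  boundary <- which(lt$mon == 9L & lt$mday <= 7L)
  last_week <- boundary[n_years + 1L] - 1L   # week before the (n+1)-th October
  seq(start, by = 1, length.out = 7L * last_week)
}

#' Simulate a daily temperature series
#'
#' `T_d = a0 + a1 cos(2 pi (doy_d - phase) / 365.25) + e_d` with `e_d` a
#' stationary AR(1) anomaly.
#'
#' @param config a [temp_sim_config()].
#' @param dates optional `Date` vector; defaults to the dates covering
#'   `config$n_years` complete analysis years from `config$start`.
#' @return `data.frame` with `date` and `tmean`.
#' @export
simulate_temperature <- function(config = temp_sim_config(), dates = NULL) {
  if (is.null(dates)) dates <- sim_dates(config$start, config$n_years)
  n <- length(dates)
  doy <- as.POSIXlt(dates)$yday + 1
  seasonal <- config$a0 + config$a1 * cos(2 * pi * (doy - config$phase) / 365.25)
  e0 <- rnorm(1, 0, config$sd / sqrt(1 - config$rho^2))
  e <- as.numeric(stats::filter(rnorm(n, 0, config$sd), config$rho,
                                method = "recursive", init = e0))
  data.frame(date = dates, tmean = seasonal + e)
}

trailing_mean <- function(x, L) {
  cs <- c(0, cumsum(x))
  d <- seq_along(x)
  lo <- pmax(d - L, 0)
  (cs[d + 1] - cs[lo + 1]) / (d - lo)
}

#' Simulate daily deaths with acute temperature effects and displacement
#'
#' The expected death rate is built in four stages.  Baseline:
#' `m_d = b0 * exp(trend_d + step_d)`.  Attributable excess:
#' `a_d = m_d * (exp(beta_cold * cbar_d + beta_heat * hbar_d + flu_d) - 1)`,
#' where `cbar`/`hbar` are trailing lag-window means of the daily degree
#' exposures and `flu_d` the epidemic log-rate increment.  Displacement: a
#' fraction `f` of each day's excess is subtracted from baseline mortality
#' at lags uniform on `1..D` days (`r_d`), floored so the depleted rate
#' never drops below `0.1 * m_d`, with any shortfall carried to the next
#' day so displaced deaths are conserved.  Finally
#' `lambda_d = m_d + a_d - r_d`, and deaths are Poisson draws (or exactly
#' `lambda_d` in expectation mode).  Influenza-coded deaths are drawn
#' binomially from total deaths with the flu-attributable share of
#' `lambda_d` as probability, so `deaths_flu <= deaths_all` always.
#'
#' Displacement scheduled beyond the end of the series (tail leakage) is
#' recorded in the ground-truth attributes; the exact conservation identity
#' `sum(r) + tail_leakage + carry_end = f * sum(a)` always holds.
#'
#' @param temps `data.frame(date, tmean)` from [simulate_temperature()].
#' @param config a [mort_sim_config()].
#' @return `data.frame` with `date`, `tmean`, `deaths_all`, `deaths_flu`,
#'   and attribute `"truth"`: the ground-truth parameters and the realised
#'   excess/displacement totals.
#' @export
simulate_mortality <- function(temps, config = mort_sim_config()) {
  h <- config$harvest
  n <- nrow(temps)
  if (n <= h$D) stop("series shorter than the displacement horizon D")
  u <- (seq_len(n) - 1) / 365.25
  log_m <- if (is.null(config$trend)) rep(0, n) else config$trend(u)

  if (!is.null(config$steps)) {
    ws <- temps$date[seq(1L, n, by = 7L)]
    lt <- as.POSIXlt(ws)
    for (k in seq_len(nrow(config$steps))) {
      yk <- config$steps$year[k]
      bnd <- ws[lt$year + 1900L == yk & lt$mon == 9L & lt$mday <= 7L]
      if (length(bnd))
        log_m <- log_m + log(config$steps$factor[k]) * (temps$date >= bnd[1])
    }
  }
  m <- config$b0 * exp(log_m)

  expo <- degree_exposures(temps$tmean, config$threshold)
  cbar <- trailing_mean(expo$cold, h$lag_cold)
  hbar <- trailing_mean(expo$heat, h$lag_heat)

  flu <- rep(0, n)
  if (!is.null(config$flu)) {
    lt <- as.POSIXlt(temps$date)
    years <- unique(lt$year + 1900L)
    intensity <- rgamma(length(years), shape = config$flu$shape,
                        scale = config$flu$rate_mean / config$flu$shape)
    for (j in seq_along(years)) {
      peak <- as.Date(sprintf("%d-01-01", years[j])) + (config$flu$peak_doy - 1)
      dd <- as.numeric(temps$date - peak)
      flu <- flu + intensity[j] * exp(-0.5 * (dd / config$flu$peak_sd)^2)
    }
  }

  a <- m * (exp(h$beta_cold * cbar + h$beta_heat * hbar + flu) - 1)

  # displaced load: uniform kernel over the previous D days
  acs <- c(0, cumsum(a))
  d <- seq_len(n)
  r_raw <- (h$f / h$D) * (acs[pmax(d - 1, 0) + 1] - acs[pmax(d - 1 - h$D, 0) + 1])
  cap <- 0.9 * m
  if (any(r_raw > cap)) {
    r <- numeric(n); carry <- 0
    for (i in d) {
      tot <- r_raw[i] + carry
      r[i] <- min(tot, cap[i])
      carry <- tot - r[i]
    }
  } else {
    r <- r_raw; carry <- 0
  }
  leak <- (h$f / h$D) * sum(a * pmax(0, h$D - (n - d)))

  lambda <- m + a - r
  deaths <- if (config$expectation) lambda else rpois(n, lambda)
  flu_excess <- m * (exp(flu) - 1)
  q <- pmin(pmax(flu_excess / lambda, 0), 1)
  deaths_flu <- if (config$expectation) q * deaths else rbinom(n, deaths, q)

  out <- data.frame(date = temps$date, tmean = temps$tmean,
                    deaths_all = deaths, deaths_flu = deaths_flu)
  attr(out, "truth") <- list(
    beta_cold = h$beta_cold, beta_heat = h$beta_heat,
    acute_pct_cold = 100 * (exp(h$beta_cold) - 1),
    acute_pct_heat = 100 * (exp(h$beta_heat) - 1),
    lag_cold = h$lag_cold, lag_heat = h$lag_heat,
    f = h$f, D = h$D, b0 = config$b0, threshold = config$threshold,
    steps = config$steps,
    sum_baseline = sum(m), sum_attributable = sum(a),
    displaced_scheduled = h$f * sum(a), displaced_realised = sum(r),
    tail_leakage = leak, carry_end = carry,
    net_excess = sum(a) - sum(r))
  out
}

#' Generate a complete synthetic dataset (daily CSV + ground-truth JSON)
#'
#' Seeds the RNG, simulates temperature then mortality, and optionally
#' writes the daily series as CSV and the ground truth as JSON.  A fixed
#' seed yields byte-identical output.
#'
#' @param temp_config a [temp_sim_config()].
#' @param mort_config a [mort_sim_config()].
#' @param seed integer RNG seed (`NULL` to use the current RNG state).
#' @param out optional path for the daily CSV.
#' @param truth_out optional path for the ground-truth JSON.
#' @return list with `daily` (the series) and `truth`.
#' @export
generate_dataset <- function(temp_config = temp_sim_config(),
                             mort_config = mort_sim_config(),
                             seed = NULL, out = NULL, truth_out = NULL) {
  if (!is.null(seed)) set.seed(seed)
  temps <- simulate_temperature(temp_config)
  daily <- simulate_mortality(temps, mort_config)
  truth <- attr(daily, "truth")
  truth$seed <- seed
  if (!is.null(out)) {
    wd <- daily
    wd$date <- format(wd$date)
    write.csv(wd, out, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(truth_out)) {
    tr <- truth
    tr$steps <- if (is.null(tr$steps)) NULL else as.list(tr$steps)
    jsonlite::write_json(tr, truth_out, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  list(daily = daily, truth = truth)
}
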