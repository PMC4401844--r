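make_annual <- function(T = 57, steps = c(1965, 1966)) {
  set.seed(99)
  a <- data.frame(year_index = seq_len(T), year_label = 1949L + seq_len(T) - 1L,
                  deaths_all = rpois(T, 60000),
                  annual_cold = rnorm(T, 7.4, 0.6),
                  annual_heat = pmax(0, rnorm(T, 0.2, 0.1)),
                  flu_prop = runif(T, 0, 0.02))
  cbind(a, step_indicators(a$year_label, steps))
}

test_that("main design has intercept + exposures + spline + flu + steps", {
  a <- make_annual()
  d <- build_annual_design(a)
  expect_equal(ncol(d$X), 11L)  # 1 + 2 + 5 + 1 + 2
  expect_equal(colnames(d$X)[1:3], c("(Intercept)", "cold", "heat"))
  d2 <- build_annual_design(a, include_flu = FALSE)
  expect_equal(ncol(d2$X), 10L)
  expect_error(build_annual_design(a, steps = 1900), "not present")
  a$flu_prop <- 0.01                      # constant: collinear with intercept
  expect_error(build_annual_design(a), "collinear")
})

test_that("threshold variants change exposures but not the calendar", {
  n_days <- length(coldharvest:::sim_dates("1949-10-02", 4))
  set.seed(4)
  d <- make_daily(n_days, tmean = rnorm(n_days, 11, 5),
                  deaths = rpois(n_days, 10))
  a18 <- build_annual_series(d, threshold = 18)
  a15 <- build_annual_series(d, threshold = 15)
  expect_equal(a15$year_label, a18$year_label)
  expect_equal(a15$deaths_all, a18$deaths_all)
  expect_false(isTRUE(all.equal(a15$annual_cold, a18$annual_cold)))
})

test_that("annual model recovers a known effect in expectation mode", {
  d <- sim_expectation(beta_cold = 0.02, f = 0, seed = 1)
  fit <- fit_annual(build_annual_series(d), include_flu = FALSE)
  truth <- 100 * (exp(0.02) - 1)
  expect_lt(abs(pct_of(fit, "cold") - truth) / truth, 0.15)
})

test_that("cold percent CI covers zero under a null temperature effect", {
  set.seed(17)
  covered <- vapply(1:100, function(i) {
    temps <- simulate_temperature(temp_sim_config())
    d <- simulate_mortality(temps, mort_sim_config(
      trend = NULL, flu = NULL,
      harvest = harvest_config(beta_cold = 0, beta_heat = 0, f = 0)))
    fit <- fit_annual(build_annual_series(d), include_flu = FALSE)
    pct_of(fit, "cold", "pct_lo") <= 0 && 0 <= pct_of(fit, "cold", "pct_hi")
  }, logical(1))
  expect_gte(mean(covered), 0.89)   # ~95% less 3 Monte-Carlo SDs at n=100
})

test_that("the 5-df spline model beats 2 df by AIC when the trend is smooth", {
  set.seed(23)
  temps <- simulate_temperature(temp_sim_config())
  wins <- vapply(1:10, function(i) {
    d <- simulate_mortality(temps, mort_sim_config(
      flu = NULL, harvest = harvest_config(beta_cold = 0.017, f = 0)))
    a <- build_annual_series(d)
    model_aic(fit_annual(a, spline_df = 5, include_flu = FALSE)) <
      model_aic(fit_annual(a, spline_df = 2, include_flu = FALSE))
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("an under-flexible spline distorts the cold estimate under trend confounding", {
  # warming temperatures (declining cold) plus declining mortality: a 2-df
  # spline under-controls the shared downward trend, which masquerades as a
  # cold-mortality association and attenuates the cold estimate
  set.seed(29)
  temps <- simulate_temperature(temp_sim_config())
  u <- (seq_len(nrow(temps)) - 1) / 365.25
  temps$tmean <- temps$tmean + 0.05 * u          # ~2.9 C warming over 57 y
  d <- simulate_mortality(temps, mort_sim_config(
    trend = function(u) -0.4 * stats::plogis((u - 28) / 6), flu = NULL,
    harvest = harvest_config(beta_cold = 0.02, f = 0), expectation = TRUE))
  a <- build_annual_series(d)
  f5 <- fit_annual(a, spline_df = 5, include_flu = FALSE)
  f2 <- fit_annual(a, spline_df = 2, include_flu = FALSE)
  truth <- 100 * (exp(0.02) - 1)
  expect_lt(pct_of(f2, "cold"), pct_of(f5, "cold"))
  expect_lt(abs(pct_of(f5, "cold") - truth) / truth, 0.2)
})

test_that("sensitivity grid reports every default variant with AIC", {
  g <- generate_dataset(
    mort_config = mort_sim_config(
      steps = data.frame(year = c(1965, 1966), factor = c(1.15, 1.08)),
      harvest = harvest_config(beta_cold = 0.017, f = 0.3)),
    seed = 7)
  sg <- sensitivity_grid(g$daily, steps = c(1965, 1966))
  expect_s3_class(sg, "tm_sensitivity")
  expect_equal(sg$label[1], "main")
  expect_true(all(c("simple regression", "negative binomial",
                    "3-knot spline (df=2)", "9-knot spline (df=8)",
                    "threshold 15C", "threshold 21C",
                    "no influenza adjustment") %in% sg$label))
  expect_true(all(is.finite(sg$cold_pct)))
  expect_true(is.na(sg$aic[sg$label == "simple regression"]))
  expect_true(all(sg$cold_lo < sg$cold_pct & sg$cold_pct < sg$cold_hi))
})
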