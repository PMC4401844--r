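test_that("natural-spline trend basis has the expected structure", {
  t <- 1:57
  b1 <- trend_basis(t, 1)
  expect_equal(ncol(b1), 1L)
  # df = 1: single column affinely equivalent to t
  expect_gt(abs(cor(b1[, 1], t)), 1 - 1e-12)
  expect_error(trend_basis(t, 0), "df")
  expect_error(trend_basis(t, 56), "df")

  # df = 5 over 57 years acts like a ~10-year moving average on a smooth trend
  smooth <- sin(t / 9) + 0.02 * t
  X <- cbind(1, trend_basis(t, 5))
  fitted5 <- X %*% qr.solve(X, smooth)
  ma10 <- stats::filter(smooth, rep(1 / 11, 11))
  ok <- !is.na(ma10)
  expect_gt(cor(fitted5[ok], ma10[ok]), 0.95)
})

test_that("Poisson MLE reproduces closed forms", {
  # two groups with mean counts 100 and 121: beta = log ratio of means
  y <- c(rep(100, 10), rep(121, 10))
  X <- cbind("(Intercept)" = 1, exposure = rep(0:1, each = 10))
  fit <- fit_count_model(y, X, family = "poisson",
                         exposure_terms = "exposure")
  expect_equal(unname(coef(fit)["exposure"]), log(1.21), tolerance = 1e-8)
  expect_equal(pct_of(fit, "exposure"), 21, tolerance = 1e-6)
  # intercept-only: beta0 = log(mean)
  f0 <- fit_count_model(c(3, 5, 10), icol(3), family = "poisson")
  expect_equal(unname(coef(f0)), log(6), tolerance = 1e-8)
})

test_that("Pearson dispersion of a true Poisson sample is near 1", {
  set.seed(11)
  y <- rpois(5000, 40)
  fit <- fit_count_model(y, icol(5000), family = "quasipoisson")
  expect_gt(fit$dispersion, 0.9)
  expect_lt(fit$dispersion, 1.1)
})

test_that("quasi-Poisson shares point estimates with Poisson, SEs scale by sqrt(phi)", {
  set.seed(2)
  X <- cbind("(Intercept)" = 1, x = rnorm(80))
  y <- rpois(80, exp(3 + 0.3 * X[, "x"])) * sample(1:2, 80, TRUE)
  fp <- fit_count_model(y, X, family = "poisson")
  fq <- fit_count_model(y, X, family = "quasipoisson")
  expect_equal(coef(fp), coef(fq), tolerance = 1e-12)
  expect_equal(unname(fq$se / fp$se), rep(sqrt(fq$dispersion), 2), tolerance = 1e-10)
})

test_that("negative binomial approaches Poisson as overdispersion vanishes", {
  set.seed(3)
  X <- cbind("(Intercept)" = 1, x = rnorm(2000))
  y <- rpois(2000, exp(2 + 0.25 * X[, "x"]))
  fp <- fit_count_model(y, X, family = "poisson")
  fnb <- fit_count_model(y, X, family = "negbin")
  expect_lt(max(abs(coef(fnb) - coef(fp))), 1e-3)
})

test_that("AIC follows the -2 loglik + 2 terms definition", {
  # saturated one-observation toy: y = 1, mu-hat = 1, loglik = -1, AIC = 4
  f1 <- fit_count_model(1, cbind("(Intercept)" = 1), family = "poisson")
  expect_equal(f1$loglik, -1)
  expect_equal(model_aic(f1), 4)
  # simple regression has no likelihood-based AIC
  y <- exp(rnorm(20, 3, 0.1))
  fs <- fit_count_model(y, cbind("(Intercept)" = 1, x = rnorm(20)),
                        family = "simple")
  expect_true(is.na(model_aic(fs)))
  expect_error(fit_count_model(c(0, 1, 2), icol(3),
                               family = "simple"), "positive")
  # a pure-noise column usually raises AIC (penalty 2 vs E[chi2_1] = 1)
  set.seed(9)
  rises <- vapply(1:20, function(i) {
    yy <- rpois(50, 20)
    X0 <- icol(50)
    X1 <- cbind(X0, noise = rnorm(50))
    model_aic(fit_count_model(yy, X1, family = "poisson")) >
      model_aic(fit_count_model(yy, X0, family = "poisson"))
  }, logical(1))
  expect_gte(sum(rises), 13)
})

test_that("percent transform is zero at zero and monotone", {
  b <- seq(-0.05, 0.05, by = 0.01)
  tab <- percent_table(setNames(b, paste0("b", seq_along(b))),
                       setNames(rep(0.01, length(b)), paste0("b", seq_along(b))))
  expect_equal(tab$pct[b == 0], 0)
  expect_true(all(diff(tab$pct) > 0))
  expect_true(all(tab$pct_lo < tab$pct & tab$pct < tab$pct_hi))
})

test_that("design rank deficiency is reported with the offending column", {
  X <- cbind("(Intercept)" = 1, a = 1:10, dup = 1:10)
  expect_error(fit_count_model(rpois(10, 5), X), "dup")
})

test_that("residual diagnostics behave under a perfect and a white-noise fit", {
  # perfectly fitted saturated model: residuals all zero
  f <- list(y = c(4, 9, 2), fitted = c(4, 9, 2))
  expect_equal(residual_diagnostics(f)$residuals, c(0, 0, 0))
  # lag-1 autocorrelation of white noise stays within the band ~95% of the time
  set.seed(5)
  inside <- vapply(1:200, function(i) {
    y <- rpois(57, 100)
    fit <- fit_count_model(y, icol(57), family = "poisson")
    d <- residual_diagnostics(fit)
    abs(d$lag1) < d$band
  }, logical(1))
  expect_gt(mean(inside), 0.88)
  # mean deviance residual near zero for a well-specified fit
  set.seed(6)
  X <- cbind("(Intercept)" = 1, x = rnorm(500))
  fit <- fit_count_model(rpois(500, exp(3 + 0.2 * X[, "x"])), X, family = "poisson")
  expect_lt(abs(mean(residual_diagnostics(fit)$residuals)), 0.1)
})
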