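#' Natural cubic spline basis for the secular trend
#'
#' Thin wrapper around [splines::ns()]: a natural cubic spline of the year
#' index, linear beyond the boundary knots, with interior knots at equally
#' spaced quantiles.  With `df = 1` the basis is a single column affinely
#' equivalent to the index itself.
#'
#' @param t numeric time index (e.g. `1:T` year indices).
#' @param df degrees of freedom, `1 <= df <= length(t) - 2`.
#' @return numeric matrix with `df` columns named `trend1..trenddf`.
#' @export
trend_basis <- function(t, df) {
  df <- as.integer(df)
  if (df < 1L || df > length(t) - 2L)
    stop("spline df must be between 1 and length(t) - 2")
  b <- splines::ns(t, df = df)
  b <- matrix(as.numeric(b), nrow = length(t),
              dimnames = list(NULL, paste0("trend", seq_len(df))))
  b
}

pois_loglik <- function(y, mu) {
  # Poisson log-likelihood valid for non-integer y (expectation-mode series)
  sum(ifelse(y > 0, y * log(mu), 0) - mu - lgamma(y + 1))
}

check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Fit a log-linear count model
#'
#' Fits the families used for the annual series: Poisson, quasi-Poisson
#' (identical point estimates, standard errors scaled by the square root of
#' the Pearson dispersion), negative binomial (via [MASS::glm.nb()]), and
#' `"simple"` (ordinary least squares of `log(y)` on the design, with the
#' coefficients read as log-rate effects).
#'
#' @param y non-negative response counts (non-integer values are allowed,
#'   for expectation-mode simulated series).
#' @param X design matrix including the intercept column, with column names.
#' @param family one of `"quasipoisson"` (default), `"poisson"`, `"negbin"`,
#'   `"simple"`.
#' @param exposure_terms names of the design columns whose coefficients are
#'   reported as percent increase per degree C.
#' @return An object of class `"tm_fit"`: coefficients on the log-rate
#'   scale, dispersion-scaled standard errors and covariance, Pearson
#'   dispersion `phi`, Poisson (or NB) log-likelihood and AIC, fitted means,
#'   and a percent-increase table for the exposure terms.
#' @export
fit_count_model <- function(y, X,
                            family = c("quasipoisson", "poisson", "negbin", "simple"),
                            exposure_terms = intersect(c("cold", "heat"), colnames(X))) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(y) != nrow(X)) stop("length(y) != nrow(X)")
  if (any(y < 0)) stop("negative counts")
  check_full_rank(X)
  n <- length(y); p <- ncol(X)

  if (family %in% c("poisson", "quasipoisson")) {
    # quasipoisson() runs the same IRLS as poisson() but accepts the
    # non-integer responses of expectation-mode simulated series
    fit <- stats::glm.fit(X, y, family = quasipoisson(),
                          control = list(epsilon = 1e-10, maxit = 200))
    if (!fit$converged) stop("IRLS did not converge for the Poisson fit")
    beta <- fit$coefficients
    mu <- fit$fitted.values
    # unscaled covariance from the final IRLS weights
    XtWX <- crossprod(X * sqrt(fit$weights))
    V0 <- chol2inv(chol(XtWX))
    phi <- sum((y - mu)^2 / mu) / (n - p)
    scale2 <- if (family == "quasipoisson") phi else 1
    V <- V0 * scale2
    ll <- pois_loglik(y, mu)
    out <- list(coefficients = beta, se = sqrt(diag(V)), vcov = V,
                dispersion = phi, fitted = mu, loglik = ll,
                aic = -2 * ll + 2 * p)
  } else if (family == "negbin") {
    dd <- as.data.frame(X)
    safe <- make.names(colnames(X), unique = TRUE)
    names(dd) <- safe
    dd$.y <- y
    # near-Poisson data drive theta -> Inf; glm.nb then warns about its
    # iteration/alternation limits, which is the benign Poisson limit
    fit <- withCallingHandlers(
      MASS::glm.nb(.y ~ 0 + ., data = dd),
      warning = function(w) {
        if (grepl("iteration limit|alternation limit", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    beta <- coef(fit); names(beta) <- colnames(X)
    V <- vcov(fit); dimnames(V) <- list(colnames(X), colnames(X))
    mu <- fitted(fit)
    phi <- sum((y - mu)^2 / (mu * (1 + mu / fit$theta))) / (n - p)
    out <- list(coefficients = beta, se = sqrt(diag(V)), vcov = V,
                dispersion = phi, fitted = mu,
                loglik = as.numeric(stats::logLik(fit)),
                aic = stats::AIC(fit), theta = fit$theta)
  } else { # simple: OLS on log counts
    if (any(y <= 0)) stop("family=\"simple\" requires strictly positive counts")
    ly <- log(y)
    fit <- stats::lm.fit(X, ly)
    beta <- fit$coefficients
    res <- ly - X %*% beta
    s2 <- sum(res^2) / (n - p)
    V <- chol2inv(chol(crossprod(X))) * s2
    dimnames(V) <- list(colnames(X), colnames(X))
    out <- list(coefficients = beta, se = sqrt(diag(V)), vcov = V,
                dispersion = NA_real_, fitted = exp(X %*% beta)[, 1],
                loglik = NA_real_, aic = NA_real_)
  }
  names(out$se) <- colnames(X)
  out$family <- family
  out$y <- y
  out$X <- X
  out$nobs <- n
  out$df_residual <- n - p
  out$exposure_terms <- exposure_terms
  out$percent <- percent_table(out$coefficients, out$se, exposure_terms)
  class(out) <- "tm_fit"
  out
}

#' Percent increase per unit exposure with 95% Wald interval
#'
#' Transforms log-rate coefficients to the percent scale,
#' `100 * (exp(beta) - 1)`, with a symmetric z = 1.96 interval on the log
#' scale transformed to percent.
#'
#' @param beta named coefficient vector (log-rate per unit).
#' @param se matching standard errors.
#' @param terms which terms to report (default all).
#' @return `data.frame` with `term`, `beta`, `se`, `pct`, `pct_lo`, `pct_hi`.
#' @export
percent_table <- function(beta, se, terms = names(beta)) {
  terms <- intersect(terms, names(beta))
  b <- beta[terms]; s <- se[terms]
  data.frame(term = terms, beta = unname(b), se = unname(s),
             pct = 100 * (exp(b) - 1),
             pct_lo = 100 * (exp(b - 1.96 * s) - 1),
             pct_hi = 100 * (exp(b + 1.96 * s) - 1),
             row.names = NULL)
}

#' Akaike information criterion of a fitted count model
#'
#' `-2 * loglik + 2 * terms`, using the unscaled Poisson likelihood for both
#' Poisson and quasi-Poisson fits and the NB likelihood for negative
#' binomial; undefined (`NA`) for the `"simple"` log-count regression.
#'
#' @param fit a `"tm_fit"`.
#' @return numeric AIC or `NA_real_`.
#' @export
model_aic <- function(fit) {
  stopifnot(inherits(fit, "tm_fit"))
  fit$aic
}

#' Residual diagnostics for a fitted count model
#'
#' Deviance residuals in time order, residual-vs-fitted values, and the
#' lag-1 residual autocorrelation with the approximate 95% white-noise band
#' `+/- 1.96 / sqrt(n)`.
#'
#' @param fit a `"tm_fit"` (or an object with `$y` and `$fitted`).
#' @param time optional time order (defaults to observation order).
#' @return object of class `"tm_diagnostics"` with `residuals`, `fitted`,
#'   `time`, `lag1`, `band`.
#' @export
residual_diagnostics <- function(fit, time = seq_along(fit$y)) {
  y <- fit$y; mu <- as.numeric(fit$fitted)
  dev <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  r <- sign(y - mu) * sqrt(pmax(dev, 0))
  n <- length(r)
  rc <- r - mean(r)
  lag1 <- if (n > 2) sum(rc[-1] * rc[-n]) / sum(rc^2) else NA_real_
  out <- list(residuals = r, fitted = mu, time = time,
              lag1 = lag1, band = 1.96 / sqrt(n), n = n)
  class(out) <- "tm_diagnostics"
  out
}

#' @export
print.tm_diagnostics <- function(x, ...) {
  cat("Residual diagnostics (deviance residuals)\n")
  cat(sprintf("  n = %d, mean = %.4f, sd = %.4f\n", x$n, mean(x$residuals), sd(x$residuals)))
  cat(sprintf("  lag-1 autocorrelation = %.3f (95%% white-noise band +/- %.3f)\n",
              x$lag1, x$band))
  invisible(x)
}

#' @export
plot.tm_diagnostics <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$time, x$residuals, xlab = "time", ylab = "deviance residual",
       main = "Residuals vs time", ...)
  abline(h = 0, lty = 2)
  plot(x$fitted, x$residuals, xlab = "fitted mean", ylab = "deviance residual",
       main = "Residuals vs fitted", ...)
  abline(h = 0, lty = 2)
  invisible(x)
}
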