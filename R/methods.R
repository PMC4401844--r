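#' @export
print.tm_fit <- function(x, digits = 3, ...) {
  cat("Log-linear count model (", x$family, "), n = ", x$nobs, sep = "")
  if (!is.null(x$n_strata)) cat(", strata =", x$n_strata)
  cat("\n")
  if (nrow(x$percent)) {
    cat("Percent increase per degree C (95% CI):\n")
    for (i in seq_len(nrow(x$percent)))
      cat(sprintf("  %-6s %5.2f%% (%.2f to %.2f)\n", x$percent$term[i],
                  x$percent$pct[i], x$percent$pct_lo[i], x$percent$pct_hi[i]))
  }
  if (is.finite(x$dispersion))
    cat(sprintf("Dispersion (Pearson) = %.3f", x$dispersion))
  if (is.finite(x$aic)) cat(sprintf("   AIC = %.1f", x$aic))
  cat("\n")
  invisible(x)
}

#' @export
summary.tm_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  out <- list(fit = object, coef_table = tab)
  class(out) <- "summary.tm_fit"
  out
}

#' @export
print.summary.tm_fit <- function(x, ...) {
  print(x$fit)
  cat("\nCoefficients (log-rate scale):\n")
  printCoefmat(x$coef_table, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.tm_fit <- function(object, ...) object$coefficients

#' @export
vcov.tm_fit <- function(object, ...) object$vcov

#' @export
fitted.tm_fit <- function(object, ...) object$fitted

#' @export
logLik.tm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients), class = "logLik")
}

#' @export
nobs.tm_fit <- function(object, ...) object$nobs

#' @export
confint.tm_fit <- function(object, parm = names(object$coefficients),
                           level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  b <- object$coefficients[parm]; s <- object$se[parm]
  out <- cbind(b - z * s, b + z * s)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  out
}

#' @export
residuals.tm_fit <- function(object, type = c("deviance", "pearson", "response"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- as.numeric(object$fitted)
  switch(type,
         response = y - mu,
         pearson = (y - mu) / sqrt(mu),
         deviance = {
           dev <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
           sign(y - mu) * sqrt(pmax(dev, 0))
         })
}

#' @export
predict.tm_fit <- function(object, newX = NULL, type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newX)) object$X else as.matrix(newX)
  eta <- as.vector(X %*% object$coefficients[colnames(X)])
  if (type == "link") eta else exp(eta)
}

#' @export
simulate.tm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- as.numeric(object$fitted)
  out <- as.data.frame(replicate(nsim, rpois(length(mu), mu)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.tm_annual <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  yl <- x$annual$year_label
  plot(yl, x$y, xlab = "analysis year", ylab = "deaths",
       main = "Observed and fitted annual deaths", ...)
  lines(yl, x$fitted, col = 2, lwd = 2)
  dg <- residual_diagnostics(x, time = yl)
  plot(yl, dg$residuals, xlab = "analysis year", ylab = "deviance residual",
       main = sprintf("Residuals (lag-1 r = %.2f)", dg$lag1), ...)
  abline(h = 0, lty = 2); abline(h = c(-2, 2), lty = 3, col = "grey")
  invisible(x)
}
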