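#' Conditional (stratum-eliminated) Poisson regression
#'
#' Maximises the Poisson log-likelihood conditional on the stratum totals,
#' `sum_s sum_{i in s} y_i (x_i b - log sum_{j in s} exp(x_j b))`, which is
#' equivalent to a Poisson regression with one fixed effect per stratum and,
#' with year-by-month strata, to a time-stratified case-crossover design.
#' Standard errors are scaled by the Pearson dispersion computed from the
#' conditional fitted means (`mu_i = Y_s p_i`), with residual degrees of
#' freedom `n - strata - terms`.
#'
#' Strata with fewer than two observations or a zero total count carry no
#' information and are dropped (with a warning for the former).  If the
#' exposures are constant within every stratum the coefficients are
#' inestimable and an error is raised.
#'
#' @param y non-negative counts (one per week).
#' @param X exposure design matrix (no intercept; it is absorbed by the
#'   strata), with column names.
#' @param strata stratum labels (factor or character), e.g. `"YYYY-MM"`.
#' @param family `"quasipoisson"` (dispersion-scaled SEs, default) or
#'   `"poisson"`.
#' @param tol convergence tolerance on the scaled score norm.
#' @param maxit maximum Newton iterations (with step-halving).
#' @return A `"tm_fit"` with conditional log-likelihood, dispersion, and the
#'   percent-increase table for the exposure columns.
#' @export
fit_conditional_poisson <- function(y, X, strata,
                                    family = c("quasipoisson", "poisson"),
                                    tol = 1e-8, maxit = 100L) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  strata <- as.character(strata)
  stopifnot(length(y) == nrow(X), length(strata) == nrow(X))
  if (any(y < 0)) stop("negative counts")

  size <- table(strata)
  singletons <- names(size)[size < 2L]
  if (length(singletons))
    warning("dropping ", length(singletons), " stratum/strata with a single observation")
  tot <- tapply(y, strata, sum)
  empty <- names(tot)[tot == 0]
  keep <- !(strata %in% c(singletons, empty))
  if (!any(keep)) stop("no informative strata remain")
  y <- y[keep]; X <- X[keep, , drop = FALSE]; s <- factor(strata[keep])
  n <- length(y); p <- ncol(X); S <- nlevels(s)
  si <- as.integer(s)
  Ys <- as.vector(rowsum(y, si))

  cond_parts <- function(beta) {
    eta <- as.vector(X %*% beta)
    m <- as.vector(tapply(eta, s, max))      # level order == si order
    w <- exp(eta - m[si])
    denom <- as.vector(rowsum(w, si))
    pr <- w / denom[si]
    mu <- Ys[si] * pr
    ll <- sum(y * eta) - sum(Ys * (log(denom) + m))
    list(mu = mu, pr = pr, ll = ll)
  }
  info_matrix <- function(mu, pr) {
    XB <- rowsum(pr * X, si)                 # stratum-weighted mean exposures
    crossprod(X, mu * X) - crossprod(XB, Ys * XB)
  }

  beta <- rep(0, p)
  parts <- cond_parts(beta)
  I0 <- info_matrix(parts$mu, parts$pr)
  if (rcond(I0) < 1e-12)
    stop("exposures are (numerically) constant within every stratum; ",
         "coefficients are inestimable after conditioning")
  scale0 <- max(1, sum(y))
  for (it in seq_len(maxit)) {
    grad <- as.vector(crossprod(X, y - parts$mu))
    I <- info_matrix(parts$mu, parts$pr)
    if (max(abs(grad)) < tol * scale0) break
    delta <- solve(I, grad)
    step <- 1
    repeat {
      cand <- cond_parts(beta + step * delta)
      if (cand$ll >= parts$ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta + step * delta
    parts <- cand
    if (it == maxit && max(abs(crossprod(X, y - parts$mu))) >= tol * scale0)
      stop("conditional Poisson did not converge in ", maxit, " iterations")
  }
  names(beta) <- colnames(X)
  mu <- parts$mu
  I <- info_matrix(mu, parts$pr)
  V0 <- chol2inv(chol(I))
  df_res <- n - S - p
  phi <- sum((y - mu)^2 / mu) / max(df_res, 1)
  scale2 <- if (family == "quasipoisson") phi else 1
  V <- V0 * scale2
  dimnames(V) <- list(colnames(X), colnames(X))
  out <- list(coefficients = beta, se = sqrt(diag(V)), vcov = V,
              dispersion = phi, fitted = mu, loglik = parts$ll,
              aic = -2 * parts$ll + 2 * p,
              family = paste0("conditional-", family),
              y = y, X = X, strata = s, n_strata = S,
              nobs = n, df_residual = df_res,
              exposure_terms = colnames(X),
              percent = percent_table(beta, sqrt(diag(V))))
  class(out) <- "tm_fit"
  out
}
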