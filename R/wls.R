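## Weighted least squares with known measurement sigmas.
## Returns coefficients, the unscaled covariance (X' W X)^-1 appropriate when
## the weights are 1/sigma^2 of known errors, and the chi-square diagnostic.
## lm()'s covariance is rescaled by the residual variance, which is not what
## error propagation from counting statistics needs, hence this helper.
wls_fit <- function(X, y, sigma) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), length(sigma) == length(y), all(sigma > 0))
  w <- 1 / sigma^2
  XtW <- t(X * w)
  M <- XtW %*% X
  cov <- solve(M)
  beta <- unname(drop(cov %*% (XtW %*% y)))
  dimnames(cov) <- NULL
  r <- y - drop(X %*% beta)
  chi2 <- sum(w * r^2)
  dof <- length(y) - ncol(X)
  list(coef = beta, cov = cov, residuals = r, chi2 = chi2, dof = dof,
       chi2_red = if (dof > 0) chi2 / dof else NA_real_)
}

## Wald-Wolfowitz runs test statistic on residual signs; |z| large means a
## systematic trend (too few runs). Returns NA for < 4 points.
runs_test_z <- function(r) {
  s <- sign(r)
  s <- s[s != 0]
  n <- length(s)
  if (n < 4) return(NA_real_)
  n1 <- sum(s > 0); n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(0)
  runs <- 1 + sum(s[-1] != s[-n])
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(NA_real_)
  (runs - mu) / sqrt(v)
}
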