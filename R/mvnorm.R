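# Small-K standardized multivariate normal rectangle probabilities,
# P(X_1 <= c_1, ..., X_K <= c_K) with unit variances and correlation Sigma.
# K <= 3 suffices here (power formulas for up to three endpoints). K = 2 uses
# the single-integral reduction of the bivariate CDF (integrating the
# correlation parameter); K = 3 conditions on the first variable and
# integrates the conditional bivariate CDF. Deterministic, abs tol ~1e-8.

pnorm2 <- function(h, k, rho) {
  if (abs(rho) >= 1 - 1e-12) {
    return(if (rho > 0) stats::pnorm(min(h, k))
           else max(0, stats::pnorm(h) + stats::pnorm(k) - 1))
  }
  if (!is.finite(h) && h > 0) return(stats::pnorm(k))
  if (!is.finite(k) && k > 0) return(stats::pnorm(h))
  if (h == -Inf || k == -Inf) return(0)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  corr <- stats::integrate(function(r) {
    1 / (2 * pi * sqrt(1 - r^2)) *
      exp(-(h^2 - 2 * h * k * r + k^2) / (2 * (1 - r^2)))
  }, 0, rho, rel.tol = 1e-10, abs.tol = 1e-12)$value
  min(1, max(0, base + corr))
}

pnorm3 <- function(c1, c2, c3, S) {
  r12 <- S[1, 2]; r13 <- S[1, 3]; r23 <- S[2, 3]
  s2 <- sqrt(1 - r12^2); s3 <- sqrt(1 - r13^2)
  rc <- (r23 - r12 * r13) / (s2 * s3)
  rc <- max(-1, min(1, rc))
  f <- function(x) {
    vapply(x, function(xi)
      pnorm2((c2 - r12 * xi) / s2, (c3 - r13 * xi) / s3, rc),
      numeric(1)) * stats::dnorm(x)
  }
  lo <- -8.5
  hi <- min(c1, 8.5)
  if (hi <= lo) return(0)
  stats::integrate(f, lo, hi, rel.tol = 1e-9, abs.tol = 1e-10)$value
}

# upper: length-K vector of (possibly infinite) upper limits
pmvnorm_rect <- function(upper, Sigma) {
  K <- length(upper)
  if (K == 1) return(stats::pnorm(upper))
  Sigma <- as.matrix(Sigma)
  if (!isSymmetric(unname(Sigma), tol = 1e-8) ||
      any(abs(diag(Sigma) - 1) > 1e-8))
    stop("`Sigma` must be a correlation matrix (unit diagonal).",
         call. = FALSE)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("`Sigma` must be positive semi-definite.", call. = FALSE)
  if (K == 2) return(pnorm2(upper[1], upper[2], Sigma[1, 2]))
  if (K == 3) return(pnorm3(upper[1], upper[2], upper[3], Sigma))
  stop("Rectangle probabilities implemented for K <= 3.", call. = FALSE)
}
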