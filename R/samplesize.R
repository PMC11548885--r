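#' Approximate power of a decision rule at a given per-arm sample size
#'
#' Large-sample normal approximation of the probability of concluding
#' superiority, used for a priori sample-size determination. For the Any and
#' All rules the power is expressed through a cumulative K-variate normal
#' distribution with mean zero and correlation matrix `Sigma` (the pairwise
#' correlations between endpoints, assumed to transfer to the endpoint test
#' statistics): with standardized shifts
#' `e_k = (theta1_k - theta0_k) * sqrt(n) / sqrt(theta1_k (1 - theta1_k) +
#' theta0_k (1 - theta0_k))`,
#' the All rule rejects on every endpoint, giving power
#' `Psi_K(-z_{1-alpha} + e_1, ..., -z_{1-alpha} + e_K)`, and the Any rule
#' rejects on at least one endpoint at the multiplicity-corrected level,
#' giving power `1 - Psi_K(z_{1-alpha/K} - e_1, ..., z_{1-alpha/K} - e_K)`.
#' The Compensatory rule reduces to a univariate two-proportion test on the
#' weighted success probabilities `theta_Tw = sum_k w_k theta_Tk`.
#'
#' At `K = 1` the Any and All rules coincide with the standard univariate
#' two-proportion normal-approximation power.
#'
#' @param rule `"any"`, `"all"` or `"compensatory"`.
#' @param n Per-arm sample size.
#' @param theta1,theta0 Length-K success probabilities per arm, in (0, 1).
#' @param Sigma `K x K` correlation matrix between endpoints (unit diagonal);
#'   a scalar is taken as an exchangeable pairwise correlation.
#' @param alpha One-sided decision error rate.
#' @param weights Compensatory-rule weights.
#' @return Power (scalar in `[0, 1]`).
#' @export
analytic_power <- function(rule, n, theta1, theta0, Sigma = 0,
                           alpha = 0.05, weights = NULL) {
  K <- length(theta1)
  stopifnot(length(theta0) == K, n > 0)
  if (any(theta1 <= 0 | theta1 >= 1 | theta0 <= 0 | theta0 >= 1))
    stop("Success probabilities must lie in (0, 1).", call. = FALSE)
  Sigma <- expand_corr(Sigma, K)
  if (rule == "compensatory") {
    check_weights(weights, K)
    t1w <- sum(weights * theta1); t0w <- sum(weights * theta0)
    v <- t1w * (1 - t1w) + t0w * (1 - t0w)
    e <- (t1w - t0w) * sqrt(n) / sqrt(v)
    return(stats::pnorm(-stats::qnorm(1 - alpha) + e))
  }
  se <- sqrt(theta1 * (1 - theta1) + theta0 * (1 - theta0))
  e <- (theta1 - theta0) * sqrt(n) / se
  if (rule == "all") {
    pmvnorm_rect(-stats::qnorm(1 - alpha) + e, Sigma)
  } else if (rule == "any") {
    1 - pmvnorm_rect(stats::qnorm(1 - alpha / K) - e, Sigma)
  } else stop("Unknown rule `", rule, "`.", call. = FALSE)
}

expand_corr <- function(Sigma, K) {
  if (length(Sigma) == 1) {
    S <- matrix(Sigma, K, K); diag(S) <- 1
    return(S)
  }
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == K, ncol(Sigma) == K)
  Sigma
}

#' A priori per-arm sample size for a decision rule
#'
#' Computes the smallest integer per-arm `n` reaching the target power. For
#' the Any and All rules this follows the iterative procedure over the
#' multivariate-normal power approximation (implemented as geometric
#' bracketing plus binary search, equivalent to gradually increasing `n`).
#' For the Compensatory rule the closed form for a large-sample two-proportion
#' test on the weighted success probabilities is used:
#' `n = ceil( [t1w (1 - t1w) + t0w (1 - t0w)] *
#'            ((z_{1-alpha} + z_{1-beta}) / (t1w - t0w))^2 )`.
#'
#' @inheritParams analytic_power
#' @param power Target power `1 - beta` (default 0.80).
#' @param n_max Search ceiling for the iterative rules.
#' @return A one-row tibble with `rule`, `n` (per arm), `achieved_power`
#'   (analytic power at the returned `n`), `alpha`, `power_target`.
#' @examples
#' required_n("compensatory", theta1 = c(0.6), theta0 = c(0.5),
#'            weights = 1)  # n = 303 per arm
#' @export
required_n <- function(rule, theta1, theta0, Sigma = 0, alpha = 0.05,
                       power = 0.80, weights = NULL, n_max = 1e7) {
  K <- length(theta1)
  if (rule == "compensatory") {
    check_weights(weights, K)
    t1w <- sum(weights * theta1); t0w <- sum(weights * theta0)
    if (abs(t1w - t0w) < 1e-12)
      stop("No solution: weighted success probabilities are equal.",
           call. = FALSE)
    n <- ceiling((t1w * (1 - t1w) + t0w * (1 - t0w)) *
                   ((stats::qnorm(1 - alpha) + stats::qnorm(power)) /
                      (t1w - t0w))^2)
    ach <- analytic_power(rule, n, theta1, theta0, Sigma, alpha, weights)
  } else {
    pw <- function(n) analytic_power(rule, n, theta1, theta0, Sigma, alpha,
                                     weights)
    lo <- 2
    if (pw(lo) >= power) {
      n <- lo
    } else {
      hi <- 4
      while (pw(hi) < power) {
        lo <- hi; hi <- hi * 2
        if (hi > n_max)
          stop("No solution: target power unattainable by n = ", n_max,
               " (null or adverse effect?).", call. = FALSE)
      }
      while (hi - lo > 1) {  # pw(lo) < power <= pw(hi)
        mid <- (lo + hi) %/% 2
        if (pw(mid) >= power) hi <- mid else lo <- mid
      }
      n <- hi
    }
    ach <- pw(n)
  }
  tibble::tibble(rule = rule, n = as.integer(n), achieved_power = ach,
                 alpha = alpha, power_target = power)
}
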