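#' Joint response probabilities from margins and pairwise correlation
#'
#' Converts endpoint success probabilities and a pairwise (phi-coefficient)
#' correlation into the joint configuration probabilities on the rows of
#' `config_matrix(K)`. For two endpoints the bivariate Bernoulli identity is
#' exact: `phi_11 = theta1 theta2 + rho sqrt(theta1(1-theta1)
#' theta2(1-theta2))`, and the remaining cells follow from the margins. For
#' three endpoints all pairwise success cells are fixed the same way and the
#' triple-success probability is set to the midpoint of its feasibility
#' interval given the pairwise cells (the pairwise correlations do not
#' identify it). Infeasible combinations (outside the Frechet-type bounds)
#' raise an error naming the violated bound.
#'
#' @param theta Length-K success probabilities in (0, 1), K in `{2, 3}`.
#' @param rho Pairwise correlation: scalar (exchangeable) or `K x K` matrix.
#' @return Length-Q probability vector ordered as `config_matrix(K)` rows.
#' @examples
#' phi_from_margins(c(0.5, 0.5), 0.2)  # (0.30, 0.20, 0.20, 0.30)
#' @export
phi_from_margins <- function(theta, rho) {
  K <- length(theta)
  if (!K %in% c(2, 3))
    stop("`phi_from_margins()` supports K = 2 or 3 endpoints.", call. = FALSE)
  if (any(theta <= 0 | theta >= 1))
    stop("`theta` must lie strictly in (0, 1).", call. = FALSE)
  R <- expand_corr(rho, K)
  s <- sqrt(theta * (1 - theta))
  pair <- function(k, l) {
    p <- theta[k] * theta[l] + R[k, l] * s[k] * s[l]
    lo <- max(0, theta[k] + theta[l] - 1); hi <- min(theta[k], theta[l])
    if (p < lo - 1e-12 || p > hi + 1e-12)
      stop(sprintf(paste0("Infeasible (theta, rho): joint success cell for ",
                          "endpoints %d,%d is %.4f, outside [%.4f, %.4f]."),
                   k, l, p, lo, hi), call. = FALSE)
    min(max(p, lo), hi)
  }
  if (K == 2) {
    p11 <- pair(1, 2)
    phi <- c(p11, theta[1] - p11, theta[2] - p11, 1 - theta[1] - theta[2] + p11)
  } else {
    p12 <- pair(1, 2); p13 <- pair(1, 3); p23 <- pair(2, 3)
    lo <- max(0, p12 + p13 - theta[1], p12 + p23 - theta[2],
              p13 + p23 - theta[3])
    hi <- min(p12, p13, p23,
              1 - theta[1] - theta[2] - theta[3] + p12 + p13 + p23)
    if (lo > hi + 1e-12)
      stop(sprintf(paste0("Infeasible (theta, rho): triple-success interval ",
                          "[%.4f, %.4f] is empty."), lo, hi), call. = FALSE)
    m <- (lo + hi) / 2  # midpoint convention; pairwise targets fix only pairs
    phi <- c(m,                                   # 111
             p12 - m,                             # 110
             p13 - m,                             # 101
             theta[1] - p12 - p13 + m,            # 100
             p23 - m,                             # 011
             theta[2] - p12 - p23 + m,            # 010
             theta[3] - p13 - p23 + m,            # 001
             1 - sum(theta) + p12 + p13 + p23 - m)  # 000
  }
  if (any(phi < -1e-12))
    stop("Infeasible (theta, rho): a joint cell is negative.", call. = FALSE)
  pmax(phi, 0)
}

#' Multinomial-logistic coefficients reproducing four anchor cells
#'
#' Inverts the trial model `psi_q = beta0_q + betaT_q T + beta1_q z +
#' beta2_q z T` at the four (arm, anchor) combinations: given feasible joint
#' probability vectors `phi` at `(T, a)` for `T in {0, 1}` and anchor values
#' `a in {a_low, a_high}`, solves the 4x4 linear system
#' `psi_q(T, a) = log(phi_q(T, a) / phi_Q(T, a))` per non-reference category.
#' The round trip through [inverse_mlogit()] is exact to numerical precision.
#'
#' @param cells A list with elements `phi0_low`, `phi0_high`, `phi1_low`,
#'   `phi1_high`: length-Q joint probability vectors for control/treated arms
#'   at the low/high anchor.
#' @param anchors Length-2 anchor covariate values (low, high), e.g. `c(0, 1)`
#'   for a binary covariate or `c(-1, 1)` for a standardized continuous one.
#' @return A `4 x (Q-1)` coefficient matrix (rows: intercept, treatment,
#'   covariate, interaction; columns: categories `1..Q-1`).
#' @export
beta_from_cells <- function(cells, anchors) {
  stopifnot(all(c("phi0_low", "phi0_high", "phi1_low", "phi1_high") %in%
                  names(cells)), length(anchors) == 2)
  if (anchors[1] == anchors[2])
    stop("Anchor values must differ.", call. = FALSE)
  Q <- length(cells$phi0_low)
  A <- rbind(c(1, 0, anchors[1], 0),
             c(1, 0, anchors[2], 0),
             c(1, 1, anchors[1], anchors[1]),
             c(1, 1, anchors[2], anchors[2]))
  logit_ref <- function(phi) {
    if (phi[Q] <= 0)
      stop("Reference-category probability is zero in a cell.", call. = FALSE)
    log(phi[-Q] / phi[Q])
  }
  Y <- rbind(logit_ref(cells$phi0_low), logit_ref(cells$phi0_high),
             logit_ref(cells$phi1_low), logit_ref(cells$phi1_high))
  beta <- solve(A, Y)
  rownames(beta) <- c("(Intercept)", "treatment", "covariate", "interaction")
  colnames(beta) <- paste0("q", seq_len(Q - 1))
  beta
}

#' Synthetic-trial data-generating mechanism
#'
#' Specifies a two-arm trial world with `K` correlated binary endpoints and
#' one covariate: conditional success probabilities and pairwise endpoint
#' correlations are stated per arm at two anchor covariate values (0/1 for a
#' binary covariate drawn Bernoulli(0.5); -1/+1 for a standard-normal
#' covariate), converted to joint cell probabilities, and interpolated
#' linearly on the log-odds scale through the multinomial-logistic model with
#' a treatment-covariate interaction. The spec carries its exact ground truth
#' (true coefficients, conditional effects at the anchors, and average
#' effects over the covariate law).
#'
#' @param covariate `"binary"` (Bernoulli(0.5), anchors 0/1) or `"normal"`
#'   (standard normal, anchors -1/+1).
#' @param theta0_low,theta0_high Control-arm success probabilities (length K)
#'   at the low/high anchor.
#' @param theta1_low,theta1_high Treated-arm success probabilities at the
#'   low/high anchor.
#' @param rho Pairwise endpoint correlation (scalar or matrix), applied in
#'   every (arm, anchor) cell.
#' @param weights Optional Compensatory weights recorded with the truth.
#' @return An object of class `bmlr_dgm`: anchors, true coefficient matrix
#'   `beta`, and a `truth` list with conditional and average effects.
#' @export
dgm_spec <- function(covariate = c("binary", "normal"),
                     theta0_low, theta0_high, theta1_low, theta1_high,
                     rho = 0, weights = NULL) {
  covariate <- match.arg(covariate)
  anchors <- if (covariate == "binary") c(0, 1) else c(-1, 1)
  K <- length(theta0_low)
  H <- config_matrix(K)
  cells <- list(phi0_low = phi_from_margins(theta0_low, rho),
                phi0_high = phi_from_margins(theta0_high, rho),
                phi1_low = phi_from_margins(theta1_low, rho),
                phi1_high = phi_from_margins(theta1_high, rho))
  beta <- beta_from_cells(cells, anchors)
  spec <- structure(
    list(covariate = covariate, anchors = anchors, K = K, Q = nrow(H), H = H,
         rho = rho, cells = cells, beta = beta, weights = weights),
    class = "bmlr_dgm")
  spec$truth <- dgm_truth_all(spec)
  spec
}

# True phi(z, T) under a dgm spec
dgm_phi <- function(spec, z, arm) {
  x <- c(1, arm, z, z * arm)
  inverse_mlogit(drop(x %*% spec$beta))
}

# Ground truth: conditional effects at the anchors and average effects over
# the covariate law. Binary covariate: exact 0.5/0.5 mixture in phi-space.
# Normal covariate: deterministic adaptive quadrature of each phi cell over
# the standard-normal density.
dgm_truth_all <- function(spec) {
  cond <- lapply(seq_along(spec$anchors), function(i) {
    a <- spec$anchors[i]
    th0 <- phi_to_theta(dgm_phi(spec, a, 0), spec$H)
    th1 <- phi_to_theta(dgm_phi(spec, a, 1), spec$H)
    list(anchor = a, theta0 = th0, theta1 = th1, delta = th1 - th0)
  })
  names(cond) <- c("low", "high")
  avg_phi <- function(arm) {
    if (spec$covariate == "binary") {
      0.5 * dgm_phi(spec, 0, arm) + 0.5 * dgm_phi(spec, 1, arm)
    } else {
      vapply(seq_len(spec$Q), function(q) {
        stats::integrate(function(z)
          vapply(z, function(zi) dgm_phi(spec, zi, arm)[q], numeric(1)) *
            stats::dnorm(z), -8, 8, rel.tol = 1e-9)$value
      }, numeric(1))
    }
  }
  phi0 <- avg_phi(0); phi1 <- avg_phi(1)
  th0 <- phi_to_theta(phi0 / sum(phi0), spec$H)
  th1 <- phi_to_theta(phi1 / sum(phi1), spec$H)
  ate <- list(theta0 = th0, theta1 = th1, delta = th1 - th0)
  if (!is.null(spec$weights)) {
    ate$delta_w <- sum(spec$weights * ate$delta)
    for (nm in names(cond))
      cond[[nm]]$delta_w <- sum(spec$weights * cond[[nm]]$delta)
  }
  list(conditional = cond, average = ate)
}

#' True effects of a DGM in an arbitrary population
#'
#' Evaluates the generating mechanism's exact treatment effect for a fixed
#' covariate value or a covariate interval (marginalized over the covariate
#' law restricted to the interval, by quadrature or the exact binary
#' mixture).
#'
#' @param spec A [dgm_spec()].
#' @param population A [pop_fixed()], [pop_interval()] or [pop_all()];
#'   fixed-value populations must use covariate name `"z"`.
#' @return A list with `theta0`, `theta1`, `delta`, and `delta_w` when the
#'   spec carries weights.
#' @export
dgm_truth <- function(spec, population = pop_all()) {
  stopifnot(inherits(spec, "bmlr_dgm"))
  if (population$mode == "fixed") {
    z <- population$values[["z"]]
    if (is.null(z)) stop("Fixed population must set covariate `z`.",
                         call. = FALSE)
    phi0 <- dgm_phi(spec, z, 0); phi1 <- dgm_phi(spec, z, 1)
  } else {
    lo <- population$lo; hi <- population$hi
    if (spec$covariate == "binary") {
      vals <- c(0, 1)[c(0, 1) >= lo & c(0, 1) <= hi]
      if (!length(vals)) stop("Empty covariate interval.", call. = FALSE)
      phi0 <- rowMeans(vapply(vals, function(a) dgm_phi(spec, a, 0),
                              numeric(spec$Q)))
      phi1 <- rowMeans(vapply(vals, function(a) dgm_phi(spec, a, 1),
                              numeric(spec$Q)))
    } else {
      lo <- max(lo, -8); hi <- min(hi, 8)
      mass <- stats::pnorm(hi) - stats::pnorm(lo)
      av <- function(arm) vapply(seq_len(spec$Q), function(q)
        stats::integrate(function(z)
          vapply(z, function(zi) dgm_phi(spec, zi, arm)[q], numeric(1)) *
            stats::dnorm(z), lo, hi, rel.tol = 1e-9)$value / mass,
        numeric(1))
      phi0 <- av(0); phi1 <- av(1)
    }
  }
  th0 <- phi_to_theta(phi0 / sum(phi0), spec$H)
  th1 <- phi_to_theta(phi1 / sum(phi1), spec$H)
  out <- list(theta0 = th0, theta1 = th1, delta = th1 - th0)
  if (!is.null(spec$weights)) out$delta_w <- sum(spec$weights * out$delta)
  out
}

#' Effect-size presets for the simulation world
#'
#' Named heterogeneity patterns for two endpoints, stated once as this
#' package's simulation world (the control arm sits at success probabilities
#' (0.5, 0.5) at both anchors):
#' * `ES1`: fully null - no conditional or average effect;
#' * `ES2`: heterogeneous with zero average effect - conditional differences
#'   +(0.2, 0.1) at the low anchor and -(0.2, 0.1) at the high anchor cancel
#'   on the success-probability scale;
#' * `ES3`: heterogeneous positive - conditional differences (0.25, 0.15) at
#'   the low anchor, (0.15, 0.05) at the high anchor (average (0.20, 0.10));
#'   the conditional effect in the low subpopulation exceeds the average;
#' * `ES4`: mirror of ES3 (low (0.15, 0.05), high (0.25, 0.15)); the
#'   conditional effect in the low subpopulation is smaller than the average;
#' * `ES5`: strongly heterogeneous positive - low (0.30, 0.20), high
#'   (0.10, 0.00); the low-anchor conditional effect is large enough that the
#'   post-stratification sample still exceeds its required size.
#'
#' @param es Preset name.
#' @param covariate `"binary"` or `"normal"`.
#' @param rho Pairwise endpoint correlation.
#' @param weights Compensatory weights to record (default `c(0.75, 0.25)`).
#' @return A [dgm_spec()].
#' @export
dgm_preset <- function(es = c("ES1", "ES2", "ES3", "ES4", "ES5"),
                       covariate = c("binary", "normal"), rho = 0,
                       weights = c(0.75, 0.25)) {
  es <- match.arg(es)
  covariate <- match.arg(covariate)
  base <- c(0.5, 0.5)
  d <- switch(es,
    ES1 = list(low = c(0, 0), high = c(0, 0)),
    ES2 = list(low = c(0.2, 0.1), high = c(-0.2, -0.1)),
    ES3 = list(low = c(0.25, 0.15), high = c(0.15, 0.05)),
    ES4 = list(low = c(0.15, 0.05), high = c(0.25, 0.15)),
    ES5 = list(low = c(0.30, 0.20), high = c(0.10, 0.00)))
  eps <- 1e-9  # keep probabilities strictly inside (0, 1)
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  dgm_spec(covariate = covariate,
           theta0_low = base, theta0_high = base,
           theta1_low = clamp(base + d$low),
           theta1_high = clamp(base + d$high),
           rho = rho, weights = weights)
}

#' Generate a synthetic two-arm trial
#'
#' Draws `n_per_arm` subjects per arm: the covariate from its stated law
#' (Bernoulli(0.5) or standard normal), and the joint binary response from
#' the multinomial distribution with probabilities `phi(z, T)` implied by the
#' mechanism's true coefficients. The returned tibble carries the spec (with
#' its ground-truth manifest) as attribute `"dgm"`.
#'
#' @param spec A [dgm_spec()] or [dgm_preset()].
#' @param n_per_arm Subjects per arm.
#' @param seed Optional integer seed.
#' @return A tibble with columns `z` (covariate), `treat` (0/1), and the
#'   outcome columns `y1..yK`.
#' @export
generate_trial <- function(spec, n_per_arm, seed = NULL) {
  stopifnot(inherits(spec, "bmlr_dgm"), n_per_arm >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * as.integer(n_per_arm)
  treat <- rep(c(0L, 1L), each = n_per_arm)
  z <- if (spec$covariate == "binary") stats::rbinom(n, 1, 0.5)
       else stats::rnorm(n)
  # category probabilities per subject via the true coefficients
  X <- cbind(1, treat, z, z * treat)
  psi <- X %*% spec$beta
  phi <- inverse_mlogit(psi)
  u <- stats::runif(n)
  cum <- t(apply(phi, 1, cumsum))
  # category = 1 + number of leading cumulative cells strictly below u
  cat_idx <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
  Y <- decode_categories(pmin(cat_idx, spec$Q), spec$H)
  out <- tibble::tibble(z = z, treat = treat)
  for (k in seq_len(spec$K)) out[[paste0("y", k)]] <- as.integer(Y[, k])
  attr(out, "dgm") <- spec
  out
}
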