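#' Transformation chain: coefficients to probabilities to differences
#'
#' The multinomial logistic coefficients have no direct interpretation; the
#' framework transforms every retained posterior draw through three stations:
#' linear predictors to joint response probabilities (`inverse_mlogit()`),
#' joint to endpoint success probabilities (`phi_to_theta()`), and per-arm
#' success probabilities to treatment differences (`theta_to_delta()`,
#' optionally weighted by `weighted_delta()`). Transforms are applied per
#' draw, never to posterior summaries, so the result is the posterior of the
#' transform.
#'
#' @param psi A length-(Q-1) numeric vector of linear predictors for one
#'   profile, or an `L x (Q-1)` matrix of draws (the reference category's
#'   predictor is implicitly 0).
#' @return `inverse_mlogit()` returns joint response probabilities on the
#'   Q-simplex, as a vector of length Q or an `L x Q` matrix.
#' @examples
#' inverse_mlogit(c(log(2), 0, 0))  # (0.4, 0.2, 0.2, 0.2)
#' @export
inverse_mlogit <- function(psi) {
  vec <- is.null(dim(psi))
  psi <- rbind(if (vec) matrix(psi, 1) else as.matrix(psi))
  if (!all(is.finite(psi)))
    stop("Non-finite linear predictor.", call. = FALSE)
  full <- cbind(psi, 0)  # reference category
  m <- apply(full, 1, max)
  e <- exp(full - m)
  phi <- e / rowSums(e)
  if (vec) phi[1, ] else phi
}

#' @rdname inverse_mlogit
#' @param phi Joint response probabilities: vector of length Q or `L x Q`
#'   matrix of draws, ordered as the rows of `H`.
#' @param H Configuration matrix from [config_matrix()].
#' @return `phi_to_theta()` returns endpoint success probabilities
#'   (length K, or `L x K`): `theta_k` is the sum of `phi` over the
#'   configurations with success on endpoint `k`. Correlation between
#'   endpoints stays encoded in `phi`; no independence is introduced.
#' @export
phi_to_theta <- function(phi, H) {
  vec <- is.null(dim(phi))
  phi <- rbind(if (vec) matrix(phi, 1) else as.matrix(phi))
  if (ncol(phi) != nrow(H))
    stop("`phi` must have Q = ", nrow(H), " elements.", call. = FALSE)
  bad <- abs(rowSums(phi) - 1) > 1e-8 | phi < -1e-12
  if (any(bad))
    stop("`phi` is off the probability simplex (row ",
         which(bad)[1], ").", call. = FALSE)
  theta <- phi %*% H  # theta_k = sum over selection set U_k
  colnames(theta) <- paste0("theta", seq_len(ncol(H)))
  if (vec) theta[1, ] else theta
}

#' @rdname inverse_mlogit
#' @param theta1,theta0 Success probabilities for the experimental (T = 1) and
#'   control (T = 0) arm: vectors of length K or `L x K` matrices of draws.
#' @return `theta_to_delta()` returns the elementwise difference
#'   `theta1 - theta0`, each element in `[-1, 1]`.
#' @export
theta_to_delta <- function(theta1, theta0) {
  if (length(theta1) != length(theta0) ||
      !identical(dim(theta1), dim(theta0)))
    stop("`theta1` and `theta0` must have matching dimensions.", call. = FALSE)
  d <- theta1 - theta0
  if (!is.null(dim(d))) colnames(d) <- sub("^theta", "delta", colnames(d))
  d
}

#' @rdname inverse_mlogit
#' @param delta Treatment differences: vector of length K or `L x K` matrix.
#' @param w Importance weights: length K, each in `[0, 1]`, summing to 1.
#' @return `weighted_delta()` returns the scalar (or length-L vector of)
#'   weighted differences `sum_k w_k delta_k`, the Compensatory-rule effect.
#' @export
weighted_delta <- function(delta, w) {
  K <- if (is.null(dim(delta))) length(delta) else ncol(delta)
  check_weights(w, K)
  if (is.null(dim(delta))) sum(w * delta) else drop(delta %*% w)
}

check_weights <- function(w, K) {
  if (length(w) != K)
    stop("Weights must have length K = ", K, ".", call. = FALSE)
  if (any(w < 0 | w > 1) || abs(sum(w) - 1) > 1e-9)
    stop("Weights must lie in [0, 1] and sum to 1.", call. = FALSE)
  invisible(w)
}

# psi_q = beta_q . x for one profile; beta is (P+1) x (Q-1), x has intercept
linear_predictor <- function(beta, x) {
  if (length(x) != nrow(beta))
    stop("Profile length ", length(x), " does not match ", nrow(beta),
         " coefficients.", call. = FALSE)
  drop(crossprod(beta, x))
}
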