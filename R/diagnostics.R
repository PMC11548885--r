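#' Gelman-Rubin convergence diagnostics
#'
#' Potential scale reduction factors comparing within- and between-chain
#' variability of the retained coefficient draws: the univariate PSRF per
#' parameter and the multivariate (Brooks-Gelman) statistic based on the
#' largest eigenvalue of `W^-1 B / L`. Values near 1 indicate convergence;
#' the conventional tolerance in this framework is 1.10.
#'
#' @param fit A [fit_bmlr()] result with at least two chains.
#' @return A list with `mpsrf` (scalar multivariate PSRF) and `psrf` (a
#'   tibble with one row per coefficient).
#' @export
gelman_rubin <- function(fit) {
  stopifnot(inherits(fit, "bmlr_fit"))
  m <- length(fit$draws)
  if (m < 2)
    stop("Gelman-Rubin diagnostics need at least 2 chains.", call. = FALSE)
  chains <- lapply(fit$draws, function(cube) {
    L <- dim(cube)[3]
    t(matrix(cube, nrow = prod(dim(cube)[1:2]), ncol = L))
  })
  L <- nrow(chains[[1]])
  d <- ncol(chains[[1]])
  means <- t(vapply(chains, colMeans, numeric(d)))
  W <- Reduce(`+`, lapply(chains, stats::cov)) / m
  Bn <- stats::cov(means)  # = B / L
  # univariate: sigma2_plus = (L-1)/L W + B/L ; Vhat adds B/(mL)
  wd <- diag(W); bd <- diag(as.matrix(Bn))
  vhat <- (L - 1) / L * wd + (1 + 1 / m) * bd
  psrf <- sqrt(vhat / wd)
  # multivariate: (L-1)/L + (m+1)/m * lambda_max(W^-1 B/L)
  lambda <- tryCatch(
    max(Re(eigen(solve(W, Bn), only.values = TRUE)$values)),
    error = function(e) NA_real_)
  mpsrf <- sqrt((L - 1) / L + (m + 1) / m * lambda)
  nm <- as.vector(outer(dimnames(fit$draws[[1]])[[1]],
                        dimnames(fit$draws[[1]])[[2]], paste, sep = "|"))
  list(mpsrf = mpsrf,
       psrf = tibble::tibble(parameter = nm, psrf = psrf))
}
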