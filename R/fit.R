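#' Polya-Gamma PG(1, z) random draws
#'
#' Exact draws from the Polya-Gamma distribution PG(1, z) via the
#' alternating-series rejection sampler (no truncation approximation). Uses
#' R's RNG stream, so results are reproducible under [set.seed()].
#'
#' @param n Number of draws.
#' @param z Tilt parameter(s); recycled to length `n`. `E[PG(1, z)] =
#'   tanh(z/2) / (2 z)` (`1/4` at `z = 0`), and the law is even in `z`.
#' @return Numeric vector of positive draws.
#' @export
rpg <- function(n, z = 0) {
  if (any(!is.finite(z))) stop("`z` must be finite.", call. = FALSE)
  rpg_cpp(as.integer(n), as.numeric(z))
}

#' Multivariate normal prior for the regression coefficients
#'
#' One independent multivariate normal prior per non-reference response
#' category. The default (mean 0, variance 10 per coefficient, zero prior
#' covariances) is diffuse on the log-odds scale while keeping the implied
#' probabilities in a realistic range.
#'
#' @param mean Prior mean: scalar, length-(P+1) vector, or `(P+1) x (Q-1)`
#'   matrix (one column per category).
#' @param variance Prior variance: scalar, length-(P+1) vector (diagonal), or
#'   `(P+1) x (P+1)` covariance matrix shared across categories.
#' @return An object of class `bmlr_prior`.
#' @export
bmlr_prior <- function(mean = 0, variance = 10) {
  structure(list(mean = mean, variance = variance), class = "bmlr_prior")
}

# Expand a bmlr_prior to explicit b0 (p x Qm1) and B0inv (p x p x Qm1)
expand_prior <- function(prior, p, Qm1) {
  b0 <- prior$mean
  if (length(b0) == 1) b0 <- matrix(b0, p, Qm1)
  else if (is.null(dim(b0))) b0 <- matrix(rep(b0, Qm1), p, Qm1)
  if (!identical(dim(b0), c(p, Qm1)))
    stop("Prior mean has wrong dimensions.", call. = FALSE)
  V <- prior$variance
  if (length(V) == 1) V <- diag(V, p)
  else if (is.null(dim(V))) {
    if (length(V) != p) stop("Prior variance vector must have length P + 1.",
                             call. = FALSE)
    V <- diag(V, p)
  }
  if (!isSymmetric(unname(V)) || any(eigen(V, symmetric = TRUE,
                                           only.values = TRUE)$values <= 0))
    stop("Prior covariance must be symmetric positive definite.",
         call. = FALSE)
  Vinv <- solve(V)
  B0inv <- array(Vinv, dim = c(p, p, Qm1))
  list(b0 = b0, B0inv = B0inv)
}

#' Fit the Bayesian multivariate logistic regression model
#'
#' Posterior sampling of multinomial logistic regression coefficients over the
#' `Q = 2^K` joint configurations of `K` binary endpoints, via Gibbs sampling
#' with a Polya-Gamma expansion. Each sweep updates categories `q = 1..Q-1` in
#' turn: the competing-category offset `C_iq = log sum_{r != q} exp(psi_ir)`
#' (with the reference predictor fixed at 0) is recomputed from the current
#' state, latent `omega_iq ~ PG(1, psi_iq - C_iq)` is drawn, and `beta_q` is
#' updated from its conditionally conjugate multivariate normal with precision
#' `X' Omega X + B0^-1`. The all-failure configuration is the reference
#' category with coefficients fixed at zero.
#'
#' @param data Data frame with one row per subject: `K` binary outcome
#'   columns, a 0/1 treatment column, and optional covariates.
#' @param outcomes Character vector of outcome column names; order defines
#'   endpoints `k = 1..K`.
#' @param treatment Name of the 0/1 treatment indicator column.
#' @param covariates Character vector of covariate column names.
#' @param interactions Interaction pairs, as in [build_design()]; the default
#'   interacts the treatment with every covariate.
#' @param prior A [bmlr_prior()].
#' @param chains,iter,burnin,thin MCMC settings: number of chains, retained
#'   iterations per chain (before thinning), burn-in iterations discarded, and
#'   thinning interval. Defaults mirror a production run (2 chains, 10,000
#'   retained, 1,000 burn-in); simulation studies typically scale these down.
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @param init `"zero"` starts all chains at `beta = 0`; `"prior"` draws
#'   overdispersed starting values from the prior.
#' @return An object of class `bmlr_fit` with elements `draws` (a list, one
#'   `(P+1) x (Q-1) x L` array per chain), `design`, `H`, `outcomes`, and the
#'   sampler settings. Methods: [tidy()], [glance()], [gelman_rubin()],
#'   [treatment_effects()].
#' @export
fit_bmlr <- function(data, outcomes, treatment, covariates = character(),
                     interactions = NULL, prior = bmlr_prior(),
                     chains = 2, iter = 10000, burnin = 1000, thin = 1,
                     seed = NULL, init = c("zero", "prior")) {
  init <- match.arg(init)
  data <- as.data.frame(data)
  if (!all(outcomes %in% names(data)))
    stop("Outcome column(s) not found: ",
         paste(setdiff(outcomes, names(data)), collapse = ", "),
         call. = FALSE)
  stopifnot(chains >= 1, iter >= 1, burnin >= 0, thin >= 1)
  K <- length(outcomes)
  H <- config_matrix(K)
  Q <- nrow(H)
  design <- build_design(data, treatment, covariates, interactions)
  X <- design$X
  p <- ncol(X)
  if (nrow(X) < p + 1)
    stop("Need at least P + 2 = ", p + 1, " subjects.", call. = FALSE)
  cat_idx <- encode_responses(data[, outcomes, drop = FALSE], H)
  pr <- expand_prior(prior, p, Q - 1L)
  if (!is.null(seed)) set.seed(seed)

  keep <- iter
  draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    beta0 <- if (init == "zero") {
      matrix(0, p, Q - 1L)
    } else {
      sds <- sqrt(diag(solve(pr$B0inv[, , 1])))
      matrix(stats::rnorm(p * (Q - 1L), as.vector(pr$b0), sds), p, Q - 1L)
    }
    cube <- gibbs_mlr_cpp(X, as.integer(cat_idx), Q, pr$b0, pr$B0inv,
                          as.integer(keep), as.integer(burnin), beta0)
    if (thin > 1) cube <- cube[, , seq(1, keep, by = thin), drop = FALSE]
    dimnames(cube) <- list(colnames(X), paste0("q", seq_len(Q - 1L)), NULL)
    draws[[ch]] <- cube
  }
  structure(
    list(draws = draws, design = design, H = H, outcomes = outcomes,
         prior = prior,
         settings = list(chains = chains, iter = iter, burnin = burnin,
                         thin = thin, seed = seed, init = init),
         n = nrow(X), K = K, Q = Q),
    class = "bmlr_fit")
}

#' Fit a Bayesian univariate logistic regression (single endpoint)
#'
#' The binary-outcome special case (`K = 1`, `Q = 2`) of [fit_bmlr()]: a
#' Polya-Gamma Gibbs sampler for ordinary Bayesian logistic regression.
#'
#' @inheritParams fit_bmlr
#' @param outcome Name of the single binary outcome column.
#' @return A `bmlr_fit` with `K = 1`.
#' @export
fit_ulr <- function(data, outcome, treatment, covariates = character(),
                    interactions = NULL, prior = bmlr_prior(),
                    chains = 2, iter = 10000, burnin = 1000, thin = 1,
                    seed = NULL, init = c("zero", "prior")) {
  fit_bmlr(data, outcomes = outcome, treatment = treatment,
           covariates = covariates, interactions = interactions,
           prior = prior, chains = chains, iter = iter, burnin = burnin,
           thin = thin, seed = seed, init = init)
}

# Stack retained draws of a fit into an L_total x (p * (Q-1)) matrix
# (chains concatenated), with stable column names "term|category".
draws_matrix <- function(fit) {
  mats <- lapply(fit$draws, function(cube) {
    L <- dim(cube)[3]
    t(matrix(cube, nrow = prod(dim(cube)[1:2]), ncol = L))
  })
  out <- do.call(rbind, mats)
  nm <- as.vector(outer(dimnames(fit$draws[[1]])[[1]],
                        dimnames(fit$draws[[1]])[[2]], paste, sep = "|"))
  colnames(out) <- nm
  out
}

#' Export posterior draws
#'
#' `draws_long()` returns the retained coefficient draws in long format (one
#' row per chain, iteration, category and term); `export_draws()` writes
#' them to CSV and/or a self-describing JSON bundle that also records the
#' configuration matrix, outcome names, prior and sampler settings.
#'
#' @param fit A [fit_bmlr()] result.
#' @return A tibble with columns `chain`, `iter`, `category`, `term`,
#'   `value`.
#' @export
draws_long <- function(fit) {
  stopifnot(inherits(fit, "bmlr_fit"))
  p <- dim(fit$draws[[1]])[1]; Qm1 <- dim(fit$draws[[1]])[2]
  terms <- dimnames(fit$draws[[1]])[[1]]
  dplyr::bind_rows(lapply(seq_along(fit$draws), function(ch) {
    cube <- fit$draws[[ch]]
    L <- dim(cube)[3]
    tibble::tibble(
      chain = ch,
      iter = rep(seq_len(L), each = p * Qm1),
      category = rep(rep(seq_len(Qm1), each = p), L),
      term = rep(terms, Qm1 * L),
      value = as.vector(cube))
  }))
}

#' @rdname draws_long
#' @param csv,json Optional output paths; `NULL` skips that format.
#' @export
export_draws <- function(fit, csv = NULL, json = NULL) {
  if (!is.null(csv))
    utils::write.csv(draws_long(fit), csv, row.names = FALSE)
  if (!is.null(json)) {
    bundle <- list(
      outcomes = fit$outcomes, H = fit$H, terms = fit$design$roles,
      prior = unclass(fit$prior), settings = fit$settings,
      draws = lapply(fit$draws, function(cube) {
        dimnames(cube) <- NULL
        cube  # chain-wise (P+1) x (Q-1) x L arrays, column-major
      }))
    jsonlite::write_json(bundle, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}

#' @export
print.bmlr_fit <- function(x, ...) {
  cat("<bmlr_fit> Bayesian multivariate logistic regression\n")
  cat("  endpoints:", x$K, " (", paste(x$outcomes, collapse = ", "), ")\n",
      sep = "")
  cat("  response categories:", x$Q, "(reference: all failures)\n")
  cat("  subjects:", x$n, "  terms:", ncol(x$design$X), "\n")
  cat("  chains:", x$settings$chains, " retained draws/chain:",
      dim(x$draws[[1]])[3], "\n")
  invisible(x)
}
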