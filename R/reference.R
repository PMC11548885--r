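#' Stratified multivariate Bernoulli-Dirichlet analysis (mB)
#'
#' The unconditional reference analysis: within the (sub)population of
#' interest, joint response configuration counts per arm are combined with a
#' diffuse Dirichlet prior (`alpha0 = 0.01`, close to the Haldane prior but
#' proper, so that empty cells remain sampleable), and treatment-specific
#' joint response probabilities are drawn directly from the posterior
#' Dirichlet distribution. Conditional effects are obtained by stratification:
#' only the rows in the subpopulation enter, so - unlike the regression
#' approach - the effective sample shrinks with the subpopulation.
#'
#' Fixed-value populations select rows whose covariate equals the fixed value
#' exactly (sensible for discrete covariates; stratification on a continuous
#' covariate needs an interval).
#'
#' @param data Trial data frame.
#' @param outcomes Character vector of outcome column names (order defines
#'   the endpoints).
#' @param treatment Name of the 0/1 treatment column.
#' @param population A [pop_fixed()], [pop_interval()] or [pop_all()].
#' @param alpha0 Dirichlet prior hyperparameter (scalar or length Q).
#' @param ndraws Posterior draws per arm.
#' @param weights Optional Compensatory weights (adds `delta_w` draws).
#' @param seed Optional seed.
#' @return A `bmlr_effects` object (method `"mB"`).
#' @export
fit_mb <- function(data, outcomes, treatment, population = pop_all(),
                   alpha0 = 0.01, ndraws = 2000, weights = NULL,
                   seed = NULL) {
  data <- as.data.frame(data)
  K <- length(outcomes)
  H <- config_matrix(K)
  Q <- nrow(H)
  if (!is.null(seed)) set.seed(seed)
  sel <- if (population$mode == "fixed") {
    v <- population$values
    Reduce(`&`, lapply(names(v), function(nm) {
      if (is.null(data[[nm]]))
        stop("Covariate `", nm, "` not found in data.", call. = FALSE)
      data[[nm]] == v[[nm]]
    }))
  } else pop_select(population, data)
  sub <- data[sel, , drop = FALSE]
  tr <- sub[[treatment]]
  if (nrow(sub) == 0 || !any(tr == 0) || !any(tr == 1))
    stop("Empty stratum: population ", pop_label(population),
         " has no observations in one of the arms.", call. = FALSE)
  cat_idx <- encode_responses(sub[, outcomes, drop = FALSE], H)
  a0 <- if (length(alpha0) == 1) rep(alpha0, Q) else alpha0
  stopifnot(length(a0) == Q, all(a0 > 0))
  draw_arm <- function(arm) {
    counts <- tabulate(cat_idx[tr == arm], nbins = Q)
    conc <- a0 + counts
    g <- matrix(stats::rgamma(ndraws * Q, shape = rep(conc, each = ndraws)),
                ndraws, Q)
    g / rowSums(g)
  }
  phi0 <- draw_arm(0)
  phi1 <- draw_arm(1)
  eff <- effects_from_phi(phi0, phi1, H, weights, population = population,
                          n_marginalized = nrow(sub), method = "mB")
  eff
}

#' Univariate logistic regression suite (uLR)
#'
#' The per-endpoint reference analysis: an independent Bayesian univariate
#' logistic regression (Polya-Gamma Gibbs) per outcome, using the full sample
#' and the same linear predictor as the multivariate model. Per-endpoint
#' difference draws are paired by draw index to form joint difference draws
#' for the multivariate decision rules - encoding the independence assumption
#' between endpoints that this comparator is designed to expose.
#'
#' @inheritParams fit_bmlr
#' @param population Population passed to [treatment_effects()] per endpoint.
#' @param data_marg Data for marginal populations (defaults to `data`).
#' @param weights Optional Compensatory weights.
#' @return A `bmlr_effects` object (method `"uLR"`) whose per-arm `phi`
#'   slots are `NULL`: the joint distribution over configurations is not
#'   identified without the correlation, only the endpoint margins.
#' @export
fit_ulr_suite <- function(data, outcomes, treatment,
                          covariates = character(), interactions = NULL,
                          population = pop_all(), data_marg = data,
                          prior = bmlr_prior(), chains = 1, iter = 2000,
                          burnin = 500, weights = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(outcomes)
  effs <- lapply(outcomes, function(oc) {
    f <- fit_ulr(data, oc, treatment, covariates, interactions,
                 prior = prior, chains = chains, iter = iter,
                 burnin = burnin)
    treatment_effects(f, population, data = data_marg)
  })
  theta0 <- do.call(cbind, lapply(effs, function(e) e$theta0[, 1]))
  theta1 <- do.call(cbind, lapply(effs, function(e) e$theta1[, 1]))
  colnames(theta0) <- colnames(theta1) <- paste0("theta", seq_len(K))
  delta <- theta_to_delta(theta1, theta0)
  structure(
    list(phi0 = NULL, phi1 = NULL, theta0 = theta0, theta1 = theta1,
         delta = delta,
         delta_w = if (!is.null(weights)) weighted_delta(delta, weights),
         weights = weights, H = config_matrix(K), population = population,
         n_marginalized = effs[[1]]$n_marginalized, method = "uLR"),
    class = "bmlr_effects")
}
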