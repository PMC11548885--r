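#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior coefficient summaries
#'
#' @param x A [fit_bmlr()] result.
#' @param conf_level Central posterior interval level.
#' @param ... Unused.
#' @return A tibble with one row per (category, term): posterior mean, SD,
#'   quantile interval bounds, and the per-parameter PSRF when the fit has
#'   two or more chains.
#' @export
tidy.bmlr_fit <- function(x, conf_level = 0.95, ...) {
  dm <- draws_matrix(x)
  a <- (1 - conf_level) / 2
  qs <- apply(dm, 2, stats::quantile, probs = c(a, 1 - a))
  out <- tibble::tibble(
    parameter = colnames(dm),
    term = sub("\\|q\\d+$", "", colnames(dm)),
    category = as.integer(sub("^.*\\|q", "", colnames(dm))),
    estimate = colMeans(dm),
    std_error = apply(dm, 2, stats::sd),
    conf_low = qs[1, ], conf_high = qs[2, ])
  if (length(x$draws) >= 2)
    out$psrf <- gelman_rubin(x)$psrf$psrf
  out
}

#' Model-level summary of a fit
#'
#' @param x A [fit_bmlr()] result.
#' @param ... Unused.
#' @return A one-row tibble: subjects, endpoints, categories, terms, chains,
#'   retained draws, and the multivariate PSRF (`NA` for a single chain).
#' @export
glance.bmlr_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, K = x$K, Q = x$Q, terms = ncol(x$design$X),
    chains = x$settings$chains,
    draws = length(x$draws) * dim(x$draws[[1]])[3],
    mpsrf = if (length(x$draws) >= 2) gelman_rubin(x)$mpsrf else NA_real_)
}

#' Tidy posterior effect summaries
#'
#' @param x A [treatment_effects()] / [fit_mb()] / [fit_ulr_suite()] result.
#' @param conf_level Central posterior interval level.
#' @param ... Unused.
#' @return A tibble with one row per quantity: per-arm success probabilities
#'   `theta0_k`, `theta1_k`, differences `delta_k`, and the weighted
#'   difference `delta_w` when weights were supplied, each with posterior
#'   mean, SD, interval bounds, and the posterior probability of a positive
#'   value.
#' @export
tidy.bmlr_effects <- function(x, conf_level = 0.95, ...) {
  a <- (1 - conf_level) / 2
  K <- ncol(x$delta)
  mats <- list()
  for (k in seq_len(K)) {
    mats[[paste0("theta0_", k)]] <- x$theta0[, k]
    mats[[paste0("theta1_", k)]] <- x$theta1[, k]
    mats[[paste0("delta_", k)]] <- x$delta[, k]
  }
  if (!is.null(x$delta_w)) mats$delta_w <- x$delta_w
  tibble::tibble(
    quantity = names(mats),
    estimate = vapply(mats, mean, numeric(1)),
    std_error = vapply(mats, stats::sd, numeric(1)),
    conf_low = vapply(mats, stats::quantile, numeric(1), probs = a),
    conf_high = vapply(mats, stats::quantile, numeric(1), probs = 1 - a),
    prob_positive = vapply(mats, function(v) mean(v > 0), numeric(1)))
}

#' @rdname tidy.bmlr_effects
#' @export
glance.bmlr_effects <- function(x, ...) {
  tibble::tibble(population = pop_label(x$population), method = x$method,
                 draws = nrow(x$delta), endpoints = ncol(x$delta),
                 n_marginalized = x$n_marginalized)
}
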