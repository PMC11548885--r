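#' Deterministic per-repetition seed
#'
#' Seeds for repetition studies are derived from a master seed so that any
#' repetition can be reproduced in isolation:
#' `seed = (master * 1009 + scenario * 101 + rep) mod (2^31 - 1) + 1`.
#'
#' @param master Master seed (integer).
#' @param scenario Scenario index (integer, default 1).
#' @param rep Repetition index.
#' @return An integer seed in `1..2^31 - 1`.
#' @export
rep_seed <- function(master, scenario = 1, rep = 1) {
  as.integer((as.double(master) %% 1e6 * 1009 +
                as.double(scenario) * 101 + as.double(rep)) %% 2147483646) + 1L
}

#' Repetition study of operating characteristics
#'
#' Runs the full generate / fit / transform / decide pipeline `reps` times
#' under one data-generating mechanism, for one or more analysis methods
#' (`"mLR"` multivariate logistic regression, `"mB"` stratified Dirichlet,
#' `"uLR"` univariate logistic suite), populations, and decision rules, and
#' collects per-repetition decisions and posterior-mean effects. Repetition
#' seeds derive deterministically from `master_seed` via [rep_seed()].
#' Individual repetition failures are caught and recorded; the run errors
#' only if more than 1% of repetitions fail.
#'
#' @param spec A [dgm_spec()] / [dgm_preset()].
#' @param n_per_arm Subjects per arm per repetition.
#' @param reps Number of repetitions.
#' @param methods Subset of `c("mLR", "mB", "uLR")`.
#' @param rules List of [decision_rule()] objects.
#' @param populations Named list of population specifications.
#' @param mcmc List of MCMC settings for the regression methods: `iter`,
#'   `burnin`, `chains` (chains > 1 adds the multivariate PSRF per fit).
#' @param ndraws_mb Posterior draws for the Dirichlet reference.
#' @param master_seed,scenario Seed derivation inputs.
#' @return An object of class `bmlr_sim`: a list with the per-repetition
#'   tibble `results`, the spec, populations and rules. Summarize with
#'   [operating_characteristics()].
#' @export
simulate_study <- function(spec, n_per_arm, reps,
                           methods = "mB",
                           rules = list(decision_rule("any"),
                                        decision_rule("compensatory",
                                                      weights = c(0.75, 0.25))),
                           populations = list(ATE = pop_all()),
                           mcmc = list(iter = 2000, burnin = 500, chains = 1),
                           ndraws_mb = 2000,
                           master_seed = 1, scenario = 1) {
  stopifnot(inherits(spec, "bmlr_dgm"), all(methods %in% c("mLR", "mB", "uLR")))
  outcomes <- paste0("y", seq_len(spec$K))
  if (is.null(names(populations)))
    names(populations) <- vapply(populations, pop_label, character(1))
  rows <- vector("list", reps)
  failures <- 0L
  for (r in seq_len(reps)) {
    res <- tryCatch(
      run_one_rep(spec, n_per_arm, outcomes, methods, rules, populations,
                  mcmc, ndraws_mb,
                  seed = rep_seed(master_seed, scenario, r)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      next
    }
    res$rep <- r
    rows[[r]] <- res
  }
  if (failures > max(1, 0.01 * reps))
    stop(failures, " of ", reps, " repetitions failed.", call. = FALSE)
  results <- dplyr::bind_rows(rows)
  structure(list(results = results, spec = spec, populations = populations,
                 rules = rules, reps = reps, failures = failures,
                 n_per_arm = n_per_arm, master_seed = master_seed),
            class = "bmlr_sim")
}

run_one_rep <- function(spec, n_per_arm, outcomes, methods, rules,
                        populations, mcmc, ndraws_mb, seed) {
  dat <- generate_trial(spec, n_per_arm, seed = seed)
  out <- list()
  fit <- NULL
  mpsrf <- NA_real_
  if ("mLR" %in% methods) {
    fit <- fit_bmlr(dat, outcomes, "treat", covariates = "z",
                    chains = mcmc$chains, iter = mcmc$iter,
                    burnin = mcmc$burnin)
    if (mcmc$chains >= 2) mpsrf <- gelman_rubin(fit)$mpsrf
  }
  for (pn in names(populations)) {
    pop <- populations[[pn]]
    effs <- list()
    if ("mLR" %in% methods)
      effs$mLR <- treatment_effects(fit, pop, data = dat,
                                    weights = spec$weights)
    if ("mB" %in% methods)
      effs$mB <- fit_mb(dat, outcomes, "treat", pop, ndraws = ndraws_mb,
                        weights = spec$weights)
    if ("uLR" %in% methods)
      effs$uLR <- fit_ulr_suite(dat, outcomes, "treat", covariates = "z",
                                population = pop, iter = mcmc$iter,
                                burnin = mcmc$burnin, weights = spec$weights)
    for (m in names(effs)) {
      e <- effs[[m]]
      dbar <- colMeans(e$delta)
      base <- tibble::tibble(
        method = m, population = pn,
        mpsrf = if (m == "mLR") mpsrf else NA_real_,
        delta_w_hat = if (!is.null(e$delta_w)) mean(e$delta_w) else NA_real_)
      for (k in seq_along(dbar)) base[[paste0("delta", k, "_hat")]] <- dbar[k]
      dec <- dplyr::bind_rows(lapply(rules, function(rl) decide(e, rl)))
      out[[length(out) + 1L]] <-
        dplyr::bind_cols(base[rep(1, nrow(dec)), ],
                         dec[, c("rule", "side", "alpha", "p_cut",
                                 "p_superior", "p_inferior", "conclusion")])
    }
  }
  dplyr::bind_rows(out)
}

#' Summarize a repetition study
#'
#' Aggregates a [simulate_study()] result into operating characteristics per
#' (method, population, rule): the proportion of superiority (and
#' inferiority) conclusions with its binomial Monte-Carlo standard error, the
#' mean bias of the posterior-mean differences against the mechanism's ground
#' truth, and the mean multivariate PSRF where available.
#'
#' @param sim A `bmlr_sim` object.
#' @return A tibble with one row per (method, population, rule).
#' @export
operating_characteristics <- function(sim) {
  stopifnot(inherits(sim, "bmlr_sim"))
  truths <- lapply(sim$populations, function(pop) dgm_truth(sim$spec, pop))
  res <- sim$results
  K <- sim$spec$K
  res |>
    dplyr::group_by(.data$method, .data$population, .data$rule) |>
    dplyr::summarise(
      reps = dplyr::n(),
      prop_superior = mean(.data$conclusion == "superior"),
      mc_se = sqrt(prop_superior * (1 - prop_superior) / reps),
      prop_inferior = mean(.data$conclusion %in%
                             c("inferior", "superior+inferior")),
      dplyr::across(dplyr::all_of(paste0("delta", seq_len(K), "_hat")), mean),
      delta_w_hat = mean(.data$delta_w_hat),
      mean_mpsrf = mean(.data$mpsrf),
      .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(
      bias_max = {
        tr <- truths[[.data$population]]
        est <- c(dplyr::c_across(dplyr::all_of(
          paste0("delta", seq_len(K), "_hat"))),
          if (!is.na(.data$delta_w_hat)) .data$delta_w_hat)
        tru <- c(tr$delta, if (!is.null(tr$delta_w)) tr$delta_w)
        max(abs(est - tru))
      }) |>
    dplyr::ungroup()
}

#' Single-trial end-to-end analysis
#'
#' Fits the multivariate logistic model, checks convergence, evaluates
#' treatment effects for each requested population, and applies each decision
#' rule: the complete workflow for one dataset.
#'
#' @inheritParams fit_bmlr
#' @param populations Named list of population specifications.
#' @param rules List of [decision_rule()] objects.
#' @param weights Compensatory weights used for effect summaries.
#' @param psrf_warn Warn when the multivariate PSRF exceeds this value.
#' @return A list of class `bmlr_analysis`: the fit, the diagnostics, a
#'   tibble of per-population effect summaries, and a tibble of decisions.
#' @export
analyze_trial <- function(data, outcomes, treatment,
                          covariates = character(), interactions = NULL,
                          populations = list(ATE = pop_all()),
                          rules = list(decision_rule("any"),
                                       decision_rule("all")),
                          weights = NULL, prior = bmlr_prior(),
                          chains = 2, iter = 10000, burnin = 1000,
                          seed = NULL, psrf_warn = 1.10) {
  fit <- fit_bmlr(data, outcomes, treatment, covariates, interactions,
                  prior = prior, chains = chains, iter = iter,
                  burnin = burnin, seed = seed)
  diag <- if (chains >= 2) gelman_rubin(fit) else NULL
  if (!is.null(diag) && is.finite(diag$mpsrf) && diag$mpsrf > psrf_warn)
    warning("Multivariate PSRF ", round(diag$mpsrf, 3), " exceeds ",
            psrf_warn, ": chains may not have converged.", call. = FALSE)
  if (is.null(names(populations)))
    names(populations) <- vapply(populations, pop_label, character(1))
  effects <- lapply(populations, function(pop)
    treatment_effects(fit, pop, data = data, weights = weights))
  summaries <- dplyr::bind_rows(lapply(names(effects), function(nm)
    dplyr::mutate(generics::tidy(effects[[nm]]), population = nm,
                  .before = 1)))
  decisions <- dplyr::bind_rows(lapply(names(effects), function(nm)
    dplyr::mutate(
      dplyr::bind_rows(lapply(rules, function(rl) decide(effects[[nm]], rl))),
      population = nm)))
  structure(list(fit = fit, diagnostics = diag, effects = effects,
                 summaries = summaries, decisions = decisions),
            class = "bmlr_analysis")
}

#' @export
print.bmlr_analysis <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$diagnostics))
    cat("  multivariate PSRF:", round(x$diagnostics$mpsrf, 4), "\n")
  cat("\nEffect summaries:\n"); print(x$summaries, n = Inf)
  cat("\nDecisions:\n")
  print(x$decisions[, c("population", "rule", "side", "p_cut", "p_superior",
                        "p_inferior", "conclusion")], n = Inf)
  invisible(x)
}
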