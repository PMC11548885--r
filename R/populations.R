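#' Specify a (sub)population of interest
#'
#' Treatment effects are evaluated for a population described either by fixed
#' covariate values (e.g. a patient with `z = -1`) or by empirical
#' marginalization over the observed covariate rows falling in an interval
#' (e.g. all subjects with `z` between one standard deviation below the mean
#' and the mean), or over the whole trial population (the average treatment
#' effect).
#'
#' @param values Named list/vector of fixed covariate values (`pop_fixed`).
#' @param covariate Covariate name (`pop_interval`).
#' @param lo,hi Interval endpoints, `-Inf`/`Inf` allowed.
#' @param closed Length-2 logical: whether the lower/upper endpoint is
#'   included (default closed on both ends).
#' @return An object of class `bmlr_population`.
#' @export
pop_fixed <- function(values) {
  values <- as.list(values)
  if (is.null(names(values)) || any(names(values) == ""))
    stop("Fixed covariate values must be named.", call. = FALSE)
  structure(list(mode = "fixed", values = values), class = "bmlr_population")
}

#' @rdname pop_fixed
#' @export
pop_interval <- function(covariate, lo = -Inf, hi = Inf,
                         closed = c(TRUE, TRUE)) {
  if (!(lo < hi)) stop("Need lo < hi.", call. = FALSE)
  structure(list(mode = "marginal", covariate = covariate,
                 lo = lo, hi = hi, closed = closed),
            class = "bmlr_population")
}

#' @rdname pop_fixed
#' @export
pop_all <- function() {
  structure(list(mode = "marginal", covariate = NULL, lo = -Inf, hi = Inf,
                 closed = c(TRUE, TRUE)), class = "bmlr_population")
}

pop_label <- function(pop) {
  if (pop$mode == "fixed") {
    paste0("fixed: ", paste(names(pop$values), unlist(pop$values),
                            sep = "=", collapse = ", "))
  } else if (is.null(pop$covariate)) {
    "trial population (ATE)"
  } else {
    paste0(pop$covariate, " in ",
           if (pop$closed[1]) "[" else "(", pop$lo, ", ", pop$hi,
           if (pop$closed[2]) "]" else ")")
  }
}

# logical selector of data rows matching a marginal population
pop_select <- function(pop, data) {
  if (is.null(pop$covariate)) return(rep(TRUE, nrow(data)))
  z <- data[[pop$covariate]]
  if (is.null(z))
    stop("Covariate `", pop$covariate, "` not found in data.", call. = FALSE)
  lo_ok <- if (pop$closed[1]) z >= pop$lo else z > pop$lo
  hi_ok <- if (pop$closed[2]) z <= pop$hi else z < pop$hi
  lo_ok & hi_ok
}

#' Posterior treatment-effect draws for a population
#'
#' Transforms every retained posterior draw to the population-level effect
#' scale. For a fixed-value population, counterfactual profiles with the
#' treatment forced to 0 and 1 (interactions recomputed) are evaluated per
#' draw through the multinomial logistic link. For a marginal population, the
#' per-subject joint response probabilities of every selected subject (from
#' both arms; randomization justifies pooling) are computed per draw per arm
#' and averaged within arm before the downstream transforms, i.e. empirical
#' marginalization over the observed covariate rows. The posterior sample
#' itself is always fit on all subjects; only covariate rows are subset.
#'
#' @param fit A [fit_bmlr()] result.
#' @param population A [pop_fixed()], [pop_interval()] or [pop_all()]
#'   specification.
#' @param data Data frame with the covariate rows to marginalize over
#'   (required for marginal populations; typically the trial data the model
#'   was fit on).
#' @param weights Optional Compensatory-rule weights; if supplied, the
#'   weighted difference draws `delta_w` are included.
#' @return An object of class `bmlr_effects`: per-arm joint response
#'   probability draws (`phi0`, `phi1`, `L x Q`), success probability draws
#'   (`theta0`, `theta1`, `L x K`), difference draws (`delta`, `L x K`, and
#'   optionally `delta_w`), plus the population descriptor.
#' @export
treatment_effects <- function(fit, population = pop_all(), data = NULL,
                              weights = NULL) {
  stopifnot(inherits(fit, "bmlr_fit"), inherits(population, "bmlr_population"))
  dm <- draws_matrix(fit)     # L x (p * (Q-1)), category-major blocks
  p <- nrow(fit$draws[[1]]); Qm1 <- fit$Q - 1L
  L <- nrow(dm)

  phi_for_profile <- function(x) {
    # psi draws for one profile: L x (Q-1)
    psi <- sapply(seq_len(Qm1), function(q)
      dm[, (q - 1L) * p + seq_len(p), drop = FALSE] %*% x)
    inverse_mlogit(matrix(psi, L, Qm1))
  }

  if (population$mode == "fixed") {
    vals <- population$values
    unknown <- setdiff(names(vals), fit$design$covariates)
    if (length(unknown))
      stop("Unknown covariate(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    phi0 <- phi_for_profile(profile_row(fit$design, vals, 0))
    phi1 <- phi_for_profile(profile_row(fit$design, vals, 1))
    n_marg <- NA_integer_
  } else {
    if (is.null(data))
      stop("Marginal populations need `data` to marginalize over.",
           call. = FALSE)
    sel <- pop_select(population, data)
    if (!any(sel))
      stop("Empty subpopulation: no subject satisfies ",
           pop_label(population), ".", call. = FALSE)
    sub <- as.data.frame(data)[sel, , drop = FALSE]
    n_marg <- nrow(sub)
    X0 <- profile_matrix(fit$design, sub, 0)
    X1 <- profile_matrix(fit$design, sub, 1)
    phi0 <- marginal_phi(dm, X0, p, Qm1)
    phi1 <- marginal_phi(dm, X1, p, Qm1)
  }

  effects_from_phi(phi0, phi1, fit$H, weights,
                   population = population, n_marginalized = n_marg,
                   method = if (fit$K == 1) "uLR" else "mLR")
}

# Average per-subject phi over a counterfactual design, per draw.
# dm: L x (p*(Q-1)) draws; X: n x p profiles. Returns L x Q.
# Vectorized over subjects and draws: softmax over the category slices of
# n x L matrices, stabilized by the rowwise max (reference predictor 0).
marginal_phi <- function(dm, X, p, Qm1) {
  # collapse duplicate profiles (e.g. a binary covariate) to a weighted mean
  key <- apply(X, 1, paste, collapse = "\r")
  if (anyDuplicated(key)) {
    tab <- table(key)
    w <- as.numeric(tab) / nrow(X)
    X <- X[match(names(tab), key), , drop = FALSE]
  } else {
    w <- rep(1 / nrow(X), nrow(X))
  }
  L <- nrow(dm); n <- nrow(X)
  psi <- vector("list", Qm1)
  for (q in seq_len(Qm1))
    psi[[q]] <- X %*% t(dm[, (q - 1L) * p + seq_len(p), drop = FALSE])
  m <- matrix(0, n, L)
  for (q in seq_len(Qm1)) m <- pmax(m, psi[[q]])
  denom <- exp(-m)
  for (q in seq_len(Qm1)) {
    psi[[q]] <- exp(psi[[q]] - m)
    denom <- denom + psi[[q]]
  }
  out <- matrix(0, L, Qm1 + 1L)
  for (q in seq_len(Qm1)) out[, q] <- crossprod(psi[[q]] / denom, w)
  out[, Qm1 + 1L] <- crossprod(exp(-m) / denom, w)
  out
}

# Assemble a bmlr_effects object from per-arm phi draws.
effects_from_phi <- function(phi0, phi1, H, weights = NULL,
                             population = pop_all(), n_marginalized = NA,
                             method = "mLR") {
  theta0 <- rbind(phi_to_theta(phi0, H))
  theta1 <- rbind(phi_to_theta(phi1, H))
  delta <- theta_to_delta(theta1, theta0)
  delta_w <- if (!is.null(weights)) weighted_delta(delta, weights)
  structure(
    list(phi0 = phi0, phi1 = phi1, theta0 = theta0, theta1 = theta1,
         delta = delta, delta_w = delta_w, weights = weights, H = H,
         population = population, n_marginalized = n_marginalized,
         method = method),
    class = "bmlr_effects")
}

#' @export
print.bmlr_effects <- function(x, ...) {
  cat("<bmlr_effects> posterior treatment-effect draws (", x$method, ")\n",
      sep = "")
  cat("  population:", pop_label(x$population), "\n")
  if (!is.na(x$n_marginalized))
    cat("  marginalized over", x$n_marginalized, "covariate rows\n")
  cat("  draws:", nrow(x$delta), " endpoints:", ncol(x$delta), "\n")
  print(generics::tidy(x))
  invisible(x)
}
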