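#' Decision rule specification
#'
#' Superiority/inferiority rules for K binary endpoints:
#' * **any**: superior when at least one endpoint difference exceeds zero
#'   (inferior when at least one falls below zero; the regions may overlap);
#' * **all**: superior when every endpoint difference exceeds zero (mutually
#'   exclusive with inferiority);
#' * **compensatory**: superior when the importance-weighted difference
#'   `sum_k w_k delta_k` exceeds zero, letting benefits on one endpoint
#'   offset harms on another.
#'
#' Region boundaries are strict: a draw with a difference exactly zero belongs
#' to no rejection region.
#'
#' The posterior decision threshold `p_cut` is derived from the rule, the
#' sidedness and the error rate: one-sided tests use `1 - alpha`
#' (All/Compensatory) or the multiplicity-corrected `1 - alpha/K` (Any);
#' two-sided tests use `1 - alpha/2` and `1 - alpha/(2K)`.
#'
#' For failure-coded outcomes (where a lower probability is better) use
#' `side = "left"`: the favorable direction is then a difference *smaller*
#' than zero, without recoding the data.
#'
#' @param rule One of `"any"`, `"all"`, `"compensatory"`.
#' @param weights Compensatory-rule importance weights (length K, in `[0,1]`,
#'   summing to 1). Required for the compensatory rule.
#' @param side `"right"` (default; superiority means differences above zero),
#'   `"left"`, or `"two_sided"`.
#' @param alpha Targeted decision error rate, in (0, 0.5).
#' @return An object of class `bmlr_rule`.
#' @export
decision_rule <- function(rule = c("any", "all", "compensatory"),
                          weights = NULL,
                          side = c("right", "left", "two_sided"),
                          alpha = 0.05) {
  rule <- match.arg(rule)
  side <- match.arg(side)
  if (rule == "compensatory" && is.null(weights))
    stop("The compensatory rule needs `weights`.", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 0.5)
    stop("`alpha` must lie in (0, 0.5).", call. = FALSE)
  structure(list(rule = rule, weights = weights, side = side, alpha = alpha),
            class = "bmlr_rule")
}

#' Posterior decision threshold
#'
#' @param rule Rule name (`"any"`, `"all"`, `"compensatory"`).
#' @param side `"right"`, `"left"` or `"two_sided"`.
#' @param alpha Error rate in (0, 0.5).
#' @param K Number of endpoints (used for the Any rule's multiplicity
#'   correction).
#' @return The threshold `p_cut` in (0.5, 1).
#' @examples
#' make_threshold("any", "right", 0.05, K = 2)        # 0.975
#' make_threshold("compensatory", "two_sided", 0.05, 2) # 0.975
#' @export
make_threshold <- function(rule, side, alpha, K) {
  if (alpha <= 0 || alpha >= 0.5) stop("`alpha` must lie in (0, 0.5).",
                                       call. = FALSE)
  a <- if (side == "two_sided") alpha / 2 else alpha
  if (rule == "any") a <- a / K
  1 - a
}

#' Rejection-region membership of difference draws
#'
#' Evaluates, per posterior draw of the treatment difference, whether the draw
#' lies in the superiority and/or inferiority region of the rule (with the
#' favorable direction flipped for `side = "left"`).
#'
#' @param delta `L x K` matrix (or length-K vector) of difference draws.
#' @param rule A [decision_rule()].
#' @return A list of two logical vectors, `sup` and `inf`.
#' @export
region_membership <- function(delta, rule) {
  stopifnot(inherits(rule, "bmlr_rule"))
  delta <- rbind(delta)
  if (rule$side == "left") delta <- -delta
  out <- if (rule$rule == "compensatory") {
    dw <- weighted_delta(delta, rule$weights)
    list(sup = dw > 0, inf = dw < 0)
  } else if (rule$rule == "any") {
    list(sup = apply(delta, 1, max) > 0, inf = apply(delta, 1, min) < 0)
  } else {
    list(sup = apply(delta, 1, min) > 0, inf = apply(delta, 1, max) < 0)
  }
  lapply(out, unname)
}

#' Posterior probability of the joint rejection regions
#'
#' The Monte-Carlo proportion of difference draws lying in a rule's
#' superiority and inferiority regions as sets (union over endpoints for
#' Any, intersection for All, half-space of the weighted difference for
#' Compensatory). This is the region-probability summary; [decide()]
#' thresholds per-endpoint probabilities instead (see its details for why).
#'
#' @param effects A `bmlr_effects` object.
#' @param rule A [decision_rule()].
#' @return A named numeric vector with elements `sup` and `inf`.
#' @export
region_prob <- function(effects, rule) {
  stopifnot(inherits(effects, "bmlr_effects"))
  memb <- region_membership(effects$delta, rule)
  c(sup = mean(memb$sup), inf = mean(memb$inf))
}

#' Posterior rejection probabilities and decision
#'
#' Computes the Monte-Carlo posterior rejection probabilities of a rule and
#' compares them with its threshold `p_cut` (strictly): superiority is
#' concluded when the superiority probability exceeds `p_cut`, inferiority
#' when the inferiority probability does, and the result is inconclusive
#' otherwise. One-sided tests only ever conclude in their own direction.
#'
#' The Compensatory rule tests the scalar weighted difference directly:
#' its probabilities are `P(delta_w > 0 | y)` and `P(delta_w < 0 | y)`. The
#' Any and All rules are evaluated per endpoint, as their thresholds
#' presume: with `P_k = P(delta_k > 0 | y)`, the Any rule's superiority
#' probability is `max_k P_k` (compared against the multiplicity-corrected
#' `1 - alpha/K`) and the All rule's is `min_k P_k` (against `1 - alpha`).
#' This per-endpoint evaluation — rather than the posterior probability of
#' the union/intersection region itself — is what keeps the Type I error at
#' the nominal level and matches the multivariate-normal sample-size
#' approximations: the posterior probability of the union region exceeds
#' every per-endpoint probability, so thresholding it at `1 - alpha/K`
#' would more than double the Type I error (see the package vignette).
#' Per-draw region queries remain available via [region_membership()].
#'
#' Under the Any rule a two-sided test can in principle trigger in both
#' directions; both probabilities are reported and a double trigger is
#' flagged rather than suppressed.
#'
#' @param effects A [treatment_effects()] result (or any `bmlr_effects`).
#' @param rule A [decision_rule()].
#' @return A one-row tibble (class `bmlr_decision`): rule, side, alpha,
#'   `p_cut`, the rejection probabilities, the number of draws and the
#'   conclusion.
#' @export
decide <- function(effects, rule) {
  stopifnot(inherits(effects, "bmlr_effects"), inherits(rule, "bmlr_rule"))
  K <- ncol(effects$delta)
  if (rule$rule == "compensatory") check_weights(rule$weights, K)
  delta <- effects$delta
  if (rule$side == "left") delta <- -delta
  L <- nrow(delta)
  if (rule$rule == "compensatory") {
    dw <- weighted_delta(delta, rule$weights)
    p_sup <- mean(dw > 0)
    p_inf <- mean(dw < 0)
  } else {
    pk_sup <- colMeans(delta > 0)
    pk_inf <- colMeans(delta < 0)
    if (rule$rule == "any") {
      p_sup <- max(pk_sup); p_inf <- max(pk_inf)
    } else {
      p_sup <- min(pk_sup); p_inf <- min(pk_inf)
    }
  }
  p_cut <- make_threshold(rule$rule, rule$side, rule$alpha, K)
  sup_hit <- p_sup > p_cut
  inf_hit <- p_inf > p_cut
  if (rule$side == "right") inf_hit <- FALSE
  if (rule$side == "left") inf_hit <- FALSE  # 'sup' already holds the favorable side
  conclusion <- if (sup_hit && inf_hit) "superior+inferior"
  else if (sup_hit) "superior"
  else if (inf_hit) "inferior"
  else "inconclusive"
  rule_name <- rule$rule; rule_side <- rule$side; rule_alpha <- rule$alpha
  out <- tibble::tibble(
    rule = rule_name, side = rule_side, alpha = rule_alpha,
    p_cut = p_cut, p_superior = unname(p_sup), p_inferior = unname(p_inf),
    draws = L,
    conclusion = conclusion, population = pop_label(effects$population),
    method = effects$method)
  class(out) <- c("bmlr_decision", class(out))
  out
}
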