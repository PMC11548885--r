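#' Plot posterior treatment-difference densities
#'
#' Density of the posterior draws of each endpoint difference (and the
#' weighted difference when present), with a reference line at zero: the
#' decision rules act on the mass either side of that line.
#'
#' @param object A `bmlr_effects` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bmlr_effects <- function(object, ...) {
  K <- ncol(object$delta)
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object$delta, .name_repair = "minimal"),
    cols = dplyr::everything(), names_to = "endpoint", values_to = "delta")
  if (!is.null(object$delta_w))
    df <- dplyr::bind_rows(df, tibble::tibble(endpoint = "weighted",
                                              delta = object$delta_w))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~endpoint, scales = "free_y") +
    ggplot2::labs(x = "treatment difference (success-probability scale)",
                  y = "posterior density",
                  title = pop_label(object$population)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Treatment differences across the covariate range
#'
#' Evaluates fixed-value conditional effects on a grid of covariate values
#' and plots the posterior mean and central credible band per endpoint - the
#' effect-versus-covariate profile that makes observable heterogeneity (sign
#' reversals, widening tails) visible.
#'
#' @param fit A [fit_bmlr()] result with a single covariate.
#' @param covariate Covariate name.
#' @param at Numeric grid of covariate values.
#' @param conf_level Credible band level.
#' @return A ggplot object.
#' @export
plot_effect_profile <- function(fit, covariate, at, conf_level = 0.95) {
  a <- (1 - conf_level) / 2
  rows <- purrr::map_dfr(at, function(v) {
    vals <- stats::setNames(list(v), covariate)
    e <- treatment_effects(fit, pop_fixed(vals))
    K <- ncol(e$delta)
    tibble::tibble(
      value = v, endpoint = paste0("delta_", seq_len(K)),
      estimate = colMeans(e$delta),
      lo = apply(e$delta, 2, stats::quantile, probs = a),
      hi = apply(e$delta, 2, stats::quantile, probs = 1 - a))
  })
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$value, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~endpoint) +
    ggplot2::labs(x = covariate, y = "treatment difference") +
    ggplot2::theme_minimal()
}
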