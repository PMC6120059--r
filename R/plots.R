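# Figure-style outputs: the capacity-pair scatter with equality and
# regression lines, and posterior densities of the hierarchical population
# parameters. ggplot2 is suggested, not imported.

#' Scatter plot of the two capacity estimates
#'
#' One point per subject, the dashed identity line the discrete-resource
#' model predicts, and the least-squares regression line with a +/- 1 SE
#' band.
#'
#' @param pairs Data frame with `k_pm`, `k_sd` (and optionally `study` for
#'   facetting).
#' @return A ggplot object.
#' @export
plot_capacity_pairs <- function(pairs) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_capacity_pairs() needs ggplot2", call. = FALSE)
  }
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$k_sd, y = .data$k_pm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         level = 0.683, colour = "red", fill = "red",
                         alpha = 0.2, linewidth = 0.6) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::labs(x = expression(K[SD]~"(items)"),
                  y = expression(K[Pm]~"(items)")) +
    ggplot2::theme_minimal()
  if ("study" %in% names(pairs)) {
    p <- p + ggplot2::facet_wrap(~study)
  }
  p
}

#' Posterior densities of the hierarchical population parameters
#'
#' @param fit A `hier_fit` from [fit_hierarchical()].
#' @param params Which monitored parameters to show.
#' @return A ggplot object.
#' @export
plot_posterior <- function(fit, params = c("kbar_sd", "kbar_pm",
                                           "sigma_k_sd", "sigma_k_pm",
                                           "rho")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_posterior() needs ggplot2", call. = FALSE)
  }
  draws <- as.data.frame(fit$draws[, params, drop = FALSE])
  long <- data.frame(
    param = factor(rep(params, each = nrow(draws)), levels = params),
    value = unlist(draws, use.names = FALSE))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.5) +
    ggplot2::facet_wrap(~param, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density") +
    ggplot2::theme_minimal()
}
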