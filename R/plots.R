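#' QQ plot of interaction-test p-values
#'
#' Observed versus expected `-log10` p-values ([qq_points()]) with the
#' identity line. Under a well-calibrated null the points follow the
#' diagonal; an early departure indicates miscalibration and an upper-tail
#' departure signal.
#'
#' @param p P-values, or a tibble already produced by [qq_points()].
#' @param min_neg_log10 Truncation passed to [qq_points()].
#' @return A ggplot object.
#' @export
plot_qq <- function(p, min_neg_log10 = 0) {
  pts <- if (is.data.frame(p)) p else qq_points(p, min_neg_log10)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](italic(p))),
      y = expression(Observed ~ -log[10](italic(p)))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulation report
#'
#' Power reports are drawn as rejection-rate curves against the interaction
#' odds ratio `lambda3`, one colour per test, with Monte-Carlo error bars;
#' type-I reports (null model) are drawn as rates per sample size against
#' the nominal level.
#'
#' @param object A `hapint_sim_report` tibble from [estimate_power()] or
#'   [estimate_type1_error()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hapint_sim_report
#' @export
autoplot.hapint_sim_report <- function(object, ...) {
  if (all(object$model == "nullxnull")) {
    return(
      ggplot2::ggplot(object,
                      ggplot2::aes(x = factor(.data$n), y = .data$rate)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::geom_errorbar(
          ggplot2::aes(ymin = .data$rate - .data$mc_se,
                       ymax = .data$rate + .data$mc_se), width = 0.2) +
        ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                            linetype = 2, colour = "red") +
        ggplot2::facet_wrap(~alpha, scales = "free_y") +
        ggplot2::labs(x = "Individuals per group",
                      y = "Empirical type I error") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda3, y = .data$rate,
                                       colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(.data$rate - .data$mc_se, 0),
                   ymax = pmin(.data$rate + .data$mc_se, 1))) +
    ggplot2::labs(x = expression(Interaction ~ odds ~ ratio ~ lambda[3]),
                  y = "Power", colour = "Test") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
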