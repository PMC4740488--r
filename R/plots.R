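#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a strategy comparison on the cost-effectiveness plane
#'
#' Shows the incremental (QALY, cost) point of the MRI-based strategy
#' against the no-treatment reference, with the willingness-to-pay line
#' through the origin.
#'
#' @param object a `wus_cea` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.wus_cea <- function(object, ...) {
  df <- tibble::tibble(delta_qalys = object$delta_qalys,
                       delta_cost = object$delta_cost)
  lim_q <- max(abs(df$delta_qalys), 1e-3) * 1.5
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_qalys, .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = object$wtp, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_point(size = 3, colour = "#2166ac") +
    ggplot2::coord_cartesian(xlim = c(-lim_q, lim_q)) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (2013 USD)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("dashed line: $%s/QALY",
                                     format(object$wtp, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' Plot the cost-effectiveness acceptability curves
#'
#' One curve per strategy: the fraction of PSA draws in which that strategy
#' has the higher net monetary benefit at each willingness-to-pay value.
#'
#' @param object a `wus_psa` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.wus_psa <- function(object, ...) {
  ggplot2::ggplot(object$ceac,
                  ggplot2::aes(.data$wtp, .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay ($/QALY)",
                  y = "Probability cost-effective",
                  colour = NULL,
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' Plot a tornado diagram of one-way sensitivity results
#'
#' Horizontal bars from the ICER at the low endpoint to the ICER at the
#' high endpoint of each parameter, ordered by spread; the vertical line
#' marks the base-case ICER. Parameters whose endpoints produced dominance
#' (no finite ICER) are dropped from the plot.
#'
#' @param object a `wus_tornado` tibble.
#' @param top keep the `top` largest spreads.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.wus_tornado <- function(object, top = 15, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$spread), ]
  df <- utils::head(df[order(-df$spread), ], top)
  df$path <- factor(df$path, levels = rev(df$path))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$path)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       yend = .data$path),
                          linewidth = 4, colour = "#2166ac", alpha = 0.8) +
    ggplot2::geom_vline(xintercept = attr(object, "icer_base"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER ($/QALY)", y = NULL,
                  title = "One-way sensitivity (tornado)") +
    ggplot2::theme_minimal()
}

#' Plot the two-way sensitivity/specificity optimal-strategy map
#'
#' @param object a `wus_twoway` tibble.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.wus_twoway <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$specificity, .data$sensitivity,
                               fill = .data$optimal)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(mri_based = "#2166ac",
                                          no_treatment = "#b2182b")) +
    ggplot2::labs(x = "MRI specificity", y = "MRI sensitivity", fill = NULL,
                  title = "Optimal strategy by MRI accuracy") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
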