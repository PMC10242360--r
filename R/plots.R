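#' Cost-effectiveness plane scatter
#'
#' Bootstrap replicates of (incremental effect, incremental cost); the
#' north-east quadrant holds replicates where the treated strategy is
#' costlier and more effective.
#'
#' @param boot a [bootstrap_cea()] result.
#' @param measure effect measure on the x axis (`"ly"` or `"qaly"`).
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(boot, measure = c("ly", "qaly")) {
  measure <- match.arg(measure)
  df <- data.frame(de = boot$replicates[[paste0("d_", measure)]],
                   dc = boot$replicates$d_cost)
  xlab <- if (measure == "ly") "Incremental life-years" else
    "Incremental QALYs"
  ggplot2::ggplot(df, ggplot2::aes(x = de, y = dc)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8, colour = "steelblue4") +
    ggplot2::labs(x = xlab, y = "Incremental cost (CAD)",
                  title = sprintf("Cost-effectiveness plane (%d replicates)",
                                  boot$B)) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param cc a [ceac()] data frame.
#' @return a ggplot object.
#' @export
plot_ceac <- function(cc) {
  measure <- attr(cc, "measure")
  ggplot2::ggplot(cc, ggplot2::aes(x = wtp, y = prob)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = sprintf("Willingness to pay (CAD per %s)",
                              toupper(measure)),
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Drug price-reduction sensitivity plot
#'
#' @param pr a [price_reduction_curve()] data frame.
#' @return a ggplot object.
#' @export
plot_price_curve <- function(pr) {
  measure <- attr(pr, "measure")
  ggplot2::ggplot(pr, ggplot2::aes(x = 100 * fraction, y = icer)) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Price reduction (%)",
                  y = sprintf("ICER (CAD per %s)", toupper(measure)),
                  title = "ICER vs drug price reduction") +
    ggplot2::theme_minimal()
}
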