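#' Plot a theta cross-validation scan
#'
#' Mean validation and training scores (left axis) with the per-fold
#' validation curves, and the ensemble preservation (right axis, rescaled)
#' against theta on a log axis. The horizontal reference at 0.5 marks "no
#' change": validation minima below it indicate a refinement that also
#' improves held-out observables.
#'
#' @param scan a [ThetaScan-class].
#' @return a ggplot object.
#' @export
plotThetaScan <- function(scan) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    ureInputError("the 'ggplot2' package is required for plotting")
  df <- diagnostics(scan)
  agg <- data.frame(theta = scan@thetaGrid, meanVal = scan@meanVal,
                    meanTrain = scan@meanTrain, ep = scan@epCurve)
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = theta)) +
    ggplot2::geom_line(data = df,
                       ggplot2::aes(y = valScore,
                                    group = fold),
                       color = "firebrick", linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = meanVal,
                                    color = "validation"), linewidth = 1) +
    ggplot2::geom_line(ggplot2::aes(y = meanTrain,
                                    color = "training"), linewidth = 1) +
    ggplot2::geom_line(ggplot2::aes(y = ep / 100,
                                    color = "ensemble preservation"),
                       linewidth = 1) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_continuous(
      name = "score",
      sec.axis = ggplot2::sec_axis(~ . * 100,
                                   name = "ensemble preservation [%]")) +
    ggplot2::scale_color_manual(values = c(validation = "firebrick",
                                           training = "grey40",
                                           `ensemble preservation` = "steelblue")) +
    ggplot2::labs(x = expression(theta), color = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(thetaRecommended(scan)))
    p <- p + ggplot2::geom_vline(xintercept = thetaRecommended(scan),
                                 linetype = "dotted")
  p
}
utils::globalVariables(c("theta", "valScore", "fold", "meanVal", "meanTrain", "ep"))
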