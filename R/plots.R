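# ggplot2 figures for evaluation and batch-prediction results.

#' Plot predicted pKa histograms per amino acid
#'
#' Faceted histograms of predicted pKa values with the solution reference
#' marked, annotated with the per-type mode, mean and count -- the standard
#' way to inspect a proteome-scale batch prediction.
#'
#' @inheritParams summarize_predictions
#' @return A ggplot object.
#' @export
plot_pka_histograms <- function(predictions, bin_width = 0.1,
                                solution = solution_pka()) {
  smry <- summarize_predictions(predictions, bin_width, solution)
  labs <- mutate(smry, label = sprintf("Sol: %.2f\nMode: %.2f\nMean: %.2f\nN: %d",
                                       .data$sol, .data$mode, .data$mean, .data$n))
  ggplot2::ggplot(predictions, ggplot2::aes(x = .data$pka)) +
    ggplot2::geom_histogram(binwidth = bin_width, fill = "grey35") +
    ggplot2::geom_vline(data = smry, ggplot2::aes(xintercept = .data$sol),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = Inf, y = Inf, label = .data$label),
                       hjust = 1.05, vjust = 1.1, size = 2.8) +
    ggplot2::facet_wrap(~aa, scales = "free") +
    ggplot2::labs(x = "predicted pKa", y = "residues")
}

#' @describeIn plot_pka_histograms Predicted versus experimental pKa for a
#'   hold-out evaluation, coloured by residue type.
#' @param object A seqpka result object.
#' @param ... Unused.
#' @export
autoplot.pka_holdout_eval <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$pka_true, y = .data$pka_pred,
                               colour = .data$aa)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "experimental pKa", y = "predicted pKa",
                  colour = "residue")
}

#' @describeIn plot_pka_histograms Overall RMSE versus layer with a
#'   standard-error ribbon.
#' @export
autoplot.pka_layer_sweep <- function(object, ...) {
  ggplot2::ggplot(object$by_layer, ggplot2::aes(x = .data$layer, y = .data$rmse)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rmse - .data$stderr,
                                      ymax = .data$rmse + .data$stderr),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "transformer layer", y = "hold-out RMSE (pH units)")
}

#' @describeIn plot_pka_histograms RMSE per ablation arm with error bars.
#' @export
autoplot.pka_ablation <- function(object, ...) {
  arms <- mutate(object$arms, arm = factor(.data$arm, levels = .data$arm))
  ggplot2::ggplot(arms, ggplot2::aes(x = .data$arm, y = .data$rmse)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rmse - .data$stderr,
                                        ymax = .data$rmse + .data$stderr),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = "hold-out RMSE (pH units)")
}
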