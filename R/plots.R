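#' ROC curve of diagnostic scores
#'
#' @param scores Tibble from [score_samples()] (`score`, `true_group`).
#' @return A ggplot object; the subtitle reports the AUC.
#' @export
plot_roc <- function(scores) {
  pos <- scores$true_group == "case"
  thr <- sort(unique(scores$score), decreasing = TRUE)
  pts <- purrr::map_dfr(c(Inf, thr, -Inf), function(t) {
    tibble::tibble(fpr = mean(scores$score[!pos] >= t),
                   tpr = mean(scores$score[pos] >= t))
  })
  auc <- roc_auc(scores$score, pos)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False-positive rate", y = "True-positive rate",
                  title = "Diagnostic score ROC",
                  subtitle = sprintf("AUC = %.3f", auc)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of differential statistics
#'
#' @param stats Tibble from [moderated_t_test()].
#' @param p_max,delta_min Thresholds drawn as guide lines.
#' @return A ggplot object.
#' @export
plot_volcano <- function(stats, p_max = 0.05, delta_min = 0.1) {
  stats$status <- dplyr::case_when(
    stats$p_value < p_max & stats$delta >= delta_min ~ "up",
    stats$p_value < p_max & stats$delta <= -delta_min ~ "down",
    TRUE ~ "ns")
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$delta,
                                      y = -log10(.data$p_value),
                                      colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-delta_min, delta_min),
                        linetype = 3) +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = 3) +
    ggplot2::scale_colour_manual(values = c(up = "#d7301f", down = "#0570b0",
                                            ns = "grey70")) +
    ggplot2::labs(x = "Mean difference (case - control)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Histogram of DMR distances to the nearest TSS
#'
#' @param context Tibble from [annotate_dmr_context()].
#' @param binwidth_kb Bin width in kb (default 10).
#' @return A ggplot object.
#' @export
plot_dmr_context <- function(context, binwidth_kb = 10) {
  ggplot2::ggplot(context,
                  ggplot2::aes(x = .data$tss_distance / 1000,
                               fill = .data$region_class)) +
    ggplot2::geom_histogram(binwidth = binwidth_kb, boundary = 0) +
    ggplot2::labs(x = "Distance to nearest TSS (kb)", y = "DMRs",
                  fill = "Region class") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of deconvolved cell proportions
#'
#' @param props Tibble from [deconvolve()].
#' @return A ggplot object.
#' @export
plot_proportions <- function(props) {
  long <- tidyr::pivot_longer(
    dplyr::select(props, -dplyr::any_of(".residual")),
    -"sample_id", names_to = "cell_type", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id,
                                     y = .data$proportion,
                                     fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Estimated proportion", fill = "Cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @param object A `cflmd_model`.
#' @param ... Unused.
#' @describeIn train_nn Training-loss curve.
#' @method autoplot cflmd_model
#' @export
autoplot.cflmd_model <- function(object, ...) {
  d <- tibble::tibble(epoch = seq_along(object$loss_trace),
                      loss = object$loss_trace)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Epoch", y = "Cross-entropy + L2 loss") +
    ggplot2::theme_minimal()
}
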