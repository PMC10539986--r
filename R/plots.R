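#' Plot cross-validation metrics with confidence intervals
#'
#' Point estimates with normal-approximation interval bars for sensitivity,
#' specificity and balanced accuracy, with the chance level marked.
#'
#' @param object An `eeg_cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_cv_result <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$metric, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Proportion", title = object$scheme) +
    ggplot2::theme_minimal()
}

#' Heatmap of permutation feature importance
#'
#' The conventional four-block layout: relative power and entropy features
#' by region, and their asymmetry counterparts by region pair. Values are
#' mean reductions in balanced accuracy, floored at 0 for display (raw
#' values, including negatives, live in the importance tibble).
#'
#' @param object An `eeg_importance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_importance <- function(object, ...) {
  r <- importance_rendering(object)
  r$measure <- factor(r$measure, levels = c("delta", "theta", "alpha",
                                            "beta", "gamma", "mse_fine",
                                            "mse_medium", "mse_coarse"))
  ggplot2::ggplot(r, ggplot2::aes(x = .data$measure, y = .data$location,
                                  fill = 100 * .data$mean_reduction)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(~ .data$block, scales = "free") +
    ggplot2::scale_fill_gradient(low = "#fde0dd", high = "#f6e726",
                                 name = "Reduction in\nbalanced accuracy (%)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a Welch power spectral density
#'
#' @param psd Tibble from [welch_psd()].
#' @param log_power Plot power on a log10 scale?
#' @return A ggplot object.
#' @export
plot_psd <- function(psd, log_power = TRUE) {
  p <- ggplot2::ggplot(psd, ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "PSD (uV²/Hz)") +
    ggplot2::theme_minimal()
  if (log_power) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot multiscale entropy curves
#'
#' @param curve Matrix from [mse_curve()] (channels x scales) or a numeric
#'   vector for a single channel.
#' @return A ggplot object with one line per channel.
#' @export
plot_mse_curve <- function(curve) {
  if (is.null(dim(curve))) curve <- matrix(curve, nrow = 1,
                                           dimnames = list("ch1", NULL))
  colnames(curve) <- paste0("V", seq_len(ncol(curve)))
  if (is.null(rownames(curve)))
    rownames(curve) <- paste0("ch", seq_len(nrow(curve)))
  df <- tibble::as_tibble(curve, rownames = "channel")
  df <- tidyr::pivot_longer(df, -"channel", names_to = "scale",
                            values_to = "entropy")
  df$scale <- as.integer(sub("^V", "", df$scale))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scale, y = .data$entropy,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Timescale (coarse-graining factor)",
                  y = "Sample entropy") +
    ggplot2::theme_minimal()
}
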