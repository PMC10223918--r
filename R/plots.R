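#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the per-frequency canonical correlations of a decision
#'
#' @param object an `ssvep_decision`.
#' @param ... unused.
#' @return A ggplot bar chart of rho by candidate frequency, the chosen
#'   frequency highlighted.
#' @export
autoplot.ssvep_decision <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$freq), y = .data$rho,
                                   fill = .data$chosen)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "#2166AC")) +
    ggplot2::labs(x = "candidate frequency (Hz)",
                  y = "max canonical correlation",
                  title = sprintf("decision: %g Hz", object$freq)) +
    ggplot2::theme_minimal()
}

#' Plot an adaptive-cancellation trace
#'
#' Shows the primary channel d(n), the background estimate y(n) and the
#' cleaned residual e(n) over time.
#'
#' @param object an `rls_trace`.
#' @param fs optional sampling rate; x axis in seconds if given, samples
#'   otherwise.
#' @param ... unused.
#' @return A ggplot with one facet per signal.
#' @export
autoplot.rls_trace <- function(object, fs = NULL, ...) {
  n <- length(object$e)
  x <- if (is.null(fs)) seq_len(n) else (seq_len(n) - 1) / fs
  df <- tibble::tibble(
    t = rep(x, 3L),
    value = c(object$d, object$y, object$e),
    signal = factor(rep(c("d(n) input", "y(n) background estimate",
                          "e(n) cleaned"), each = n),
                    levels = c("d(n) input", "y(n) background estimate",
                               "e(n) cleaned")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1L, scales = "free_y") +
    ggplot2::labs(x = if (is.null(fs)) "sample" else "time (s)",
                  y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Left panel: per-epoch narrowband SNR at the true stimulation frequency
#' before vs after adaptive cancellation. Right panel: confusion counts of
#' predicted vs true target.
#'
#' @param object an `ssvep_eval`.
#' @param ... unused.
#' @return A ggplot (patchwork-free single figure using facets).
#' @export
autoplot.ssvep_eval <- function(object, ...) {
  pe <- object$per_epoch
  if (object$config$rls_enabled) {
    df <- tidyr::pivot_longer(
      pe[, c("snr_before_db", "snr_after_db")],
      cols = dplyr::everything(),
      names_to = "condition", values_to = "snr_db")
    df$condition <- factor(df$condition,
                           levels = c("snr_before_db", "snr_after_db"),
                           labels = c("before RLS", "after RLS"))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$snr_db)) +
      ggplot2::geom_boxplot(outlier.size = 0.5) +
      ggplot2::labs(x = NULL, y = "narrowband SNR at true frequency (dB)",
                    title = sprintf("accuracy %.3f, ITR %.1f bits/min",
                                    object$accuracy,
                                    object$itr_bits_per_min)) +
      ggplot2::theme_minimal()
  } else {
    cm <- dplyr::count(pe, .data$target, .data$pred)
    ggplot2::ggplot(cm, ggplot2::aes(x = factor(.data$target),
                                     y = factor(.data$pred),
                                     fill = .data$n)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "true target", y = "predicted target",
                    title = sprintf("accuracy %.3f", object$accuracy)) +
      ggplot2::theme_minimal()
  }
}
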