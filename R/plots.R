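#' Plot time-domain spectra by group
#'
#' Overlays traces (optionally the per-group mean) against time in
#' milliseconds, coloured by class label.
#'
#' @param spectra A spectra tibble.
#' @param mean_by_group Plot the per-group mean trace instead of individual
#'   traces.
#' @param max_per_group When plotting individual traces, at most this many
#'   per group (keeps the figure readable).
#' @return A ggplot object.
#' @export
plot_spectra <- function(spectra, mean_by_group = FALSE, max_per_group = 3L) {
  assert_spectra(spectra)
  long <- tidyr::unnest(
    mutate(
      spectra[, c("id", "label", "start_time", "sampling_rate", "samples")],
      time_ms = lapply(seq_len(nrow(spectra)), function(i) {
        1e3 * (spectra$start_time[i] +
                 (seq_along(spectra$samples[[i]]) - 1) / spectra$sampling_rate[i])
      })
    ),
    cols = c("samples", "time_ms")
  )
  if (mean_by_group) {
    long <- summarise(
      group_by(long, .data$label, .data$time_ms),
      amplitude = mean(.data$samples), .groups = "drop"
    )
    ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$amplitude,
                                       colour = .data$label)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "Time (ms)", y = "Mean amplitude (a.u.)",
                    colour = "Group")
  } else {
    keep <- unlist(lapply(
      split(unique(long$id), sub("_t.*", "", unique(long$id))),
      head, max_per_group
    ), use.names = FALSE)
    long <- filter(long, .data$id %in% keep)
    ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$samples,
                                       group = .data$id,
                                       colour = .data$label)) +
      ggplot2::geom_line(alpha = 0.7) +
      ggplot2::labs(x = "Time (ms)", y = "Amplitude (a.u.)", colour = "Group")
  }
}

#' Plot the subband energy distribution of a wavelet packet tree
#'
#' @param tree A [wpd_decompose()] result.
#' @return A ggplot bar chart of per-node energy fractions (percent).
#' @export
plot_energy_distribution <- function(tree) {
  dist <- energy_distribution(tree)
  ggplot2::ggplot(dist, ggplot2::aes(.data$node, 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Subband node (depth.index)", y = "Energy (%)")
}

#' @method autoplot mrmr_ranking
#' @export
autoplot.mrmr_ranking <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(stats::reorder(.data$feature, .data$rank), .data$score)
  ) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "Selected coefficient (selection order)",
                  y = "Importance score") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot pa_eval
#' @export
autoplot.pa_eval <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey20", high = "firebrick") +
    ggplot2::labs(
      x = "Predicted class", y = "True class", fill = "Count",
      title = sprintf("%s kernel, accuracy %.1f%%",
                      object$kernel, object$accuracy)
    )
}

#' @method autoplot pa_holdout
#' @export
autoplot.pa_holdout <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$kernel, .data$accuracy,
                               colour = .data$kernel)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "Kernel", y = "Test accuracy (%)")
}
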