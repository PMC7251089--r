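#' Plot a recording with its annotations
#'
#' Waveforms per channel (thinned for display) with annotated events shaded:
#' swallows in red, distractors in grey.
#'
#' @param object A `swallow_recording`.
#' @param channels Channels to show (default all).
#' @param max_points Display thinning: at most this many samples per
#'   channel.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.swallow_recording <- function(object, channels = NULL,
                                       max_points = 20000, ...) {
  channels <- channels %||% colnames(object$channels)
  fs <- object$sampling_rate
  step <- max(1L, n_samples(object) %/% max_points)
  idx <- seq(1L, n_samples(object), by = step)
  df <- purrr::map_dfr(channels, function(ch) {
    tibble(time = (idx - 1) / fs, value = object$channels[idx, ch],
           channel = ch)
  })
  ann <- dplyr::mutate(object$annotations,
                       onset_s = .data$onset / fs,
                       offset_s = .data$offset / fs,
                       swallow = is_swallow_label(.data$label))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value))
  if (nrow(ann) > 0) {
    p <- p + ggplot2::geom_rect(
      data = ann,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf, fill = .data$swallow),
      alpha = 0.25, inherit.aes = FALSE) +
      ggplot2::scale_fill_manual(
        values = c(`TRUE` = "red", `FALSE` = "grey40"),
        labels = c(`TRUE` = "swallow", `FALSE` = "distractor"),
        name = NULL)
  }
  p + ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, title = object$id)
}

#' Plot the training loss trace of a classifier
#'
#' @param object A trained `swallow_mlp`.
#' @param ... Unused.
#' @return A ggplot object (per-epoch mean loss).
#' @export
autoplot.swallow_mlp <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0) abort("Model has no training trace yet.")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$mean_loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean loss",
                  title = "Full-sweep SGD training trace")
}

#' Plot a segmentation mask against reference annotations
#'
#' Detected segments (raw and refined) as horizontal bars over the sample
#' axis, with reference swallows above for comparison.
#'
#' @param object A `segmentation_mask`.
#' @param reference Optional annotation tibble (sample units).
#' @param sampling_rate Hz, for the time axis (default 4000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segmentation_mask <- function(object, reference = NULL,
                                       sampling_rate = 4000, ...) {
  bars <- dplyr::bind_rows(
    mask_segments(object, "raw"),
    if (!is.null(object$raw_segments)) mask_segments(object, "refined"))
  if (!is.null(reference)) {
    if ("label" %in% names(reference)) {
      reference <- reference[is_swallow_label(reference$label), ]
    }
    bars <- dplyr::bind_rows(
      bars,
      tibble(recording_id = object$recording_id, onset = reference$onset,
             offset = reference$offset, source = "reference"))
  }
  bars <- dplyr::mutate(bars, onset_s = .data$onset / sampling_rate,
                        offset_s = .data$offset / sampling_rate)
  ggplot2::ggplot(bars) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$onset_s, xend = .data$offset_s,
                   y = .data$source, yend = .data$source,
                   colour = .data$source),
      linewidth = 4) +
    ggplot2::labs(x = "time (s)", y = NULL, title = object$recording_id) +
    ggplot2::theme(legend.position = "none")
}

#' Plot a parameter-selection grid
#'
#' Accuracy, sensitivity and specificity against window size, one line per
#' channel, faceted by metric (and linetype by overlap mode when both are
#' present).
#'
#' @param results Output of [run_parameter_selection()].
#' @return A ggplot object.
#' @export
plot_selection_grid <- function(results) {
  long <- tidyr::pivot_longer(
    results, c("accuracy", "sensitivity", "specificity"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$size, y = .data$value,
                               colour = .data$channel,
                               linetype = .data$overlap)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(x = "window size (samples)", y = NULL)
}
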