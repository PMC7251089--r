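#' Channel names used for cervical auscultation recordings
#'
#' Canonical order of the four signal lines: the three accelerometer axes
#' (anterior-posterior, superior-inferior, medial-lateral) and the lapel
#' microphone.
#'
#' @export
hrca_channels <- c("AP", "SI", "ML", "MIC")

#' Build an annotation table
#'
#' Annotations are half-open sample intervals `[onset, offset)` with a label.
#' Swallow labels are `"single"`, `"multiple"` or `"sequential"`; distractor
#' (non-swallow) events carry a `"nonswallow:<type>"` label and are ignored
#' when windows are labelled or detections scored.
#'
#' @param onset,offset Integer sample indices, 0-based; `onset` inclusive,
#'   `offset` exclusive.
#' @param label Character labels, recycled to length.
#' @return A tibble with columns `onset`, `offset`, `label`, sorted by onset.
#' @export
segment_tbl <- function(onset = integer(), offset = integer(),
                        label = character()) {
  if (length(onset) != length(offset)) {
    abort("`onset` and `offset` must have equal length.")
  }
  if (length(onset) > 0 && length(label) == 0) label <- "single"
  tbl <- tibble(
    onset = as.numeric(onset),
    offset = as.numeric(offset),
    label = rep_len(as.character(label), length(onset))
  )
  validate_segments(dplyr::arrange(tbl, .data$onset))
}

validate_segments <- function(segments, n_samples = NULL) {
  if (!all(c("onset", "offset", "label") %in% names(segments))) {
    abort("Annotations need columns `onset`, `offset`, `label`.")
  }
  if (nrow(segments) == 0) return(segments)
  if (any(segments$onset < 0) || any(segments$offset <= segments$onset)) {
    abort("Annotations must satisfy 0 <= onset < offset.")
  }
  if (is.unsorted(segments$onset)) {
    segments <- dplyr::arrange(segments, .data$onset)
  }
  if (nrow(segments) > 1 &&
      any(segments$onset[-1] < segments$offset[-nrow(segments)])) {
    abort("Annotations must be pairwise disjoint.")
  }
  if (!is.null(n_samples) && any(segments$offset > n_samples)) {
    abort("Annotation extends past the end of the signal.")
  }
  segments
}

#' Is a segment label a swallow label?
#'
#' @param label Character vector of segment labels.
#' @return Logical vector: `TRUE` unless the label starts with `nonswallow:`.
#' @export
is_swallow_label <- function(label) {
  !startsWith(label, "nonswallow:")
}

#' Construct a multi-channel recording
#'
#' A recording bundles equal-length sample streams for up to four channels
#' (see [hrca_channels]), the sampling rate, and a ground-truth annotation
#' table in sample units.
#'
#' @param id Recording identifier (string).
#' @param channels Numeric matrix (samples x channels) with column names
#'   drawn from [hrca_channels], or a named list of equal-length numeric
#'   vectors.
#' @param sampling_rate Sampling rate in Hz.
#' @param annotations Annotation tibble as built by [segment_tbl()], in
#'   sample indices at `sampling_rate`.
#' @return An object of class `swallow_recording`.
#' @export
new_recording <- function(id, channels, sampling_rate,
                          annotations = segment_tbl()) {
  if (is.list(channels) && !is.data.frame(channels)) {
    lens <- lengths(channels)
    if (length(unique(lens)) > 1) abort("All channels must have equal length.")
    channels <- do.call(cbind, channels)
  }
  channels <- as.matrix(channels)
  if (is.null(colnames(channels))) {
    colnames(channels) <- hrca_channels[seq_len(ncol(channels))]
  }
  if (!all(colnames(channels) %in% hrca_channels)) {
    abort(paste0("Channel names must be among: ",
                 paste(hrca_channels, collapse = ", ")))
  }
  annotations <- validate_segments(annotations, n_samples = nrow(channels))
  structure(
    list(id = as.character(id), channels = channels,
         sampling_rate = sampling_rate, annotations = annotations),
    class = "swallow_recording"
  )
}

#' @export
print.swallow_recording <- function(x, ...) {
  n <- nrow(x$channels)
  cat(sprintf("<swallow_recording> %s\n", x$id))
  cat(sprintf("  %d samples x %d channel(s) [%s] @ %g Hz (%.2f s)\n",
              n, ncol(x$channels),
              paste(colnames(x$channels), collapse = ", "),
              x$sampling_rate, n / x$sampling_rate))
  n_sw <- sum(is_swallow_label(x$annotations$label))
  cat(sprintf("  %d annotation(s): %d swallow, %d distractor\n",
              nrow(x$annotations), n_sw, nrow(x$annotations) - n_sw))
  invisible(x)
}

#' Number of samples per channel of a recording
#' @param recording A `swallow_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(recording) nrow(recording$channels)

#' Extract one channel of a recording
#' @param recording A `swallow_recording`.
#' @param channel Channel name, one of [hrca_channels].
#' @return Numeric sample vector.
#' @export
recording_channel <- function(recording, channel) {
  if (!channel %in% colnames(recording$channels)) {
    abort(sprintf("Recording '%s' has no channel '%s'.",
                  recording$id, channel))
  }
  recording$channels[, channel]
}

#' Annotations of a recording as a tibble
#'
#' @param recording A `swallow_recording`.
#' @param swallows_only Drop `nonswallow:*` distractor annotations?
#' @return Tibble with `recording_id`, `onset`, `offset`, `label`.
#' @export
recording_annotations <- function(recording, swallows_only = FALSE) {
  ann <- dplyr::mutate(recording$annotations, recording_id = recording$id,
                       .before = 1)
  if (swallows_only) ann <- dplyr::filter(ann, is_swallow_label(.data$label))
  ann
}
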