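# Merge sorted intervals that overlap or touch.
merge_segments <- function(segments) {
  if (nrow(segments) <= 1) return(segments)
  segments <- dplyr::arrange(segments, .data$onset)
  onset <- segments$onset; offset <- segments$offset
  keep_on <- onset[1]; keep_off <- offset[1]
  out_on <- numeric(0); out_off <- numeric(0)
  for (i in seq_len(nrow(segments))[-1]) {
    if (onset[i] <= keep_off) {
      keep_off <- max(keep_off, offset[i])
    } else {
      out_on <- c(out_on, keep_on); out_off <- c(out_off, keep_off)
      keep_on <- onset[i]; keep_off <- offset[i]
    }
  }
  tibble(onset = c(out_on, keep_on), offset = c(out_off, keep_off))
}

#' Assemble per-window decisions into a segmentation mask
#'
#' Marks every sample covered by at least one positive window and returns
#' the maximal runs of positive samples as segments. With non-overlapping
#' windows this merges consecutive positive windows into
#' `[first window start, last window end)`.
#'
#' @param decisions Binary vector (0/1, logical, or
#'   `"swallow"`/`"non_swallow"`), one entry per partition window.
#' @param spec The [window_spec()] used to partition.
#' @param signal_length Signal length in samples.
#' @param recording_id Recording the mask belongs to.
#' @return A `segmentation_mask`: list with `recording_id`, `spec`,
#'   `decisions` and `segments` (tibble of disjoint, sorted sample
#'   intervals).
#' @export
assemble_mask <- function(decisions, spec, signal_length,
                          recording_id = "") {
  stopifnot(inherits(spec, "window_spec"))
  if (is.character(decisions) || is.factor(decisions)) {
    decisions <- as.character(decisions) == "swallow"
  }
  decisions <- as.logical(decisions)
  n_expected <- if (signal_length < spec$size) 0L else {
    (signal_length - spec$size) %/% spec$hop + 1L
  }
  if (length(decisions) != n_expected) {
    abort(sprintf("Expected %d window decisions, got %d.",
                  n_expected, length(decisions)))
  }
  starts <- (seq_along(decisions) - 1L) * spec$hop
  pos <- which(decisions)
  segments <- if (length(pos) == 0) {
    tibble(onset = numeric(0), offset = numeric(0))
  } else {
    merge_segments(tibble(onset = starts[pos],
                          offset = starts[pos] + spec$size))
  }
  structure(list(recording_id = recording_id, spec = spec,
                 decisions = decisions, segments = segments),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %s: %d/%d positive windows, %d segment(s)\n",
              x$recording_id, sum(x$decisions), length(x$decisions),
              nrow(x$segments)))
  invisible(x)
}

# AUC of the single frame starting at `start` (0-based) in `x`.
frame_auc <- function(x, start, frame_length, fft_length = 512L) {
  auc_curve(x[(start + 1):(start + frame_length)], frame_length, fft_length)
}

#' Refine segment borders by thresholding the spectral AUC
#'
#' For each detected segment, the area-under-the-spectral-estimate curve
#' (per-frame sum across frequency bins, frame length `N/5`) is thresholded
#' at `min + alpha * (max - min)` of the segment's own AUC values, and each
#' border is walked outward frame by frame while the flanking AUC stays at
#' or above the threshold. The inspection area is limited to 2 windows
#' (`2 N` samples) on each side; segments are never shrunk, and segments
#' that come to touch are merged.
#'
#' @param mask A `segmentation_mask` from [assemble_mask()].
#' @param channel_samples The signal channel the mask was computed on.
#' @param alpha Threshold position between the segment AUC min (0) and max
#'   (1); default 0.5, the midpoint.
#' @param fft_length Transform length used for the AUC (default 512).
#' @return The mask with refined (possibly merged) segments; the original
#'   segments are kept in `$raw_segments`.
#' @export
refine_borders <- function(mask, channel_samples, alpha = 0.5,
                           fft_length = 512L) {
  stopifnot(inherits(mask, "segmentation_mask"))
  segs <- mask$segments
  if (nrow(segs) == 0) {
    mask$raw_segments <- segs
    return(mask)
  }
  N <- mask$spec$size
  fl <- N %/% 5L
  max_ext_frames <- (2L * N) %/% fl  # inspection limited to 2 windows
  L <- length(channel_samples)

  refined <- segs
  for (i in seq_len(nrow(segs))) {
    on <- segs$onset[i]; off <- segs$offset[i]
    auc_in <- auc_curve(channel_samples[(on + 1):off], fl, fft_length)
    if (length(auc_in) == 0) next
    thr <- min(auc_in) + alpha * (max(auc_in) - min(auc_in))
    # walk left
    j <- 0L
    while (j < max_ext_frames && on - (j + 1L) * fl >= 0 &&
           frame_auc(channel_samples, on - (j + 1L) * fl, fl,
                     fft_length) >= thr) {
      j <- j + 1L
    }
    # walk right
    k <- 0L
    while (k < max_ext_frames && off + (k + 1L) * fl <= L &&
           frame_auc(channel_samples, off + k * fl, fl,
                     fft_length) >= thr) {
      k <- k + 1L
    }
    refined$onset[i] <- on - j * fl
    refined$offset[i] <- off + k * fl
  }
  mask$raw_segments <- segs
  mask$segments <- merge_segments(refined)
  mask
}

#' Mask segments as an annotation-style tibble
#'
#' @param mask A `segmentation_mask`.
#' @param source Which segment set to return: `"refined"` (current) or
#'   `"raw"` (pre-refinement, if available).
#' @return Tibble with `recording_id`, `onset`, `offset`, `source`.
#' @export
mask_segments <- function(mask, source = c("refined", "raw")) {
  source <- match.arg(source)
  segs <- if (source == "raw") mask$raw_segments %||% mask$segments else {
    mask$segments
  }
  dplyr::mutate(segs, recording_id = mask$recording_id, source = source,
                .before = 1)
}
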