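# Symmetric Hanning taper of length n.
hanning_taper <- function(n) {
  if (n == 1) return(1)
  0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
}

# Magnitude spectrum of tapered, zero-padded frames (columns), keeping the
# fft_length/2 + 1 non-negative-frequency bins.
frame_magnitudes <- function(frames, fft_length) {
  fl <- nrow(frames)
  tapered <- frames * hanning_taper(fl)
  padded <- rbind(tapered, matrix(0, fft_length - fl, ncol(frames)))
  Mod(stats::mvfft(padded))[seq_len(fft_length / 2 + 1), , drop = FALSE]
}

#' Magnitude spectrogram of one analysis window
#'
#' Splits the window into 5 consecutive non-overlapping frames of `N/5`
#' samples, tapers each with a Hanning window, zero-pads to `fft_length`
#' (512) and keeps the magnitude of the 257 non-negative-frequency bins per
#' frame; phase is discarded. The feature shape (257 x 5) is independent of
#' the window size because the transform length is fixed.
#'
#' @param window_samples Numeric vector whose length is divisible by 5 and
#'   at most `5 * fft_length`.
#' @param fft_length Transform length (default 512).
#' @return A `spectrogram_feature`: list with `magnitude` (257 x 5 matrix,
#'   frequency bins x time frames) and `normalized` flag.
#' @export
spectrogram <- function(window_samples, fft_length = 512L) {
  n <- length(window_samples)
  if (n %% 5 != 0) abort("Window length must be divisible by 5.")
  fl <- n %/% 5L
  if (fl > fft_length) abort("Frame length exceeds the transform length.")
  frames <- matrix(window_samples, nrow = fl, ncol = 5)
  structure(list(magnitude = frame_magnitudes(frames, fft_length),
                 normalized = FALSE),
            class = "spectrogram_feature")
}

#' Normalize a spectrogram feature to unit scale
#'
#' Min-max scales the whole magnitude matrix to `[0, 1]`. Normalisation is
#' per spectrogram (no dataset-wide statistics), so it is usable in an
#' online setting. A constant matrix maps to all zeros.
#'
#' @param feature A `spectrogram_feature` not yet normalized.
#' @return The feature with entries in `[0, 1]` and `normalized = TRUE`.
#' @export
normalize_spectrogram <- function(feature) {
  stopifnot(inherits(feature, "spectrogram_feature"))
  if (feature$normalized) abort("Feature is already normalized.")
  m <- feature$magnitude
  rng <- range(m)
  feature$magnitude <- if (rng[2] > rng[1]) {
    (m - rng[1]) / (rng[2] - rng[1])
  } else {
    m * 0
  }
  feature$normalized <- TRUE
  feature
}

#' Flatten a spectrogram feature to the classifier input vector
#'
#' Frame-major concatenation: entry (bin b, frame f), both 0-based, lands at
#' index `f * 257 + b`. Length is 257 x 5 = 1285, the input width of the
#' classifier.
#'
#' @param feature A normalized `spectrogram_feature`.
#' @return Numeric vector of length 1285.
#' @export
flatten_spectrogram <- function(feature) {
  stopifnot(inherits(feature, "spectrogram_feature"))
  if (!feature$normalized) abort("Normalize the feature before flattening.")
  if (!all(dim(feature$magnitude) == c(257, 5))) {
    abort("Expected a 257 x 5 magnitude matrix.")
  }
  as.vector(feature$magnitude)
}

#' Rebuild the magnitude matrix from a flattened feature vector
#'
#' @param x Numeric vector of length `n_bins * n_frames`.
#' @param n_bins,n_frames Matrix shape (defaults 257 x 5).
#' @return Magnitude matrix.
#' @export
unflatten_spectrogram <- function(x, n_bins = 257L, n_frames = 5L) {
  if (length(x) != n_bins * n_frames) abort("Length does not match shape.")
  matrix(x, nrow = n_bins, ncol = n_frames)
}

#' Area under the spectral-estimate curve
#'
#' For consecutive non-overlapping frames of `frame_length` samples over a
#' signal region, returns the per-frame sum of the 257 spectrogram magnitude
#' values (summation across frequencies for each time sample). This is the
#' statistic used to refine segment borders.
#'
#' @param channel_samples Numeric signal region.
#' @param frame_length Frame length in samples (`N/5` for window size N).
#' @param fft_length Transform length (default 512).
#' @return Numeric vector with one non-negative value per complete frame
#'   (empty if the region is shorter than one frame).
#' @export
auc_curve <- function(channel_samples, frame_length, fft_length = 512L) {
  if (frame_length > fft_length) {
    abort("Frame length exceeds the transform length.")
  }
  n_frames <- length(channel_samples) %/% frame_length
  if (n_frames == 0) return(numeric(0))
  frames <- matrix(channel_samples[seq_len(n_frames * frame_length)],
                   nrow = frame_length)
  colSums(frame_magnitudes(frames, fft_length))
}

#' Feature matrix for a table of windows
#'
#' Computes the normalized, flattened spectrogram feature of every window.
#'
#' @param recordings A single `swallow_recording` or a named list of them
#'   (names or ids matching `windows$recording_id`).
#' @param windows Window tibble from [partition_windows()] (optionally
#'   labelled).
#' @param fft_length Transform length (default 512).
#' @return Numeric matrix, one row per window, 1285 columns.
#' @export
window_features <- function(recordings, windows, fft_length = 512L) {
  if (inherits(recordings, "swallow_recording")) {
    recordings <- list(recordings)
    names(recordings) <- recordings[[1]]$id
  }
  if (is.null(names(recordings))) {
    names(recordings) <- purrr::map_chr(recordings, "id")
  }
  out <- matrix(0, nrow = nrow(windows), ncol = 257 * 5)
  for (i in seq_len(nrow(windows))) {
    rec <- recordings[[windows$recording_id[i]]]
    if (is.null(rec)) {
      abort(sprintf("No recording '%s' supplied.", windows$recording_id[i]))
    }
    x <- recording_channel(rec, windows$channel[i])
    seg <- x[(windows$start[i] + 1):(windows$start[i] + windows$size[i])]
    out[i, ] <- flatten_spectrogram(
      normalize_spectrogram(spectrogram(seg, fft_length)))
  }
  out
}
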