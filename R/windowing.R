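#' Sliding-window specification
#'
#' The analysis grid uses window sizes of 500 to 1500 samples (125 to 375 ms
#' at the 4 kHz working rate) in steps of 100, either non-overlapping or
#' with 50% overlap. The size must be divisible by 5 because the feature
#' stage splits each window into 5 equal frames.
#'
#' @param size Window size in samples.
#' @param overlap `"none"` (hop = size) or `"half"` (hop = size/2).
#' @return A `window_spec` list with fields `size` and `hop`.
#' @export
window_spec <- function(size = 800L, overlap = c("none", "half")) {
  overlap <- match.arg(overlap)
  size <- as.integer(size)
  if (size < 1) abort("Window size must be positive.")
  if (size %% 5 != 0) abort("Window size must be divisible by 5.")
  hop <- if (overlap == "none") size else {
    if (size %% 2 != 0) abort("50% overlap requires an even window size.")
    size %/% 2L
  }
  structure(list(size = size, hop = hop, overlap = overlap),
            class = "window_spec")
}

#' Partition a recording channel into analysis windows
#'
#' Windows start at 0, hop, 2*hop, ...; trailing samples that cannot fill a
#' complete window are discarded, so for a signal of `L >= size` samples the
#' count is `floor((L - size)/hop) + 1` (zero windows when `L < size`).
#'
#' @param recording A `swallow_recording` at the working rate.
#' @param spec A [window_spec()].
#' @param channel Channel name to attribute windows to.
#' @return Tibble with columns `recording_id`, `channel`, `start`, `size`,
#'   `hop`.
#' @export
partition_windows <- function(recording, spec, channel = "AP") {
  stopifnot(inherits(spec, "window_spec"))
  if (!channel %in% colnames(recording$channels)) {
    abort(sprintf("Recording '%s' has no channel '%s'.",
                  recording$id, channel))
  }
  L <- n_samples(recording)
  starts <- if (L < spec$size) integer(0) else {
    seq(0L, L - spec$size, by = spec$hop)
  }
  tibble(recording_id = recording$id, channel = channel,
         start = as.integer(starts), size = spec$size, hop = spec$hop)
}

# Largest per-window overlap (in samples) with any single swallow segment.
max_segment_overlap <- function(start, size, annotations) {
  ann <- annotations[is_swallow_label(annotations$label), , drop = FALSE]
  best <- numeric(length(start))
  for (i in seq_len(nrow(ann))) {
    ov <- pmin(start + size, ann$offset[i]) - pmax(start, ann$onset[i])
    best <- pmax(best, ov)
  }
  best
}

#' Label a single window against manual annotations
#'
#' A window is a swallow window iff some single annotated swallow segment
#' overlaps it by at least half the window size (the 50% threshold is
#' inclusive). Distractor (`nonswallow:*`) annotations never make a window
#' positive.
#'
#' @param start Window start (sample index).
#' @param size Window size in samples.
#' @param annotations Annotation tibble in sample units.
#' @return `"swallow"` or `"non_swallow"`.
#' @export
label_window <- function(start, size, annotations) {
  ifelse(max_segment_overlap(start, size, annotations) >= size / 2,
         "swallow", "non_swallow")
}

#' Label a window table against annotations
#'
#' @param windows Window tibble from [partition_windows()].
#' @param annotations Annotation tibble in sample units (same recording).
#' @return `windows` with an added `label` column.
#' @export
label_windows <- function(windows, annotations) {
  dplyr::mutate(windows,
                label = label_window(.data$start, .data$size, annotations))
}

#' Balance swallow and non-swallow windows by undersampling
#'
#' Keeps the full set of swallow windows and draws (without replacement) an
#' equally sized random subset of the non-swallow windows, mirroring the
#' class-balancing used before training. If non-swallow windows are already
#' the minority, everything is kept with a warning.
#'
#' @param windows Labelled window tibble.
#' @param seed Seed for the undersampling draw.
#' @return Balanced window tibble (row order: swallow then sampled
#'   non-swallow).
#' @export
balance_windows <- function(windows, seed = 1L) {
  sw <- dplyr::filter(windows, .data$label == "swallow")
  ns <- dplyr::filter(windows, .data$label == "non_swallow")
  if (nrow(ns) < nrow(sw)) {
    warn("Fewer non-swallow than swallow windows; keeping all of both.")
    return(dplyr::bind_rows(sw, ns))
  }
  pick <- withr::with_seed(seed, sample.int(nrow(ns), nrow(sw)))
  dplyr::bind_rows(sw, ns[pick, , drop = FALSE])
}

#' Random train/test split of windows
#'
#' @param windows Window tibble.
#' @param fraction Training fraction in (0, 1); the split point is
#'   `round(fraction * n)`.
#' @param seed Shuffle seed.
#' @return List with tibbles `train` and `test` (disjoint; union is the
#'   input multiset).
#' @export
split_train_test <- function(windows, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  n <- nrow(windows)
  ord <- withr::with_seed(seed, sample.int(n))
  n_train <- round(fraction * n)
  list(train = windows[ord[seq_len(n_train)], , drop = FALSE],
       test = windows[ord[setdiff(seq_len(n), seq_len(n_train))], ,
                      drop = FALSE])
}

#' Grouped k-fold partition of recording ids
#'
#' Splits recordings (not windows) into k folds of near-equal size, so no
#' recording contributes windows to both a training and a test set.
#'
#' @param ids Character vector of recording ids.
#' @param k Number of folds (`k <= length(ids)`).
#' @param seed Shuffle seed.
#' @return List of `k` character vectors partitioning `ids`; sizes differ by
#'   at most one.
#' @export
group_kfold <- function(ids, k = 10L, seed = 1L) {
  n <- length(ids)
  if (k > n) abort("Cannot make more folds than recordings.")
  if (k < 1) abort("`k` must be at least 1.")
  shuffled <- withr::with_seed(seed, sample(ids))
  unname(split(shuffled, rep(seq_len(k), length.out = n)))
}
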