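#' Window-level confusion metrics
#'
#' Accuracy, sensitivity and specificity of per-window decisions against
#' reference window labels. Ratios with a zero denominator are reported as
#' `NA` (absent), never as zero.
#'
#' @param predicted,reference Equal-length vectors of window decisions
#'   (0/1, logical, or `"swallow"`/`"non_swallow"`).
#' @return One-row tibble with `tp`, `fp`, `tn`, `fn`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
window_metrics <- function(predicted, reference) {
  to_bin <- function(x) {
    if (is.character(x) || is.factor(x)) as.character(x) == "swallow" else {
      as.logical(x)
    }
  }
  p <- to_bin(predicted); r <- to_bin(reference)
  if (length(p) != length(r)) {
    abort("`predicted` and `reference` must have equal length.")
  }
  tp <- sum(p & r); fp <- sum(p & !r)
  tn <- sum(!p & !r); fn <- sum(!p & r)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = ratio(tp + tn, tp + tn + fp + fn),
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp))
}

#' Overlap criteria for counting a reference swallow as detected
#'
#' Two families of minimum-overlap criteria: a fixed duration irrespective
#' of the segment (defaults 431.89 ms, two SD below the average clinical
#' swallow duration, and 675.56 ms, one SD below), and a fraction of the
#' manually measured reference duration (defaults 90% and 95%). Fixed
#' criteria are capped at the reference duration so swallows shorter than
#' the fixed value remain detectable.
#'
#' @param fixed_msec Numeric vector of fixed-overlap criteria, msec.
#' @param fractions Numeric vector of fraction-of-reference criteria in
#'   (0, 1].
#' @return Tibble with columns `criterion` (label), `kind`
#'   (`"fixed_msec"`/`"fraction_of_reference"`) and `value`.
#' @export
detection_criteria <- function(fixed_msec = c(431.89, 675.56),
                               fractions = c(0.90, 0.95)) {
  if (any(fixed_msec <= 0)) abort("Fixed criteria must be positive.")
  if (any(fractions <= 0 | fractions > 1)) {
    abort("Fraction criteria must lie in (0, 1].")
  }
  dplyr::bind_rows(
    tibble(criterion = sprintf("fixed_%.2fms", fixed_msec),
           kind = "fixed_msec", value = fixed_msec),
    tibble(criterion = sprintf("overlap_%d%%", round(fractions * 100)),
           kind = "fraction_of_reference", value = fractions)
  )
}

#' Score detected segments against reference swallows under one criterion
#'
#' For each reference swallow the overlap with the single best-matching
#' detected segment is compared to the required minimum overlap: the
#' criterion value in milliseconds (capped at the reference duration) for
#' fixed criteria, or the criterion value times the reference duration for
#' fractional ones.
#'
#' @param detected Tibble of detected segments (`onset`, `offset`, sample
#'   units).
#' @param reference Tibble of reference swallow segments (same units;
#'   `nonswallow:*` labels, if present, are dropped).
#' @param criterion One row of [detection_criteria()] (or a list with
#'   `kind` and `value`).
#' @param sampling_rate Hz, to convert samples to milliseconds.
#' @return Tibble with one row per reference swallow: `onset`, `offset`,
#'   `ref_duration_ms`, `overlap_ms`, `required_ms`, `detected`,
#'   `matched_duration_ms` (duration of the best-matching detected
#'   segment; `NA` when nothing overlaps).
#' @export
detect_swallows <- function(detected, reference, criterion,
                            sampling_rate = 4000) {
  if ("label" %in% names(reference)) {
    reference <- reference[is_swallow_label(reference$label), , drop = FALSE]
  }
  ms <- 1000 / sampling_rate
  n_ref <- nrow(reference)
  overlap_ms <- numeric(n_ref)
  matched_ms <- rep(NA_real_, n_ref)
  for (i in seq_len(n_ref)) {
    if (nrow(detected) == 0) break
    ov <- pmin(reference$offset[i], detected$offset) -
      pmax(reference$onset[i], detected$onset)
    best <- which.max(ov)
    if (ov[best] > 0) {
      overlap_ms[i] <- ov[best] * ms
      matched_ms[i] <- (detected$offset[best] - detected$onset[best]) * ms
    }
  }
  ref_dur <- (reference$offset - reference$onset) * ms
  required <- if (criterion$kind == "fixed_msec") {
    pmin(criterion$value, ref_dur)
  } else {
    criterion$value * ref_dur
  }
  tibble(onset = reference$onset, offset = reference$offset,
         ref_duration_ms = ref_dur, overlap_ms = overlap_ms,
         required_ms = required, detected = overlap_ms >= required,
         matched_duration_ms = matched_ms)
}

#' Summarize detection results across criteria
#'
#' Runs [detect_swallows()] for every criterion and reports the detected
#' fraction and the mean and population SD of the matched detected-segment
#' durations (detected references only).
#'
#' @param detected,reference Segment tibbles as in [detect_swallows()].
#' @param criteria Criterion tibble from [detection_criteria()].
#' @param sampling_rate Hz.
#' @return Tibble with one row per criterion: `criterion`, `kind`, `value`,
#'   `n_reference`, `n_detected`, `detected_fraction`, `mean_duration_ms`,
#'   `sd_duration_ms`.
#' @export
summarize_detections <- function(detected, reference,
                                 criteria = detection_criteria(),
                                 sampling_rate = 4000) {
  if ("label" %in% names(reference)) {
    reference <- reference[is_swallow_label(reference$label), , drop = FALSE]
  }
  if (nrow(reference) == 0) abort("At least one reference swallow needed.")
  purrr::map_dfr(seq_len(nrow(criteria)), function(i) {
    crit <- criteria[i, ]
    res <- detect_swallows(detected, reference, crit, sampling_rate)
    hit <- res$matched_duration_ms[res$detected]
    tibble(
      criterion = crit$criterion, kind = crit$kind, value = crit$value,
      n_reference = nrow(res), n_detected = sum(res$detected),
      detected_fraction = mean(res$detected),
      mean_duration_ms = if (length(hit)) mean(hit) else NA_real_,
      sd_duration_ms = if (length(hit)) pop_sd(hit) else NA_real_
    )
  })
}

# Population SD (divisor n), the convention used for duration spreads.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
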