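#' Read a recording from plain-text signal and annotation files
#'
#' The signal file is whitespace/tab-delimited with one column per channel
#' (1 to 4 columns, optionally headed by channel names); the annotation file
#' is a CSV with columns `recording_id`, `onset_ms`, `offset_ms`, `type`.
#' Annotation times are converted from milliseconds to sample indices at
#' `sampling_rate`.
#'
#' @param signal_path Path to the signal column file.
#' @param annotation_path Path to the annotation CSV, or `NULL` for none.
#' @param sampling_rate Sampling rate of the signal file, Hz.
#' @param id Recording id; defaults to the signal file stem.
#' @return A [new_recording()].
#' @export
read_recording <- function(signal_path, annotation_path = NULL,
                           sampling_rate = 20000, id = NULL) {
  if (!file.exists(signal_path)) {
    abort(sprintf("Signal file not found: %s", signal_path))
  }
  id <- id %||% sub("\\.[^.]*$", "", basename(signal_path))
  first <- readLines(signal_path, n = 1)
  has_header <- any(strsplit(trimws(first), "[\t ]+")[[1]] %in% hrca_channels)
  tbl <- suppressWarnings(
    readr::read_table(signal_path, col_names = has_header,
                      show_col_types = FALSE,
                      col_types = readr::cols(
                        .default = readr::col_double())))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed signal row at line %d of %s.",
                  probs$row[1] + has_header, signal_path))
  }
  if (ncol(tbl) < 1 || ncol(tbl) > 4) {
    abort("Signal files must have 1 to 4 channel columns.")
  }
  mat <- as.matrix(tbl)
  if (!has_header) colnames(mat) <- hrca_channels[seq_len(ncol(mat))]

  ann <- segment_tbl()
  if (!is.null(annotation_path)) {
    ann <- read_annotations(annotation_path, sampling_rate)
    ann <- ann[, c("onset", "offset", "label")]
  }
  new_recording(id, mat, sampling_rate, ann)
}

#' Read an annotation CSV (millisecond units) into sample units
#'
#' @param path Annotation CSV with columns `recording_id`, `onset_ms`,
#'   `offset_ms`, `type`.
#' @param sampling_rate Rate used to convert milliseconds to samples.
#' @return Tibble with `recording_id`, `onset`, `offset`, `label`.
#' @export
read_annotations <- function(path, sampling_rate) {
  tbl <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      recording_id = readr::col_character(),
                      onset_ms = readr::col_double(),
                      offset_ms = readr::col_double(),
                      type = readr::col_character())))
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed annotation row at line %d of %s.",
                  probs$row[1] + 1, path))
  }
  tibble(
    recording_id = tbl$recording_id,
    onset = round(tbl$onset_ms / 1000 * sampling_rate),
    offset = round(tbl$offset_ms / 1000 * sampling_rate),
    label = tbl$type
  )
}

#' Write a recording to plain-text signal and annotation files
#'
#' Inverse of [read_recording()]: signal as a tab-separated column file with
#' a channel-name header, annotations as a millisecond-unit CSV.
#'
#' @param recording A `swallow_recording`.
#' @param signal_path Output path for the signal columns.
#' @param annotation_path Output path for the annotation CSV (optional).
#' @return The recording, invisibly.
#' @export
write_recording <- function(recording, signal_path,
                            annotation_path = NULL) {
  readr::write_tsv(tibble::as_tibble(recording$channels), signal_path)
  if (!is.null(annotation_path)) {
    fs <- recording$sampling_rate
    ann <- recording$annotations
    readr::write_csv(
      tibble(recording_id = recording$id,
             onset_ms = ann$onset / fs * 1000,
             offset_ms = ann$offset / fs * 1000,
             type = ann$label),
      annotation_path)
  }
  invisible(recording)
}

#' Write a generated dataset to a directory
#'
#' One signal file and one annotation CSV per recording, plus the manifest.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset$recordings) {
    write_recording(rec,
                    file.path(dir, paste0(rec$id, ".txt")),
                    file.path(dir, paste0(rec$id, "_annotations.csv")))
  }
  readr::write_csv(dataset$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory holding `<id>.txt` signal files and
#'   `<id>_annotations.csv` annotation files.
#' @param sampling_rate Sampling rate of the signal files, Hz.
#' @return Named list of recordings.
#' @export
read_dataset <- function(dir, sampling_rate = 4000) {
  sigs <- list.files(dir, pattern = "\\.txt$", full.names = TRUE)
  if (length(sigs) == 0) abort(sprintf("No signal files under %s.", dir))
  recs <- lapply(sigs, function(path) {
    id <- sub("\\.txt$", "", basename(path))
    ann <- file.path(dir, paste0(id, "_annotations.csv"))
    read_recording(path, if (file.exists(ann)) ann else NULL,
                   sampling_rate, id = id)
  })
  stats::setNames(recs, vapply(recs, function(r) r$id, character(1)))
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase FIR anti-aliasing low-pass (cutoff at 90% of the new
#' Nyquist) before keeping every `factor`-th sample. Annotation onsets are
#' rounded down and offsets up, so a ground-truth segment never shrinks.
#'
#' @param recording A `swallow_recording`.
#' @param factor Integer decimation factor >= 1 (5 takes 20 kHz to the
#'   4 kHz working rate).
#' @return The downsampled `swallow_recording`.
#' @export
downsample_recording <- function(recording, factor = 5L) {
  if (factor < 1 || factor != round(factor)) {
    abort("`factor` must be a positive integer.")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(recording)
  L <- n_samples(recording)
  if (L < factor) abort("Recording shorter than the decimation factor.")

  b <- as.numeric(signal::fir1(64, 0.9 / factor, type = "low"))
  b <- b / sum(b)  # exact unity DC gain
  keep <- seq(1L, L, by = factor)
  filtered <- apply(recording$channels, 2,
                    function(x) signal::filtfilt(b, 1, x))
  out <- filtered[keep, , drop = FALSE]
  colnames(out) <- colnames(recording$channels)

  ann <- recording$annotations
  if (nrow(ann) > 0) {
    ann$onset <- floor(ann$onset / factor)
    ann$offset <- pmin(ceiling(ann$offset / factor), length(keep))
    if (nrow(ann) > 1) {  # rounding outward must not create overlap
      ann$offset[-nrow(ann)] <- pmin(ann$offset[-nrow(ann)], ann$onset[-1])
    }
  }
  new_recording(recording$id, out, recording$sampling_rate / factor, ann)
}
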