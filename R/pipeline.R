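#' Labelled windows for a set of recordings
#'
#' Partitions every recording on one channel and labels the windows against
#' its ground-truth annotations.
#'
#' @param recordings List of `swallow_recording` objects.
#' @param spec A [window_spec()].
#' @param channel Channel name.
#' @return Labelled window tibble across all recordings.
#' @export
labelled_windows <- function(recordings, spec, channel = "AP") {
  purrr::map_dfr(recordings, function(rec) {
    label_windows(partition_windows(rec, spec, channel), rec$annotations)
  })
}

name_recordings <- function(recordings) {
  if (inherits(recordings, "swallow_recording")) recordings <- list(recordings)
  stats::setNames(recordings, purrr::map_chr(recordings, "id"))
}

#' Segment one recording with a trained classifier
#'
#' Runs the online path: partition, spectrogram features, window
#' classification, mask assembly and (optionally) AUC border refinement.
#'
#' @param model A trained `swallow_mlp`.
#' @param recording A `swallow_recording` at the working rate.
#' @param spec A [window_spec()].
#' @param channel Channel to classify on (A-P by default, the best
#'   performing line; refinement uses the same channel).
#' @param refine Apply [refine_borders()]?
#' @param alpha Refinement threshold position (see [refine_borders()]).
#' @return A `segmentation_mask`.
#' @export
segment_recording <- function(model, recording, spec, channel = "AP",
                              refine = TRUE, alpha = 0.5) {
  windows <- partition_windows(recording, spec, channel)
  if (nrow(windows) == 0) {
    return(assemble_mask(logical(0), spec, n_samples(recording),
                         recording$id))
  }
  feats <- window_features(recording, windows)
  decisions <- predict(model, feats, type = "class")
  mask <- assemble_mask(decisions, spec, n_samples(recording), recording$id)
  if (refine) {
    mask <- refine_borders(mask, recording_channel(recording, channel),
                           alpha)
  }
  mask
}

train_one_model <- function(recordings, windows, train_cfg, hidden_size,
                            seed) {
  feats <- window_features(recordings, windows)
  cfg <- train_config(epochs = train_cfg$epochs,
                      learning_rate = train_cfg$learning_rate,
                      seed = derive_seed(seed, 2),
                      shuffle_each_epoch = train_cfg$shuffle_each_epoch,
                      loss = train_cfg$loss)
  model <- mlp_init(input_size = ncol(feats), hidden_size = hidden_size,
                    seed = derive_seed(seed, 1))
  mlp_train(model, feats, windows$label, cfg)
}

#' Parameter-selection grid over channels and window sizes
#'
#' For every (channel, window size, overlap) cell: partition and label the
#' windows of all recordings, balance the classes, split 80/20 at window
#' level, train a classifier and report window-level metrics on the test
#' part. A failing cell is logged and reported as `NA`, without aborting
#' the grid.
#'
#' @param recordings List of `swallow_recording` objects at the working
#'   rate.
#' @param channels Channels to evaluate.
#' @param sizes Window sizes in samples (default the 500..1500 step 100
#'   grid).
#' @param overlaps Subset of `c("none", "half")`.
#' @param train_cfg A [train_config()] template (its seed is re-derived per
#'   cell).
#' @param fraction Training fraction for the window-level split.
#' @param hidden_size Hidden layer width (default 1285).
#' @param seed Master seed for balancing/splitting/initialisation.
#' @return Tibble with one row per grid cell: `channel`, `size`, `overlap`,
#'   window counts and test metrics.
#' @export
run_parameter_selection <- function(recordings, channels = "AP",
                                    sizes = seq(500, 1500, by = 100),
                                    overlaps = "none",
                                    train_cfg = train_config(),
                                    fraction = 0.8, hidden_size = 1285L,
                                    seed = 1L) {
  recordings <- name_recordings(recordings)
  grid <- tidyr::expand_grid(channel = channels, size = sizes,
                             overlap = overlaps)
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cell <- grid[i, ]
    cell_seed <- derive_seed(seed, i * 17)
    res <- tryCatch({
      spec <- window_spec(cell$size, cell$overlap)
      windows <- labelled_windows(recordings, spec, cell$channel)
      balanced <- balance_windows(windows, seed = cell_seed)
      parts <- split_train_test(balanced, fraction,
                                seed = derive_seed(cell_seed, 3))
      model <- train_one_model(recordings, parts$train, train_cfg,
                               hidden_size, cell_seed)
      pred <- predict(model, window_features(recordings, parts$test),
                      type = "class")
      dplyr::mutate(window_metrics(pred, parts$test$label),
                    n_train = nrow(parts$train), n_test = nrow(parts$test))
    }, error = function(e) {
      warn(sprintf("Grid cell (%s, %d, %s) failed: %s",
                   cell$channel, cell$size, cell$overlap,
                   conditionMessage(e)))
      tibble(tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
             fn = NA_integer_, accuracy = NA_real_,
             sensitivity = NA_real_, specificity = NA_real_,
             n_train = NA_integer_, n_test = NA_integer_)
    })
    dplyr::bind_cols(cell, res)
  })
}

#' Best configuration from a parameter-selection table
#'
#' Argmax of test accuracy; ties are broken toward the smaller window size
#' (cheaper online operation), then toward the earlier channel.
#'
#' @param results Output of [run_parameter_selection()].
#' @return The winning row.
#' @export
best_configuration <- function(results) {
  valid <- dplyr::filter(results, !is.na(.data$accuracy))
  if (nrow(valid) == 0) abort("No grid cell produced a valid accuracy.")
  valid <- dplyr::arrange(valid, dplyr::desc(.data$accuracy), .data$size)
  valid[1, ]
}

#' Final grouped k-fold train/test run with refinement
#'
#' Recordings are split into k folds; for each fold a classifier is trained
#' on the balanced windows of the other folds' recordings, every test
#' recording is segmented (classification, mask assembly, AUC refinement),
#' and the detections are scored under all criteria. Window-level metrics
#' are computed per test recording.
#'
#' @param recordings List of `swallow_recording` objects at the working
#'   rate.
#' @param channel Channel to use (the chosen best line).
#' @param size Window size in samples (the chosen best size).
#' @param overlap `"none"` or `"half"`.
#' @param k Number of recording folds.
#' @param train_cfg A [train_config()] template.
#' @param criteria Detection criteria tibble ([detection_criteria()]).
#' @param refine,alpha Border-refinement switches (see
#'   [segment_recording()]).
#' @param hidden_size Hidden layer width.
#' @param seed Master seed.
#' @param keep_masks Keep the per-recording segmentation masks (raw and
#'   refined segments) in the result?
#' @return A `swallowseg_final` list: `folds` (id partition),
#'   `window_metrics` (per test recording), `detections` (per fold x
#'   criterion), `aggregate` (per criterion mean and SD of the detected
#'   fraction across folds) and `window_summary` (mean and SD of
#'   per-recording sensitivity/specificity/accuracy).
#' @export
run_final <- function(recordings, channel = "AP", size = 800L,
                      overlap = "none", k = 10L,
                      train_cfg = train_config(),
                      criteria = detection_criteria(), refine = TRUE,
                      alpha = 0.5, hidden_size = 1285L, seed = 1L,
                      keep_masks = FALSE) {
  recordings <- name_recordings(recordings)
  spec <- window_spec(size, overlap)
  folds <- group_kfold(names(recordings), k, seed = derive_seed(seed, 5))

  win_rows <- list(); det_rows <- list(); masks <- list()
  for (f in seq_along(folds)) {
    test_ids <- folds[[f]]
    train_ids <- setdiff(names(recordings), test_ids)
    fold_seed <- derive_seed(seed, 100 + f)
    train_windows <- balance_windows(
      labelled_windows(recordings[train_ids], spec, channel),
      seed = fold_seed)
    model <- train_one_model(recordings, train_windows, train_cfg,
                             hidden_size, fold_seed)

    per_ref <- list()
    for (id in test_ids) {
      rec <- recordings[[id]]
      windows <- label_windows(partition_windows(rec, spec, channel),
                               rec$annotations)
      pred <- predict(model, window_features(rec, windows), type = "class")
      win_rows[[length(win_rows) + 1]] <- dplyr::bind_cols(
        tibble(fold = f, recording_id = id),
        window_metrics(pred, windows$label))
      mask <- assemble_mask(pred, spec, n_samples(rec), id)
      if (refine) {
        mask <- refine_borders(mask, recording_channel(rec, channel), alpha)
      }
      if (keep_masks) masks[[id]] <- mask
      ref <- rec$annotations[is_swallow_label(rec$annotations$label), ]
      if (nrow(ref) > 0) {
        per_ref[[id]] <- purrr::map_dfr(seq_len(nrow(criteria)), function(ci) {
          dplyr::mutate(
            detect_swallows(mask$segments, ref, criteria[ci, ],
                            rec$sampling_rate),
            criterion = criteria$criterion[ci], recording_id = id)
        })
      }
    }
    fold_det <- dplyr::bind_rows(per_ref)
    det_rows[[f]] <- if (nrow(fold_det) == 0) {
      # fold without any reference swallow: detection stats absent
      dplyr::mutate(criteria, fold = f, n_reference = 0L, n_detected = 0L,
                    detected_fraction = NA_real_,
                    mean_duration_ms = NA_real_, sd_duration_ms = NA_real_)
    } else {
      fold_det |>
        dplyr::group_by(.data$criterion) |>
        dplyr::summarise(
          n_reference = dplyr::n(), n_detected = sum(.data$detected),
          detected_fraction = mean(.data$detected),
          mean_duration_ms = mean(.data$matched_duration_ms[.data$detected]),
          sd_duration_ms = pop_sd(.data$matched_duration_ms[.data$detected]),
          .groups = "drop") |>
        dplyr::left_join(criteria, by = "criterion") |>
        dplyr::mutate(fold = f)
    }
  }

  window_metrics_tbl <- dplyr::bind_rows(win_rows)
  detections <- dplyr::bind_rows(det_rows)
  aggregate <- detections |>
    dplyr::group_by(.data$criterion) |>
    dplyr::summarise(
      mean_detected_fraction = mean(.data$detected_fraction, na.rm = TRUE),
      sd_detected_fraction = pop_sd(stats::na.omit(.data$detected_fraction)),
      .groups = "drop")
  window_summary <- window_metrics_tbl |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy, na.rm = TRUE),
      sd_accuracy = pop_sd(stats::na.omit(.data$accuracy)),
      mean_sensitivity = mean(.data$sensitivity, na.rm = TRUE),
      sd_sensitivity = pop_sd(stats::na.omit(.data$sensitivity)),
      mean_specificity = mean(.data$specificity, na.rm = TRUE),
      sd_specificity = pop_sd(stats::na.omit(.data$specificity)))

  structure(list(folds = folds, spec = spec, channel = channel,
                 window_metrics = window_metrics_tbl,
                 detections = detections, aggregate = aggregate,
                 window_summary = window_summary,
                 masks = if (keep_masks) masks),
            class = "swallowseg_final")
}

#' @export
print.swallowseg_final <- function(x, ...) {
  cat(sprintf("<swallowseg_final> %d folds, channel %s, N = %d\n",
              length(x$folds), x$channel, x$spec$size))
  print(x$aggregate)
  invisible(x)
}

#' Tidy per-fold detection results of a final run
#' @param x A `swallowseg_final`.
#' @param ... Unused.
#' @return The per-fold, per-criterion detection tibble.
#' @export
tidy.swallowseg_final <- function(x, ...) x$detections

#' One-row summary of a final run
#' @param x A `swallowseg_final`.
#' @param ... Unused.
#' @return One-row tibble combining window-level means with the detected
#'   fraction per criterion (wide).
#' @export
glance.swallowseg_final <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::select(x$aggregate, "criterion", "mean_detected_fraction"),
    names_from = "criterion", values_from = "mean_detected_fraction",
    names_prefix = "detected_")
  dplyr::bind_cols(x$window_summary, wide)
}
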