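cfg_fast <- function(...) {
  args <- list(n_recordings = 2, recording_duration = 8,
               sampling_rate = 4000, n_channels = 2, event_rate = 8,
               seed = 11L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

test_that("swallow durations honour the configured distribution", {
  cfg <- synth_config(seed = 5L)
  d <- sample_event_durations(cfg, 2000)
  expect_true(all(d >= cfg$duration_min))
  # calibrated truncation keeps the realized moments on target
  expect_lt(abs(mean(d) - cfg$duration_mean),
            3 * cfg$duration_sd / sqrt(2000))
  expect_lt(abs(sd(d) - cfg$duration_sd),
            3 * cfg$duration_sd / sqrt(2 * 2000))

  degen <- synth_config(duration_sd = 0, seed = 5L)
  expect_equal(sample_event_durations(degen, 10), rep(862.6, 10))

  hard_min <- synth_config(duration_min = 700, seed = 5L)
  expect_gte(min(sample_event_durations(hard_min, 500)), 700)
})

test_that("same seed gives bit-identical recordings, different seed differs", {
  cfg <- cfg_fast()
  a <- generate_recording(cfg, 0)
  b <- generate_recording(cfg, 0)
  expect_identical(a$channels, b$channels)
  expect_identical(a$annotations, b$annotations)

  other <- cfg_fast(seed = 12L)
  c <- generate_recording(other, 0)
  expect_false(identical(a$channels, c$channels))
})

test_that("zero event rate yields background-only recordings", {
  cfg <- synth_config(n_recordings = 1, recording_duration = 4,
                      sampling_rate = 4000, n_channels = 1, event_rate = 0,
                      distractor_spec = list(
                        cough = list(rate = 0, dur_range = c(100, 300)),
                        head_motion = list(rate = 0,
                                           dur_range = c(1000, 3000))),
                      seed = 3L)
  rec <- generate_recording(cfg, 0)
  expect_equal(nrow(rec$annotations), 0)
  expect_lt(abs(sd(rec$channels[, 1]) - cfg$noise_sd), 0.05)
})

test_that("annotations are disjoint, sorted, inside the signal", {
  for (seed in c(1L, 7L, 21L)) {
    rec <- generate_recording(cfg_fast(seed = seed), 1)
    ann <- rec$annotations
    expect_true(all(ann$onset < ann$offset))
    expect_true(all(ann$onset >= 0))
    expect_true(all(ann$offset <= n_samples(rec)))
    if (nrow(ann) > 1) {
      expect_true(all(ann$onset[-1] >= ann$offset[-nrow(ann)]))
      expect_false(is.unsorted(ann$onset))
    }
  }
})

test_that("event band power dominates background band power", {
  cfg <- synth_config(n_recordings = 4, recording_duration = 10,
                      sampling_rate = 4000, n_channels = 1,
                      event_rate = 12, event_snr_db = 20, seed = 8L,
                      distractor_spec = list(
                        cough = list(rate = 0, dur_range = c(100, 300)),
                        head_motion = list(rate = 0,
                                           dur_range = c(1000, 3000))))
  ds <- generate_dataset(cfg)
  rec <- ds$recordings[[which(ds$manifest$n_swallow > 0)[1]]]
  ann <- rec$annotations
  expect_gt(nrow(ann), 0)
  x <- rec$channels[, "AP"]
  ev <- x[(ann$onset[1] + 1):ann$offset[1]]
  # background stretch before the first event, same length
  n_bg <- min(length(ev), ann$onset[1])
  bg <- x[seq_len(n_bg)]
  ratio <- band_power_oracle(ev[seq_len(n_bg)], 50, 700, 4000) /
    band_power_oracle(bg, 50, 700, 4000)
  expect_gt(ratio, 10)
})

test_that("dataset manifest books events consistently", {
  cfg <- cfg_fast(n_recordings = 3)
  ds <- generate_dataset(cfg)
  expect_length(ds$recordings, 3)
  expect_equal(nrow(ds$manifest), 3)
  expect_equal(ds$manifest$n_events,
               vapply(ds$recordings, function(r) nrow(r$annotations),
                      numeric(1)))
  expect_equal(ds$manifest$n_swallow + ds$manifest$n_distractor,
               ds$manifest$n_events)
})

test_that("total event count stays within Poisson bounds of the plan", {
  # 10 recordings x 6 expected swallows each -> lambda = 60
  cfg <- synth_config(n_recordings = 10, recording_duration = 60,
                      sampling_rate = 4000, n_channels = 1, event_rate = 6,
                      distractor_spec = list(
                        cough = list(rate = 0, dur_range = c(100, 300)),
                        head_motion = list(rate = 0,
                                           dur_range = c(1000, 3000))),
                      seed = 17L)
  ds <- generate_dataset(cfg)
  total <- sum(ds$manifest$n_swallow)
  expect_lt(abs(total - 60), 4 * sqrt(60))
})

test_that("impossible configurations are rejected", {
  expect_error(synth_config(recording_duration = 2, event_rate = 60),
               "cannot fit")
  expect_error(synth_config(event_band = c(100, 3000),
                            sampling_rate = 4000), "event_band")
  expect_error(synth_config(duration_mean = 100, duration_sd = 200),
               "duration_mean")
  expect_error(synth_config(event_rate = -1), "rates")
})
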