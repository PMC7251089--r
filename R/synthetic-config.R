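#' Configuration for the synthetic recording generator
#'
#' Describes a batch of seeded synthetic recordings that emulate the
#' statistical structure of clinical cervical-auscultation data: Gaussian
#' background noise, band-limited swallow bursts whose durations follow a
#' truncated normal law (mean 862.6 ms, SD 277 ms in the clinical cohort the
#' defaults mirror), and two distractor event classes (short broadband
#' cough-like bursts and long low-frequency head-motion drifts).
#'
#' @param n_recordings Number of recordings to generate.
#' @param recording_duration Duration of each recording, seconds.
#' @param sampling_rate Sampling rate in Hz; 20000 (ingest rate) or 4000
#'   (working rate).
#' @param n_channels Number of channels (1..4), taken in [hrca_channels]
#'   order.
#' @param event_rate Swallow events per minute.
#' @param duration_mean,duration_sd Mean and SD of swallow duration, msec.
#' @param duration_min Lower truncation bound on swallow duration, msec.
#' @param event_band Frequency interval (Hz) holding the swallow-burst
#'   energy.
#' @param event_snr_db Swallow burst RMS over background RMS, in dB.
#' @param distractor_spec Named list with elements `cough` and
#'   `head_motion`, each a list with `rate` (events/min) and `dur_range`
#'   (msec, length 2).
#' @param gap_range Inter-event gap range, seconds. Default gaps exceed the
#'   default swallow duration, mirroring recordings in which blank
#'   background stretches dominate.
#' @param channel_gains Named multiplier per channel applied to every event
#'   waveform; the anterior-posterior axis carries events most strongly by
#'   default.
#' @param noise_sd Background noise standard deviation per channel.
#' @param seed Master seed; all randomness (including per-recording derived
#'   seeds) flows from it.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_recordings = 1,
                         recording_duration = 30,
                         sampling_rate = 20000,
                         n_channels = 4,
                         event_rate = 4,
                         duration_mean = 862.6,
                         duration_sd = 277,
                         duration_min = 300,
                         event_band = c(50, 700),
                         event_snr_db = 15,
                         distractor_spec = list(
                           cough = list(rate = 1, dur_range = c(100, 300)),
                           head_motion = list(rate = 0.5,
                                              dur_range = c(1000, 3000))
                         ),
                         gap_range = c(1.5, 4),
                         channel_gains = c(AP = 1, SI = 0.6, ML = 0.5,
                                           MIC = 0.8),
                         noise_sd = 1,
                         seed = 1L) {
  cfg <- structure(
    list(n_recordings = n_recordings,
         recording_duration = recording_duration,
         sampling_rate = sampling_rate, n_channels = n_channels,
         event_rate = event_rate, duration_mean = duration_mean,
         duration_sd = duration_sd, duration_min = duration_min,
         event_band = event_band, event_snr_db = event_snr_db,
         distractor_spec = distractor_spec, gap_range = gap_range,
         channel_gains = channel_gains, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_recordings >= 1, cfg$recording_duration > 0,
            cfg$sampling_rate > 0, cfg$n_channels >= 1, cfg$n_channels <= 4)
  if (!(cfg$duration_mean > cfg$duration_sd) || cfg$duration_sd < 0) {
    abort("Need duration_mean > duration_sd >= 0.")
  }
  if (cfg$duration_min > cfg$duration_mean) {
    abort("duration_min must not exceed duration_mean.")
  }
  if (cfg$event_band[1] <= 0 || cfg$event_band[2] >= cfg$sampling_rate / 2 ||
      cfg$event_band[1] >= cfg$event_band[2]) {
    abort("event_band must lie within (0, sampling_rate/2).")
  }
  rates <- c(cfg$event_rate,
             vapply(cfg$distractor_spec, function(d) d$rate, numeric(1)))
  if (any(rates < 0)) abort("All event rates must be >= 0.")
  if (cfg$gap_range[1] < 0 || cfg$gap_range[2] < cfg$gap_range[1]) {
    abort("gap_range must be non-negative and increasing.")
  }
  # planned counts must plausibly fit in the recording
  plan <- planned_event_counts(cfg)
  mean_dur_s <- c(
    swallow = cfg$duration_mean / 1000,
    vapply(cfg$distractor_spec, function(d) mean(d$dur_range) / 1000,
           numeric(1))
  )
  need <- sum(plan * mean_dur_s[names(plan)]) +
    (sum(plan) + 1) * cfg$gap_range[1]
  if (need > cfg$recording_duration) {
    abort(sprintf(
      "Expected event durations (%.1f s) cannot fit in a %.1f s recording.",
      need, cfg$recording_duration))
  }
  cfg
}

# Expected per-event-type counts for one recording (Poisson means).
planned_event_counts <- function(cfg) {
  mins <- cfg$recording_duration / 60
  c(swallow = cfg$event_rate * mins,
    vapply(cfg$distractor_spec, function(d) d$rate * mins, numeric(1)))
}

# Per-recording seed derived from the master seed; kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) %% 97651) * 20011 +
               (index %% 1021) * 7919 + index + 1) %% 2147483647L
}
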