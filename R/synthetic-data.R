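# Moments of a normal(mu, sigma) truncated below at a.
truncnorm_moments <- function(mu, sigma, a) {
  alpha <- (a - mu) / sigma
  z <- pnorm(alpha, lower.tail = FALSE)
  delta <- dnorm(alpha) / z
  list(mean = mu + sigma * delta,
       sd = sigma * sqrt(pmax(1 + alpha * delta - delta^2, 0)))
}

# Location/scale of the lower-truncated normal whose realized mean and SD
# equal the configured values. The naive parameterisation inflates the mean
# (and deflates the SD) whenever the truncation bound bites; this calibration
# keeps cohort statistics of the simulated durations on target.
truncnorm_calibrate <- function(target_mean, target_sd, a) {
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  if (pnorm((a - target_mean) / target_sd) < 1e-12) {
    return(c(mu = target_mean, sigma = target_sd))
  }
  objective <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), a)
    (m$mean - target_mean)^2 / target_sd^2 +
      (m$sd - target_sd)^2 / target_sd^2
  }
  fit <- optim(c(target_mean, log(target_sd)), objective,
               method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# Draw swallow durations (msec) from the calibrated truncated normal using
# the current RNG state. Inverse-CDF sampling: one uniform per draw, so the
# RNG stream advances deterministically.
draw_durations <- function(cfg, n) {
  if (cfg$duration_sd == 0) return(rep(cfg$duration_mean, n))
  par <- truncnorm_calibrate(cfg$duration_mean, cfg$duration_sd,
                             cfg$duration_min)
  p_lo <- pnorm((cfg$duration_min - par["mu"]) / par["sigma"])
  u <- runif(n, min = p_lo, max = 1)
  unname(par["mu"] + par["sigma"] * qnorm(u))
}

#' Sample synthetic swallow durations
#'
#' Draws swallow-event durations from a normal law truncated below at
#' `duration_min`, with location and scale calibrated so the realized mean
#' and SD match `duration_mean` and `duration_sd` despite the truncation.
#'
#' @param config A [synth_config()].
#' @param n Number of durations to draw (>= 1).
#' @param seed Seed for this draw; defaults to the config's master seed.
#' @return Numeric vector of `n` durations in milliseconds, all
#'   `>= duration_min`.
#' @export
sample_event_durations <- function(config, n, seed = config$seed) {
  stopifnot(inherits(config, "synth_config"), n >= 1)
  withr::with_seed(seed, draw_durations(config, n))
}

# Band-limited Gaussian noise via frequency-domain masking: exact energy
# confinement to [band[1], band[2]] Hz, no filter-design edge effects.
band_noise <- function(n, band, fs) {
  x <- rnorm(n)
  spec <- fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  fold <- pmin(freq, fs - freq)  # two-sided spectrum folded to [0, fs/2]
  spec[fold < band[1] | fold > band[2]] <- 0i
  Re(fft(spec, inverse = TRUE)) / n
}

# Raised-cosine attack/decay envelope; attack shorter than decay, mimicking
# burst morphology (sharp onset, gradual release).
burst_envelope <- function(n, attack_frac = 0.2, decay_frac = 0.5) {
  na <- max(2L, round(attack_frac * n))
  nd <- max(2L, round(decay_frac * n))
  if (na + nd > n) {
    na <- max(1L, floor(n * attack_frac / (attack_frac + decay_frac)))
    nd <- n - na
  }
  env <- rep(1, n)
  env[seq_len(na)] <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = na)))
  env[seq(n - nd + 1, n)] <- 0.5 * (1 + cos(pi * seq(0, 1, length.out = nd)))
  env
}

scale_rms <- function(x, target_rms) {
  r <- sqrt(mean(x^2))
  if (r == 0) return(x)
  x * (target_rms / r)
}

# One event waveform at the recording sampling rate (unit channel gain).
synth_event_waveform <- function(type, n, cfg) {
  fs <- cfg$sampling_rate
  target <- cfg$noise_sd * 10^(cfg$event_snr_db / 20)
  wav <- switch(
    type,
    swallow = scale_rms(
      band_noise(n, cfg$event_band, fs) * burst_envelope(n, 0.2, 0.5),
      target),
    cough = scale_rms(
      rnorm(n) * burst_envelope(n, 0.1, 0.35),
      target),
    head_motion = scale_rms(
      band_noise(n, c(0.5, 10), fs) * burst_envelope(n, 0.3, 0.3),
      2 * target),
    abort(sprintf("Unknown event type '%s'.", type))
  )
  wav
}

# Sequential event layout: shuffled event order, inter-event gaps drawn
# uniformly from gap_range; gaps rescaled proportionally if the drawn layout
# overruns the recording (durations are never shrunk).
place_events <- function(types, dur_samples, L, cfg) {
  k <- length(types)
  if (k == 0) {
    return(tibble(type = character(), onset = numeric(),
                  offset = numeric()))
  }
  ord <- sample.int(k)
  types <- types[ord]
  dur_samples <- dur_samples[ord]
  fs <- cfg$sampling_rate
  gaps <- round(runif(k + 1, cfg$gap_range[1], cfg$gap_range[2]) * fs)
  total <- sum(dur_samples) + sum(gaps)
  if (total > L) {
    avail <- L - sum(dur_samples)
    if (avail < 0) {
      abort("Sampled event durations exceed the recording length.")
    }
    gaps <- floor(gaps * (avail / sum(gaps)))
  }
  onset <- cumsum(gaps[seq_len(k)]) + c(0, cumsum(dur_samples))[seq_len(k)]
  tibble(type = types, onset = onset, offset = onset + dur_samples)
}

#' Generate one synthetic recording
#'
#' Builds a seeded multi-channel recording: Gaussian background noise plus
#' enveloped band-limited swallow bursts and distractor events. Per-type
#' event counts are Poisson draws around `rate * duration`, events are laid
#' out sequentially with uniform inter-event gaps, ground-truth annotations
#' exactly bracket the event envelopes, and events never overlap one
#' another.
#'
#' @param config A [synth_config()].
#' @param index Recording ordinal in `0:(n_recordings - 1)`; determines the
#'   per-recording derived seed.
#' @return A [new_recording()] object with id `"synth-<index>"`.
#' @export
generate_recording <- function(config, index = 0) {
  stopifnot(inherits(config, "synth_config"),
            index >= 0, index < config$n_recordings)
  fs <- config$sampling_rate
  L <- round(config$recording_duration * fs)
  chans <- hrca_channels[seq_len(config$n_channels)]
  gains <- config$channel_gains[chans]

  seed_i <- derive_seed(config$seed, index)
  withr::with_seed(seed_i, {
    sig <- matrix(rnorm(L * length(chans), sd = config$noise_sd),
                  nrow = L, dimnames = list(NULL, chans))
    lambda <- planned_event_counts(config)
    counts <- stats::rpois(length(lambda), lambda)
    types <- rep(names(lambda), counts)
    dur_ms <- numeric(length(types))
    n_sw <- sum(types == "swallow")
    if (n_sw > 0) dur_ms[types == "swallow"] <- draw_durations(config, n_sw)
    for (dt in names(config$distractor_spec)) {
      sel <- types == dt
      if (any(sel)) {
        rng <- config$distractor_spec[[dt]]$dur_range
        dur_ms[sel] <- runif(sum(sel), rng[1], rng[2])
      }
    }
    layout <- place_events(types, round(dur_ms / 1000 * fs), L, config)
    for (i in seq_len(nrow(layout))) {
      n_ev <- layout$offset[i] - layout$onset[i]
      wav <- synth_event_waveform(layout$type[i], n_ev, config)
      idx <- seq(layout$onset[i] + 1, layout$offset[i])
      for (ch in chans) sig[idx, ch] <- sig[idx, ch] + gains[[ch]] * wav
    }
  })

  lab <- ifelse(layout$type == "swallow", "single",
                paste0("nonswallow:", layout$type))
  ann <- segment_tbl(layout$onset, layout$offset, lab)
  new_recording(sprintf("synth-%03d", index), sig, fs, ann)
}

#' Generate a synthetic dataset
#'
#' @param config A [synth_config()].
#' @return A list with elements `recordings` (list of
#'   [new_recording()] objects) and `manifest` (tibble with one row per
#'   recording: id, sample count, event counts by type).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  recordings <- purrr::map(seq_len(config$n_recordings) - 1,
                           ~generate_recording(config, .x))
  manifest <- purrr::map_dfr(recordings, function(rec) {
    ann <- rec$annotations
    tibble(
      recording_id = rec$id,
      n_samples = n_samples(rec),
      sampling_rate = rec$sampling_rate,
      n_events = nrow(ann),
      n_swallow = sum(is_swallow_label(ann$label)),
      n_distractor = sum(!is_swallow_label(ann$label))
    )
  })
  list(recordings = recordings, manifest = manifest)
}
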