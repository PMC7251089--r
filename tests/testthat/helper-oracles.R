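# Independent oracles used across the suite. These deliberately avoid the
# package's FFT/overlap code paths: direct O(n^2) DFT sums and explicit
# per-sample enumeration.

# Magnitude of the direct DFT of a Hanning-tapered, zero-padded frame:
# |sum_m x[m] w[m] exp(-2 pi i k m / nfft)| for k = 0..nfft/2.
dft_frame_oracle <- function(frame, nfft = 512) {
  n <- length(frame)
  w <- if (n == 1) 1 else 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  xt <- frame * w
  m <- 0:(n - 1)
  vapply(0:(nfft / 2), function(k) {
    Mod(sum(xt * exp(-2i * pi * k * m / nfft)))
  }, numeric(1))
}

# Raw (untapered) periodogram magnitude at every DFT bin of a signal.
periodogram_oracle <- function(x) {
  n <- length(x)
  m <- 0:(n - 1)
  vapply(0:(n %/% 2), function(k) {
    Mod(sum(x * exp(-2i * pi * k * m / n)))^2 / n
  }, numeric(1))
}

# Mean power of `x` restricted to [f1, f2] Hz, via the direct periodogram.
band_power_oracle <- function(x, f1, f2, fs) {
  p <- periodogram_oracle(x)
  freq <- (seq_along(p) - 1) * fs / length(x)
  mean(p[freq >= f1 & freq <= f2])
}

# Number of integer sample positions shared by window [start, start + size)
# and segment [onset, offset), counted one by one.
overlap_count_oracle <- function(start, size, onset, offset) {
  win <- seq(start, start + size - 1)
  sum(win >= onset & win < offset)
}

# Brute-force window label: swallow iff some single swallow segment covers
# at least half the window's samples.
label_oracle <- function(start, size, annotations) {
  ann <- annotations[is_swallow_label(annotations$label), , drop = FALSE]
  best <- 0
  for (i in seq_len(nrow(ann))) {
    best <- max(best, overlap_count_oracle(start, size,
                                           ann$onset[i], ann$offset[i]))
  }
  if (best >= size / 2) "swallow" else "non_swallow"
}

# A tiny 4 kHz recording with hand-placed swallow segments: a strong
# band-limited tone burst per segment on top of faint noise.
make_toy_recording <- function(id = "toy", L = 8000, segments = NULL,
                               seed = 99, fs = 4000) {
  withr::with_seed(seed, {
    x <- rnorm(L, sd = 0.05)
    segments <- segments %||% segment_tbl(c(1600, 5200), c(3200, 6400))
    for (i in seq_len(nrow(segments))) {
      idx <- (segments$onset[i] + 1):segments$offset[i]
      tt <- seq_along(idx) / fs
      x[idx] <- x[idx] + sin(2 * pi * 300 * tt) + 0.5 * sin(2 * pi * 150 * tt)
    }
  })
  new_recording(id, matrix(x, dimnames = list(NULL, list("AP"))), fs,
                segments)
}

# Named recording list, as window_features() and the pipeline expect.
as_named_recs <- function(recs) {
  stats::setNames(recs, vapply(recs, function(r) r$id, character(1)))
}
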