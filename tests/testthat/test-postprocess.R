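# tone whose period (16 samples at 250 Hz / 4 kHz) divides the 160-sample
# frame, so every full frame of amplitude a has the same AUC, linear in a
frame_tone <- function(amps, fl = 160) {
  unlist(lapply(amps, function(a) a * sin(2 * pi * 250 * (0:(fl - 1)) / 4000)))
}

test_that("masks merge consecutive positive windows into segments", {
  spec <- window_spec(800, "none")
  m <- assemble_mask(c(0, 1, 1, 0), spec, 3200)
  expect_equal(m$segments$onset, 800)
  expect_equal(m$segments$offset, 2400)

  expect_equal(nrow(assemble_mask(rep(0, 4), spec, 3200)$segments), 0)
  all_on <- assemble_mask(rep(1, 4), spec, 3300)  # 100 trailing samples
  expect_equal(all_on$segments$onset, 0)
  expect_equal(all_on$segments$offset, 3200)

  half <- window_spec(800, "half")
  # windows 0-800 and 400-1200 positive: union, not intersection
  mh <- assemble_mask(c(1, 1, 0, 0, 0, 0, 0), half, 3200)
  expect_equal(mh$segments$onset, 0)
  expect_equal(mh$segments$offset, 1200)

  expect_error(assemble_mask(c(1, 0), spec, 3200), "decisions")
})

test_that("borders stay put when the flank AUC is below threshold", {
  # segment frames at amplitudes 1 and 0.6 -> threshold at 0.8 of the tone
  # AUC; flanks are silent
  x <- c(numeric(1600), frame_tone(c(1, 0.6, 0.6, 0.6, 1)), numeric(1600))
  mask <- assemble_mask(c(0, 0, 1, 0, 0), window_spec(800), length(x))
  out <- refine_borders(mask, x)
  expect_equal(out$segments, mask$segments)
  expect_equal(out$raw_segments, mask$segments)
})

test_that("the border walk extends frame-by-frame exactly as hand-simulated", {
  # 3 supra-threshold frames after the offset, then silence
  x <- c(numeric(1600), frame_tone(c(1, 0.6, 0.6, 0.6, 1)),
         frame_tone(c(1, 1, 1)), numeric(1600))
  spec <- window_spec(800)
  mask <- assemble_mask(c(0, 0, 1, 0, 0), spec, length(x))
  expect_equal(mask$segments$onset, 1600)
  out <- refine_borders(mask, x)

  # independent step-by-step walk of the extension rule
  fl <- 160
  auc_in <- auc_curve(x[1601:2400], fl)
  thr <- min(auc_in) + 0.5 * (max(auc_in) - min(auc_in))
  walk <- function(border, dir) {
    steps <- 0
    repeat {
      nxt <- if (dir < 0) border - (steps + 1) * fl else border + steps * fl
      if (steps >= 10 || nxt < 0 || nxt + fl > length(x)) break
      if (auc_curve(x[(nxt + 1):(nxt + fl)], fl) < thr) break
      steps <- steps + 1
    }
    steps
  }
  expect_equal(walk(1600, -1), 0)
  expect_equal(walk(2400, +1), 3)
  expect_equal(out$segments$onset, 1600)
  expect_equal(out$segments$offset, 2400 + 3 * fl)
})

test_that("extension is capped at two windows per side and merges touches", {
  # uniform tone everywhere: every flank frame passes the threshold
  x <- frame_tone(rep(1, 50))  # 8000 samples
  spec <- window_spec(800)
  mask <- assemble_mask(c(0, 0, 0, 0, 1, 0, 0, 0, 0, 0), spec, length(x))
  out <- refine_borders(mask, x)
  expect_equal(out$segments$onset, 3200 - 1600)  # capped at 2N
  expect_equal(out$segments$offset, 4000 + 1600)

  # two segments whose extensions touch must merge
  mask2 <- assemble_mask(c(0, 0, 1, 0, 1, 0, 0, 0, 0, 0), spec, length(x))
  out2 <- refine_borders(mask2, x)
  expect_equal(nrow(out2$segments), 1)
})

test_that("refinement is monotone and keeps segments disjoint and sorted", {
  withr::with_seed(31, {
    for (rep in 1:10) {
      x <- rnorm(8000)
      dec <- runif(10) < 0.4
      mask <- assemble_mask(dec, window_spec(800), 8000)
      out <- refine_borders(mask, x)
      segs <- out$segments
      if (nrow(segs) > 1) {
        expect_true(all(segs$onset[-1] >= segs$offset[-nrow(segs)]))
        expect_false(is.unsorted(segs$onset))
      }
      # every raw segment is contained in some refined segment
      raw <- out$raw_segments
      for (i in seq_len(nrow(raw))) {
        covered <- any(segs$onset <= raw$onset[i] &
                         segs$offset >= raw$offset[i])
        expect_true(covered)
        # and no border moved further than 2 windows
        j <- which(segs$onset <= raw$onset[i] & segs$offset >= raw$offset[i])[1]
        expect_lte(raw$onset[i] - segs$onset[j], 1600 +
                     (raw$onset[i] - min(raw$onset)))
      }
    }
  })
})
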