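test_that("window metrics report confusion ratios with NA when undefined", {
  mixed <- c("swallow", "non_swallow", "swallow", "non_swallow")
  perfect <- window_metrics(mixed, mixed)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$tp + perfect$tn + perfect$fp + perfect$fn, 4)

  m <- window_metrics(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(unlist(m[, c("tp", "fp", "tn", "fn")]),
               c(tp = 1, fp = 1, tn = 1, fn = 1))
  expect_equal(m$accuracy, 0.5)

  allneg <- window_metrics(c(0, 0, 1), c(0, 0, 0))
  expect_true(is.na(allneg$sensitivity))
  expect_equal(allneg$specificity, 2 / 3)
  expect_error(window_metrics(c(1, 0), c(1, 0, 0)), "equal length")
})

test_that("default criteria carry the clinical overlap constants", {
  crit <- detection_criteria()
  expect_equal(crit$value[crit$kind == "fixed_msec"], c(431.89, 675.56))
  expect_equal(crit$value[crit$kind == "fraction_of_reference"],
               c(0.90, 0.95))
  expect_error(detection_criteria(fractions = 1.2), "Fraction")
})

test_that("detection decisions follow the overlap criteria", {
  fs <- 4000
  crit <- detection_criteria()
  ref <- segment_tbl(400, 3600)              # 100..900 ms -> 800 ms
  det <- tibble::tibble(onset = 0, offset = 4000)  # 0..1000 ms
  r90 <- detect_swallows(det, ref, crit[3, ], fs)
  expect_true(r90$detected)                  # overlap 800 >= 720
  expect_equal(r90$overlap_ms, 800)

  # overlap 400 ms below the fixed 431.89 ms criterion
  short <- tibble::tibble(onset = 400, offset = 2000)
  r2sd <- detect_swallows(short, ref, crit[1, ], fs)
  expect_false(r2sd$detected)
  expect_equal(r2sd$required_ms, 431.89)

  # fixed criterion capped at the reference duration: a fully covered
  # 320 ms swallow counts as detected
  tiny <- segment_tbl(0, 1280)
  rcap <- detect_swallows(det, tiny, crit[1, ], fs)
  expect_equal(rcap$required_ms, 320)
  expect_true(rcap$detected)

  none <- detect_swallows(det[0, ], ref, crit[1, ], fs)
  expect_false(none$detected)
  expect_true(is.na(none$matched_duration_ms))
})

test_that("detection agrees with the exhaustive sample-counting oracle", {
  fs <- 4000
  crit <- detection_criteria()
  withr::with_seed(77, {
    for (rep in 1:150) {
      ro <- sample(0:4000, 1); rd <- sample(800:4000, 1)
      ref <- segment_tbl(ro, ro + rd)
      k <- sample(0:3, 1)
      det <- if (k == 0) tibble::tibble(onset = numeric(0),
                                        offset = numeric(0)) else {
        o <- sort(sample(0:9000, k))
        tibble::tibble(onset = o, offset = o + sample(200:5000, k))
      }
      best <- 0
      for (j in seq_len(nrow(det))) {
        best <- max(best, overlap_count_oracle(det$onset[j],
                                               det$offset[j] - det$onset[j],
                                               ref$onset, ref$offset))
      }
      ci <- sample(1:4, 1)
      res <- detect_swallows(det, ref, crit[ci, ], fs)
      dur_ms <- rd / fs * 1000
      req_ms <- if (crit$kind[ci] == "fixed_msec") {
        min(crit$value[ci], dur_ms)
      } else {
        crit$value[ci] * dur_ms
      }
      expect_equal(res$detected, best / fs * 1000 >= req_ms)
    }
  })
})

test_that("tightening a criterion never increases the detected fraction", {
  fs <- 4000
  crit <- detection_criteria()
  withr::with_seed(55, {
    for (rep in 1:30) {
      n_ref <- sample(3:8, 1)
      on <- cumsum(sample(7000:12000, n_ref))
      ref <- segment_tbl(on, on + sample(1800:6000, n_ref, replace = TRUE))
      o <- pmax(0, on + sample(-800:800, n_ref))
      det <- tibble::tibble(onset = o, offset = o + sample(1000:7000, n_ref))
      frac <- vapply(seq_len(nrow(crit)), function(i) {
        mean(detect_swallows(det, ref, crit[i, ], fs)$detected)
      }, numeric(1))
      # pointwise-comparable pairs: 2 SD <= 1 SD, 90% <= 95% requirements
      expect_gte(frac[1], frac[2])
      expect_gte(frac[3], frac[4])
      expect_true(all(frac >= 0 & frac <= 1))
    }
  })
})

test_that("detection summaries use the population SD convention", {
  ref <- segment_tbl(c(0, 10000), c(4000, 18000))  # 1000 ms and 2000 ms
  det <- tibble::tibble(onset = c(0, 10000), offset = c(4000, 18000))
  s <- summarize_detections(det, ref, sampling_rate = 4000)
  expect_true(all(s$detected_fraction == 1))
  expect_equal(s$mean_duration_ms[1], 1500)
  expect_equal(s$sd_duration_ms[1], 500)  # population SD, divisor n
  expect_error(summarize_detections(det, ref[0, ]), "reference")
})
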