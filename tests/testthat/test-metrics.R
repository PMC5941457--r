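flat_rec <- function(values, times = 0:10, leads = paste0("E", seq_len(nrow(values))),
                     j_point = 2) {
  ecg_recording(values, times, leads, "electrodes", qrs_onset = 0,
                j_point = j_point)
}

test_that("the T-wave window ends when the across-lead RMS settles", {
  # half-sine T wave, peak 0.3 mV, zero afterwards
  tt <- 0:100
  s <- numeric(101)
  s[tt >= 10 & tt <= 50] <- 0.3 * sin(pi * (tt[tt >= 10 & tt <= 50] - 10) / 40)
  rec <- flat_rec(matrix(s, 1), times = tt, j_point = 10)
  w <- find_twave_window(rec)
  expect_equal(w$t_start, 10)
  # direct-scan oracle: first sample after the peak with |s| <= 0.005
  peak <- which.max(abs(s))
  oracle <- tt[which(abs(s) <= 0.005 & seq_along(s) > peak)[1]]
  expect_equal(w$t_end, oracle)

  # identically zero after J: the window closes at the next sample
  rec0 <- flat_rec(matrix(0, 1, 101), times = tt, j_point = 10)
  expect_equal(find_twave_window(rec0)$t_end, 11)

  # a signal that never settles is an error
  recc <- flat_rec(matrix(0.1, 1, 101), times = tt, j_point = 10)
  expect_error(find_twave_window(recc), "settle")
})

test_that("t_mean is the sample mean of the window", {
  expect_equal(t_mean(c(1, 2, 3)), 2)
  expect_equal(t_mean(rep(0, 7)), 0)
  expect_equal(t_mean(0.25), 0.25)
  expect_error(t_mean(numeric(0)), "empty")
})

test_that("TWA amplitude is the absolute mean difference, per lead", {
  expect_equal(twa_amplitude(0.5, 0.3), 0.2)
  expect_equal(twa_amplitude(c(1, 2), c(1, 2)), c(0, 0))
  expect_equal(twa_amplitude(c(1, 2), c(2, 1)), twa_amplitude(c(2, 1), c(1, 2)))
  expect_error(twa_amplitude(1:3, 1:2), "dimension")
})

test_that("VMA is the norm of the difference divided by the lead count", {
  expect_equal(vma(c(3, 4), c(0, 0)), 2.5)
  expect_equal(vma(c(1, 1), c(1, 1)), 0)
  delta <- 0.02
  expect_equal(vma(rep(delta, 192), rep(0, 192)), delta / sqrt(192))
  expect_error(vma(1, 2, n = 0), "positive")
})

test_that("VAA is the angle between the mean T-wave vectors", {
  expect_equal(vaa(c(1, 0), c(2, 0)), 0)
  expect_equal(vaa(c(1, 0), c(0, 3)), pi / 2)
  expect_equal(vaa(c(1, 1), c(-2, -2)), pi)
  expect_equal(vaa(c(1, 2, 3), c(1, 2, 3)), 0)   # clamped against fp overshoot
  expect_error(vaa(c(0, 0), c(1, 0)), "zero mean")
  expect_equal(vaa(c(0, 0), c(0, 0)), 0)  # identical null beats
})

test_that("VMA and TWA scale with the signals while VAA is scale-invariant", {
  set.seed(3)
  a <- rnorm(12); b <- rnorm(12)
  for (k in c(0.5, 2, 10)) {
    expect_equal(vma(k * a, k * b), k * vma(a, b))
    expect_equal(twa_amplitude(k * a, k * b), k * twa_amplitude(a, b))
    expect_equal(vaa(k * a, k * b), vaa(a, b))
  }
})

test_that("max_twa_lead uses canonical ordering for ties", {
  amps <- setNames(rep(0, 12), c("I", "II", "III", "aVR", "aVL", "aVF",
                                 paste0("V", 1:6)))
  expect_equal(max_twa_lead(amps), "I")
  amps["V1"] <- 0.02
  expect_equal(max_twa_lead(amps), "V1")
  amps2 <- amps; amps2["II"] <- 0.02
  expect_equal(max_twa_lead(amps2), "II")  # earlier canonical lead wins the tie
})

test_that("detection threshold is 10 uV, boundary inclusive", {
  f <- fixture("tiny")
  pair <- simulate_beat_pair(f$model, f$activation, f$tm,
                             scenario_spec("APD", "CONC", "L5"),
                             layer_table = f$layer_table, gain = f$gain,
                             block_mm = f$block_mm)
  r <- compute_twa(pair, "12lead")
  expect_identical(r$detected, r$amplitudes >= 0.010)
  # boundary: an amplitude of exactly 0.010 mV counts as detected
  r2 <- compute_twa(pair, "12lead", detection_threshold = max(r$amplitudes))
  expect_true(r2$detected[which.max(r$amplitudes)])
})

test_that("QT interval and QT alternans follow the annotations", {
  tt <- 0:100
  s <- numeric(101)
  s[tt >= 10 & tt <= 50] <- 0.3 * sin(pi * (tt[tt >= 10 & tt <= 50] - 10) / 40)
  rec <- flat_rec(matrix(s, 1), times = tt, j_point = 10)
  w <- find_twave_window(rec)
  expect_equal(qt_interval(rec), w$t_end - 0)
  rec$qrs_onset <- NULL
  expect_error(qt_interval(rec), "annotation")

  f <- fixture("tiny")
  pair <- simulate_beat_pair(f$model, f$activation, f$tm,
                             scenario_spec("APD", "CONC", "L5", magnitude = 0),
                             layer_table = f$layer_table, gain = f$gain,
                             block_mm = f$block_mm)
  expect_equal(qt_alternans(pair), 0)
})

test_that("BSPM maps arrange amplitudes on the 12 x 16 electrode grid", {
  flat <- bspm_twa_map(rep(0.02, 192))
  expect_equal(flat$min, flat$max)
  amps <- rep(0, 192)
  amps[(4 - 1) * 16 + 7] <- 1  # row 4, column 7 in row-major order
  mp <- bspm_twa_map(amps)
  expect_equal(which(mp$map == 1, arr.ind = TRUE)[1, ], c(row = 4, col = 7))
  expect_error(bspm_twa_map(rep(0, 100)), "expected 192")
  expect_equal(map_similarity(mp, mp), 1)
})
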