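make_electrode_rec <- function(values, n_t = 4) {
  leads <- c("RA", "LA", "LL", "RL", paste0("V", 1:6))
  sig <- matrix(rep(values, n_t), nrow = length(leads))
  ecg_recording(sig, seq_len(n_t), leads, "electrodes")
}

test_that("12-lead derivation follows the standard lead algebra", {
  rec <- make_electrode_rec(c(RA = 1, LA = 0, LL = 0, RL = 0,
                              V1 = 0, V2 = 0, V3 = 0, V4 = 0, V5 = 0, V6 = 0))
  l <- derive_12lead(rec)
  expect_equal(unname(l$signals[c("I", "II", "III", "aVR", "aVL", "aVF"), 1]),
               c(-1, -1, 0, 1, -0.5, -0.5))
  # precordials referenced to the Wilson central terminal
  expect_equal(unname(l$signals["V1", 1]), 0 - 1 / 3)

  # all-equal electrode potentials give all-zero leads
  l0 <- derive_12lead(make_electrode_rec(rep(2.5, 10)))
  expect_equal(max(abs(l0$signals)), 0)
})

test_that("the Einthoven identity holds exactly on simulated recordings", {
  f <- fixture("tiny")
  pair <- simulate_beat_pair(f$model, f$activation, f$tm,
                             scenario_spec("APD", "CONC", "L5"),
                             layer_table = f$layer_table, gain = f$gain,
                             block_mm = f$block_mm)
  for (rec in beat_pair_leads(pair, "12lead")) {
    # III = II - I holds bit for bit by construction
    expect_identical(rec$signals["III", ],
                     rec$signals["II", ] - rec$signals["I", ])
    expect_equal(rec$signals["I", ] + rec$signals["III", ],
                 rec$signals["II", ], tolerance = 1e-14)
  }
})

test_that("missing electrodes are reported", {
  rec <- make_electrode_rec(rep(0, 10))
  rec$leads[1] <- "XX"
  rownames(rec$signals)[1] <- "XX"
  expect_error(derive_12lead(rec), "missing electrodes: RA")
})

test_that("VCG leads are the components of the total heart vector", {
  # hand-built sequence: two blocks, x-directed moments only
  sq <- structure(list(times = 0:3,
                       moments = rbind(c(1, 2, 3, 4), 0, 0,
                                       c(4, 3, 2, 1), 0, 0),
                       positions = matrix(0, 2, 3), n_blocks = 2L,
                       gain = 1, block_mm = 5),
                  class = "dipole_sequence")
  v <- derive_vcg(sq)
  expect_equal(unname(v$signals["X", ]), c(5, 5, 5, 5))
  expect_equal(max(abs(v$signals[c("Y", "Z"), ])), 0)

  # rotating every moment rotates the VCG identically
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  sq_rot <- sq
  for (b in 1:2) {
    rows <- (3 * (b - 1) + 1):(3 * b)
    sq_rot$moments[rows, ] <- R %*% sq$moments[rows, ]
  }
  expect_equal(derive_vcg(sq_rot)$signals, R %*% v$signals,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a uniform AP field yields a null VCG", {
  mask <- array(TRUE, c(4, 4, 4))
  m <- toy_model(mask)
  asg <- structure(list(group = rep(1L, m$n_nodes),
                        templates = list(ap_template())),
                   class = "ap_assignment")
  sq <- build_sequence(m, uniform_activation(m), asg, seq(0, 400, 50),
                       gain = 1, block_mm = 2, weights = rep(1, m$n_nodes))
  expect_equal(max(abs(derive_vcg(sq)$signals)), 0)
})

test_that("the BSPM view extracts the 192-electrode grid", {
  f <- fixture("tiny")
  pair <- simulate_beat_pair(f$model, f$activation, f$tm,
                             scenario_spec("APD", "CONC", "L5", magnitude = 0),
                             layer_table = f$layer_table, gain = f$gain,
                             block_mm = f$block_mm)
  b <- beat_pair_leads(pair, "bspm")
  expect_equal(length(b$even$leads), 192)
  expect_equal(b$even$lead_system, "bspm")
})
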