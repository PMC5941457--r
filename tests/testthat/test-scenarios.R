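test_that("the scenario catalog enumerates the full protocol", {
  specs <- scenario_catalog()
  expect_length(specs, 72)  # 14 APD topologies x 4 layers + 4 amplitude x 4
  ids <- vapply(specs, scenario_id, character(1))
  expect_false(any(duplicated(ids)))
  expect_length(scenario_catalog(layers = "L5"), 18)
  expect_length(scenario_catalog(mechanisms = character(0)), 0)
  expect_length(scenario_catalog("APD"), 56)
  expect_length(scenario_catalog("AMPLITUDE"), 16)
})

test_that("default magnitudes follow the protocol", {
  expect_equal(scenario_spec("APD", "CONC", "L5")$magnitude, 0.04)
  expect_equal(scenario_spec("APD", "D_L/R", "L3")$magnitude, 0.04)
  expect_equal(scenario_spec("APD", "R_ANT", "L2")$magnitude, 0.10)
  expect_equal(scenario_spec("AMPLITUDE", "CONC", "L4")$magnitude, 0.10)
  expect_error(scenario_spec("APD", "CONC", "L1"), "L2..L5")
  expect_error(scenario_spec("APD", "NOWHERE", "L5"), "topology")
})

test_that("concordant APD assignment shortens even beats and lengthens odd beats", {
  m <- fixture("tiny")$model
  tab <- layer_ap_table()
  sp <- scenario_spec("APD", "CONC", "L5")
  for (parity in c("even", "odd")) {
    a <- assign_ap(m, tab, sp, parity)
    target <- m$layer == 5L
    fac <- if (parity == "even") 0.96 else 1.04
    expect_equal(a$templates[[unique(a$group[target])]]$apd,
                 tab$L5$apd * fac)
    # all other nodes keep their reference layer templates
    expect_identical(a$group[!target], m$layer[!target])
  }
})

test_that("discordant APD assignment is phase-opposed and swaps with parity", {
  m <- fixture("tiny")$model
  tab <- layer_ap_table()
  sp <- scenario_spec("APD", "D_L/R", "L2")
  ae <- assign_ap(m, tab, sp, "even")
  ao <- assign_ap(m, tab, sp, "odd")
  pair <- select_region(m, "D_L/R")
  lv2 <- pair$a & m$layer == 2L
  rv2 <- pair$b & m$layer == 2L
  apd_of <- function(a, mask) a$templates[[unique(a$group[mask])]]$apd
  expect_equal(apd_of(ae, lv2), tab$L2$apd * 0.96)
  expect_equal(apd_of(ae, rv2), tab$L2$apd * 1.04)
  expect_equal(apd_of(ao, lv2), tab$L2$apd * 1.04)
  expect_equal(apd_of(ao, rv2), tab$L2$apd * 0.96)
  # locality: nodes outside the target layer are untouched in both parities
  out <- m$layer != 2L
  expect_identical(ae$group[out], ao$group[out])
})

test_that("amplitude alternans applies only to the odd beat for concordant topologies", {
  m <- fixture("tiny")$model
  tab <- layer_ap_table()
  sp <- scenario_spec("AMPLITUDE", "CONC", "L3")
  ae <- assign_ap(m, tab, sp, "even")
  expect_identical(ae$group, ap_assignment(m, tab)$group)  # reference beat
  ao <- assign_ap(m, tab, sp, "odd")
  g <- unique(ao$group[m$layer == 3L])
  expect_equal(ao$templates[[g]]$p2_factor, 0.9)
  expect_equal(ao$templates[[g]]$apd, tab$L3$apd)  # APD untouched
})

test_that("a null scenario reproduces the reference beat sample for sample", {
  f <- fixture("tiny")
  sp <- scenario_spec("APD", "CONC", "L5", magnitude = 0)
  pair <- simulate_beat_pair(f$model, f$activation, f$tm, sp,
                             layer_table = f$layer_table, gain = f$gain,
                             block_mm = f$block_mm)
  expect_identical(pair$even$signals, pair$odd$signals)
  expect_identical(pair$vcg_even$signals, pair$vcg_odd$signals)
})

test_that("doubling the APD alternans magnitude does not decrease the maximal TWA", {
  f <- fixture("tiny")
  for (tp in c("CONC", "D_L/R", "D_P/A")) {
    a1 <- compute_twa(simulate_beat_pair(
      f$model, f$activation, f$tm,
      scenario_spec("APD", tp, "L5", magnitude = 0.02),
      layer_table = f$layer_table, gain = f$gain, block_mm = f$block_mm), "bspm")
    a2 <- compute_twa(simulate_beat_pair(
      f$model, f$activation, f$tm,
      scenario_spec("APD", tp, "L5", magnitude = 0.04),
      layer_table = f$layer_table, gain = f$gain, block_mm = f$block_mm), "bspm")
    expect_gte(max(a2$amplitudes), max(a1$amplitudes))
  }
})

test_that("lengthened epicardial APD shifts the T peak later", {
  f <- fixture("small")
  pair <- simulate_beat_pair(f$model, f$activation, f$tm,
                             scenario_spec("APD", "CONC", "L5"),
                             layer_table = f$layer_table, gain = f$gain,
                             block_mm = f$block_mm)
  l <- beat_pair_leads(pair, "12lead")
  peak_t <- function(rec) {
    rms <- sqrt(colMeans(rec$signals^2))
    rms[rec$times <= pair$j_point] <- 0
    rec$times[which.max(rms)]
  }
  expect_gt(peak_t(l$odd), peak_t(l$even))
})
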