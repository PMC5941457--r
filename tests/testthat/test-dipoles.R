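test_that("a spatially uniform potential field produces exactly zero dipoles", {
  mask <- array(TRUE, c(5, 5, 5))
  m <- toy_model(mask)
  asg <- structure(list(group = rep(1L, m$n_nodes),
                        templates = list(ap_template())),
                   class = "ap_assignment")
  act <- uniform_activation(m)  # everyone activated together
  for (t in c(-10, 50, 150, 600)) {
    d <- dipoles_at(m, act, asg, t, gain = 1, weights = rep(1, m$n_nodes))
    expect_equal(max(abs(d)), 0)
  }
})

test_that("node dipoles equal an independent finite-difference computation", {
  set.seed(11)
  mask <- array(runif(5^3) < 0.8, c(5, 5, 5))
  m <- toy_model(mask)
  asg <- structure(list(group = rep(1L, m$n_nodes),
                        templates = list(ap_template())),
                   class = "ap_assignment")
  act <- structure(list(time = runif(m$n_nodes, 0, 30),
                        unreachable = rep(FALSE, m$n_nodes),
                        start_rows = 1L, onsets = 0,
                        cfg = propagation_config()),
                   class = "activation_map")
  t0 <- 40
  gain <- 2.5
  d <- dipoles_at(m, act, asg, t0, gain = gain, weights = rep(1, m$n_nodes))

  # oracle: sample each node's template value, then accumulate face moments
  # gain * (V_i - V_j) / 2 onto both face nodes, one-sided at boundaries
  # reproduce the 0.5 ms curve sampling used by the engine
  Vs <- approx(seq(0, ap_template()$t_full_repol + 2, by = 0.5),
               ap_value(ap_template(), seq(0, ap_template()$t_full_repol + 2, by = 0.5)),
               xout = pmax(t0 - act$time, 0))$y
  oracle <- matrix(0, m$n_nodes, 3)
  for (ax in 1:3) {
    plus <- m$neighbors[, 2 * ax]
    has <- !is.na(plus)
    u <- which(has); v <- plus[has]
    mom <- 0.5 * gain * (Vs[u] - Vs[v])
    for (k in seq_along(u)) {
      oracle[u[k], ax] <- oracle[u[k], ax] + mom[k]
      oracle[v[k], ax] <- oracle[v[k], ax] + mom[k]
    }
  }
  expect_equal(d, oracle, tolerance = 1e-12)
})

test_that("interior faces of a uniform block telescope to zero net moment", {
  mask <- array(TRUE, c(6, 6, 6))
  m <- toy_model(mask)
  asg <- structure(list(group = rep(1L, m$n_nodes),
                        templates = list(ap_template())),
                   class = "ap_assignment")
  # linear-in-x activation field gives a uniform x-gradient in V
  act <- structure(list(time = m$coords[, 1] * 2,
                        unreachable = rep(FALSE, m$n_nodes), start_rows = 1L,
                        onsets = 0, cfg = propagation_config()),
                   class = "activation_map")
  d <- dipoles_at(m, act, asg, 20, gain = 1, weights = rep(1, m$n_nodes))
  # summed moment equals the boundary (one-sided) terms only: compare against
  # direct summation of face moments, which telescopes internally
  Vs <- ap_value(ap_template(), 20 - act$time)
  total_x <- 0
  plus <- m$neighbors[, 2]
  has <- !is.na(plus)
  total_x <- sum(Vs[which(has)] - Vs[plus[has]])
  expect_equal(sum(d[, 1]), total_x, tolerance = 1e-9)
})

test_that("dipole sequence is linear in the gain and silent outside the beat", {
  f <- fixture("tiny")
  asg <- ap_assignment(f$model, f$layer_table)
  tg <- seq(0, 540, by = 10)
  s1 <- build_sequence(f$model, f$activation, asg, tg, gain = 1,
                       block_mm = f$block_mm)
  s2 <- build_sequence(f$model, f$activation, asg, tg, gain = 2,
                       block_mm = f$block_mm)
  expect_equal(s2$moments, 2 * s1$moments, tolerance = 1e-12)
  # zero columns up to the earliest activation and after full repolarization
  expect_equal(max(abs(s1$moments[, tg <= min(f$activation$time)])), 0)
  t_last <- max(f$activation$time) +
    max(vapply(f$layer_table, `[[`, numeric(1), "t_full_repol"))
  expect_equal(max(abs(s1$moments[, tg > t_last])), 0)
  expect_error(build_sequence(f$model, f$activation, asg, numeric(0)), "empty")
})

test_that("block aggregation preserves the far field within 3% RMS", {
  f <- fixture("tiny")
  asg <- ap_assignment(f$model, f$layer_table)
  tg <- seq(0, 540, by = 5)
  sq_agg <- build_sequence(f$model, f$activation, asg, tg, gain = f$gain,
                           block_mm = 8)
  sq_fine <- build_sequence(f$model, f$activation, asg, tg, gain = f$gain,
                            block_mm = f$model$resolution)
  bl_agg <- source_blocks(f$model, 8)
  bl_fine <- source_blocks(f$model, f$model$resolution)
  tm_agg <- build_transfer_matrix(f$torso, heart_to_torso(f$model, bl_agg$centers))
  tm_fine <- build_transfer_matrix(f$torso, heart_to_torso(f$model, bl_fine$centers))
  ra <- forward(tm_agg, sq_agg)$signals
  rf <- forward(tm_fine, sq_fine)$signals
  expect_lt(sqrt(mean((ra - rf)^2)) / sqrt(mean(rf^2)), 0.03)
  # aggregation also conserves the total heart vector exactly
  expect_equal(total_heart_vector(sq_agg), total_heart_vector(sq_fine),
               tolerance = 1e-9)
})
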