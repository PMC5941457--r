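test_that("travel time equals distance over velocity on a free straight line", {
  mask <- array(FALSE, c(31, 3, 3))
  mask[, 2, 2] <- TRUE
  m <- toy_model(mask)
  cfg <- propagation_config(velocity = 0.5, l1_multiplier = 3,
                            sites = m$coords[1, , drop = FALSE])
  act <- compute_activation(m, cfg)
  # node 21 lies 20 mm down the line: 20 mm / 0.5 mm/ms = 40 ms
  expect_equal(act$time[21], 20 / 0.5, tolerance = 1e-12)
  # an L1 path is three times faster: 15 mm at 1.5 mm/ms = 10 ms
  m1 <- toy_model(mask, layer = 1L)
  act1 <- compute_activation(m1, cfg)
  expect_equal(act1$time[16], 15 / 1.5, tolerance = 1e-12)
})

test_that("activation times match an independent shortest-path solver", {
  skip_if_not_installed("igraph")
  set.seed(7)
  mask <- array(runif(20^3) < 0.6, c(20, 20, 20))
  mask[10, 10, 10] <- TRUE
  m <- toy_model(mask, layer = array(sample(1:5, 20^3, TRUE), c(20, 20, 20)))
  start <- m$coords[which(m$ijk[, 1] == 9 & m$ijk[, 2] == 9 & m$ijk[, 3] == 9), , drop = FALSE]
  cfg <- propagation_config(sites = start)
  act <- compute_activation(m, cfg)

  # brute-force oracle: explicit weighted graph over the same 26-neighbourhood
  sp <- ifelse(m$layer == 1L, 1.5, 0.5)
  edges <- NULL; w <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    ii <- m$ijk[, 1] + dx; jj <- m$ijk[, 2] + dy; kk <- m$ijk[, 3] + dz
    ok <- ii >= 0 & ii < 20 & jj >= 0 & jj < 20 & kk >= 0 & kk < 20
    lin <- ii[ok] + 20 * (jj[ok] + 20 * kk[ok]) + 1
    row_of <- integer(20^3); row_of[m$grid_index] <- seq_len(m$n_nodes)
    tgt <- row_of[lin]
    keep <- tgt > 0
    src <- which(ok)[keep]; tgt <- tgt[keep]
    len <- sqrt(dx^2 + dy^2 + dz^2)
    edges <- rbind(edges, cbind(src, tgt))
    w <- c(w, len / (0.5 * (sp[src] + sp[tgt])))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  srow <- which(m$ijk[, 1] == 9 & m$ijk[, 2] == 9 & m$ijk[, 3] == 9)
  d <- as.numeric(igraph::distances(g, v = srow, algorithm = "dijkstra"))
  # duplicated undirected edges do not change shortest paths
  comparable <- is.finite(d) & is.finite(act$time)
  expect_equal(act$time[comparable], d[comparable], tolerance = 1e-9)
  expect_equal(is.finite(act$time), is.finite(d))
})

test_that("doubling the velocity halves all travel times", {
  mask <- array(TRUE, c(10, 10, 10))
  m <- toy_model(mask)
  s <- m$coords[1, , drop = FALSE]
  a1 <- compute_activation(m, propagation_config(velocity = 0.5, sites = s))
  a2 <- compute_activation(m, propagation_config(velocity = 1.0, sites = s))
  expect_equal(a2$time, a1$time / 2, tolerance = 1e-12)
})

test_that("isochrones in a homogeneous block are spherical within a voxel", {
  mask <- array(TRUE, c(21, 21, 21))
  m <- toy_model(mask)
  center <- m$coords[which(m$ijk[, 1] == 10 & m$ijk[, 2] == 10 & m$ijk[, 3] == 10), , drop = FALSE]
  act <- compute_activation(m, propagation_config(velocity = 1, sites = center))
  eu <- sqrt(colSums((t(m$coords) - as.numeric(center))^2))
  # graph distance slightly overestimates Euclidean distance; the worst-case
  # 26-neighbour chamfer ratio is ~1.125 (realised near direction (2,1,1))
  expect_true(all(act$time >= eu - 1e-9))
  expect_lt(max(act$time[eu > 0] / eu[eu > 0]), 1.13)
  # within one voxel for radii below the anisotropy horizon
  near <- eu > 0 & eu <= 7
  expect_lt(max(act$time[near] - eu[near]), 1)
})

test_that("neighbouring activation times satisfy the edge travel-time bound", {
  f <- fixture("tiny")
  m <- f$model; act <- f$activation
  sp <- ifelse(m$layer == 1L, 1.5, 0.5)
  for (d in 1:6) {
    has <- !is.na(m$neighbors[, d])
    u <- which(has); v <- m$neighbors[has, d]
    w <- m$resolution / (0.5 * (sp[u] + sp[v]))
    expect_true(all(abs(act$time[u] - act$time[v]) <= w + 1e-9))
  }
})

test_that("qrs_end is the last upstroke completion and rejects unreachable maps", {
  mask <- array(FALSE, c(9, 3, 3))
  mask[1:3, 2, 2] <- TRUE; mask[7:9, 2, 2] <- TRUE  # two islands
  m <- toy_model(mask)
  act <- compute_activation(m, propagation_config(sites = m$coords[1, , drop = FALSE]))
  expect_true(any(act$unreachable))
  expect_error(qrs_end(act), "unreachable")

  f <- fixture("tiny")
  expect_equal(qrs_end(f$activation, upstroke = 2), max(f$activation$time) + 2)
  expect_false(any(f$activation$unreachable))
})

test_that("a pacing site outside the myocardium is rejected", {
  f <- fixture("tiny")
  expect_error(
    compute_activation(f$model,
                       propagation_config(sites = matrix(c(500, 500, 500), 1))),
    "outside the myocardium")
})
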