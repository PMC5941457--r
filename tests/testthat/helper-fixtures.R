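# Shared fixtures, built once per test run on first use.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(size = "tiny") {
  if (is.null(.fixture_env[[size]]))
    .fixture_env[[size]] <- make_fixtures(size)
  .fixture_env[[size]]
}

# the default 1 mm model (used by the geometry acceptance checks)
default_model_1mm <- function() {
  if (is.null(.fixture_env$m1)) {
    .fixture_env$m1 <- build_heart_model(grid_spec(1), ellipsoid_params())
  }
  .fixture_env$m1
}

# TWA results over the APD scenario catalog on the small (2 mm) fixture,
# for both 12-lead and BSPM systems
apd_catalog_results <- function() {
  if (is.null(.fixture_env$catalog)) {
    f <- fixture("small")
    out <- list()
    for (sp in scenario_catalog("APD")) {
      pair <- simulate_beat_pair(f$model, f$activation, f$tm, sp,
                                 layer_table = f$layer_table,
                                 gain = f$gain, block_mm = f$block_mm)
      out[[scenario_id(sp)]] <- list(
        spec = sp,
        lead12 = compute_twa(pair, "12lead"),
        bspm = compute_twa(pair, "bspm"))
    }
    .fixture_env$catalog <- out
  }
  .fixture_env$catalog
}

# minimal voxel model on an arbitrary mask, for controlled propagation and
# dipole tests; mask is a 3-d logical array, layer an integer array or scalar
toy_model <- function(mask, resolution = 1, layer = 2L) {
  dims <- dim(mask)
  idx <- which(mask)
  lin <- idx - 1L
  i <- lin %% dims[1]
  rest <- lin %/% dims[1]
  j <- rest %% dims[2]
  k <- rest %/% dims[2]
  coords <- cbind((i + 0.5) * resolution, (j + 0.5) * resolution,
                  (k + 0.5) * resolution)
  row_of <- integer(prod(dims))
  row_of[idx] <- seq_along(idx)
  nbr <- matrix(NA_integer_, length(idx), 6L)
  offs <- list(c(-1L,0L,0L), c(1L,0L,0L), c(0L,-1L,0L),
               c(0L,1L,0L), c(0L,0L,-1L), c(0L,0L,1L))
  for (d in seq_along(offs)) {
    ii <- i + offs[[d]][1]; jj <- j + offs[[d]][2]; kk <- k + offs[[d]][3]
    ok <- ii >= 0L & ii < dims[1] & jj >= 0L & jj < dims[2] & kk >= 0L & kk < dims[3]
    lin2 <- ii[ok] + dims[1] * (jj[ok] + dims[2] * kk[ok]) + 1L
    r <- row_of[lin2]; r[r == 0L] <- NA_integer_
    nbr[ok, d] <- r
  }
  lay <- if (length(layer) == 1L) rep(as.integer(layer), length(idx))
  else as.integer(layer[idx])
  structure(list(
    dims = as.integer(dims), origin = c(0, 0, 0), resolution = resolution,
    grid_index = idx, ijk = cbind(i = i, j = j, k = k),
    coords = coords, lambda = rep(0.5, length(idx)),
    layer = lay, ventricle = rep("LV", length(idx)),
    septum = rep(FALSE, length(idx)),
    third = rep("mid", length(idx)), sector = rep("anterior", length(idx)),
    neighbors = nbr, lv_cavity = integer(0), rv_cavity = integer(0),
    n_nodes = length(idx),
    grid = grid_spec(resolution), params = ellipsoid_params()
  ), class = "heart_model")
}

# uniform activation map for a toy model (all nodes at a fixed onset)
uniform_activation <- function(model, t0 = 0) {
  structure(list(time = rep(t0, model$n_nodes),
                 unreachable = rep(FALSE, model$n_nodes),
                 start_rows = 1L, onsets = t0,
                 cfg = propagation_config()),
            class = "activation_map")
}
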