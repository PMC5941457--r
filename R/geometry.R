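#' Voxel grid specification
#'
#' Defines the cubic sampling grid on which the two-ventricle model is
#' discretized. Voxel centers sit at `origin + (index + 0.5) * resolution`
#' with 0-based integer indices; the bounding box is derived from the
#' ellipsoid parameters plus a margin.
#'
#' @param resolution Edge length of a voxel in mm (default 1).
#' @param margin Extra space around the ventricles in mm.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(resolution = 1, margin = 2) {
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution <= 0)
    stop("`resolution` must be a single positive number (mm)", call. = FALSE)
  structure(list(resolution = resolution, margin = margin), class = "grid_spec")
}

#' Ellipsoidal two-ventricle parameters
#'
#' Geometry of the five-layered ventricular walls: each ventricle is the
#' shell between two confocal-by-offset ellipsoids, truncated by a basal
#' plane. The septum (left-ventricular wall lying inside the right-ventricular
#' outer ellipsoid) is labelled LV. Layers L1 (endocardial, Purkinje-like)
#' through L5 (epicardial) are slabs of the transmural coordinate, with
#' per-ventricle thickness fractions.
#'
#' The defaults are frozen calibration constants chosen so that the relative
#' layer volumes of the default 1 mm model match the reference volume table
#' used throughout the package (see `scripts/calibrate_geometry.R` in the
#' source repository for the calibration procedure).
#'
#' @param lv_outer,rv_outer Outer semi-axes (mm), length-3 `(a, b, c)`;
#'   `c` is the long (apex-base) axis.
#' @param lv_wall,rv_wall Wall thickness (mm), subtracted from every semi-axis
#'   to form the inner (endocardial) ellipsoid.
#' @param rv_center Center of the right-ventricular ellipsoid in heart-local
#'   coordinates (the LV ellipsoid is centered at the origin).
#' @param lv_layer_fractions,rv_layer_fractions Transmural thickness fractions
#'   of layers L1..L5 (must be positive, summing to 1).
#' @param base_z Basal truncation plane: myocardium satisfies `z <= base_z`.
#' @param ab_split_z Apex/base partition plane for the discordant apex-base
#'   scenario (`z < ab_split_z` is the apex side).
#' @param pa_split_y Posterior/anterior partition plane (`y > pa_split_y`
#'   is the posterior side; heart-local +y points posterior).
#' @param position Heart center in torso coordinates (mm).
#' @param orientation 3x3 rotation matrix mapping heart-local directions into
#'   torso directions (torso frame: +x left, +y posterior, +z cranial).
#' @return An object of class `ellipsoid_params`.
#' @export
ellipsoid_params <- function(lv_outer = c(34, 34, 57),
                             rv_outer = c(43, 30, 52),
                             lv_wall = 11.5,
                             rv_wall = 6.5,
                             rv_center = c(-18, -2, -4),
                             lv_layer_fractions = c(0.1630, 0.2190, 0.2190, 0.2190, 0.1801),
                             rv_layer_fractions = c(0.1723, 0.1855, 0.1855, 0.1855, 0.2711),
                             base_z = 18,
                             ab_split_z = -17,
                             pa_split_y = -2,
                             position = c(40, -30, 40),
                             orientation = default_heart_orientation()) {
  stopifnot(length(lv_outer) == 3L, length(rv_outer) == 3L,
            length(rv_center) == 3L, length(position) == 3L)
  if (lv_wall <= 0 || rv_wall <= 0)
    stop("wall thickness must be positive", call. = FALSE)
  if (any(lv_outer - lv_wall <= 0) || any(rv_outer - rv_wall <= 0))
    stop("wall thickness exceeds an outer semi-axis", call. = FALSE)
  for (fr in list(lv_layer_fractions, rv_layer_fractions)) {
    if (length(fr) != 5L || any(fr <= 0))
      stop("layer thickness fractions must be 5 positive values", call. = FALSE)
    if (abs(sum(fr) - 1) > 1e-3)
      stop("layer thickness fractions must sum to 1", call. = FALSE)
  }
  lv_layer_fractions <- lv_layer_fractions / sum(lv_layer_fractions)
  rv_layer_fractions <- rv_layer_fractions / sum(rv_layer_fractions)
  if (!is.matrix(orientation) || any(dim(orientation) != c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("`orientation` must be a 3x3 rotation matrix", call. = FALSE)
  structure(list(
    lv_outer = as.numeric(lv_outer), rv_outer = as.numeric(rv_outer),
    lv_wall = lv_wall, rv_wall = rv_wall,
    rv_center = as.numeric(rv_center),
    lv_layer_fractions = as.numeric(lv_layer_fractions),
    rv_layer_fractions = as.numeric(rv_layer_fractions),
    base_z = base_z, ab_split_z = ab_split_z, pa_split_y = pa_split_y,
    position = as.numeric(position), orientation = orientation
  ), class = "ellipsoid_params")
}

#' Default anatomical orientation of the heart in the torso
#'
#' Rotation that tilts the heart-local long axis (local -z, pointing to the
#' apex) toward the left, anterior and caudal direction, as in situ.
#'
#' @return A 3x3 rotation matrix.
#' @export
default_heart_orientation <- function() {
  # apex direction in torso coordinates (x left, y posterior, z up):
  # leftward, anterior and moderately caudal, giving upright T waves in
  # I, II and V2-V6 with an inverted T in V1 on the reference beat
  apex <- c(0.85, -0.30, -0.43)
  apex <- apex / sqrt(sum(apex^2))
  zl <- -apex                              # heart-local +z (base) in torso frame
  yl <- c(0, 1, 0)                         # keep local +y near posterior
  yl <- yl - sum(yl * zl) * zl
  yl <- yl / sqrt(sum(yl^2))
  xl <- c(yl[2] * zl[3] - yl[3] * zl[2],
          yl[3] * zl[1] - yl[1] * zl[3],
          yl[1] * zl[2] - yl[2] * zl[1])
  cbind(xl, yl, zl, deparse.level = 0)
}

# squared "ellipsoidal radius": <1 inside, =1 on surface
.rho2 <- function(p, center, semi) {
  ((p[, 1] - center[1]) / semi[1])^2 +
    ((p[, 2] - center[2]) / semi[2])^2 +
    ((p[, 3] - center[3]) / semi[3])^2
}

# transmural coordinate lambda in [0,1] for points inside the shell between
# ellipsoids with semi-axes (semi - wall) and semi: bisection on the family
# semi_in + lambda * wall (monotone in lambda).
.transmural_lambda <- function(p, center, semi, wall, iter = 40L) {
  lo <- rep(0, nrow(p)); hi <- rep(1, nrow(p))
  si <- semi - wall
  px <- p[, 1] - center[1]; py <- p[, 2] - center[2]; pz <- p[, 3] - center[3]
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    g <- (px / (si[1] + mid * wall))^2 + (py / (si[2] + mid * wall))^2 +
      (pz / (si[3] + mid * wall))^2
    inside <- g < 1            # point inside the mid-surface -> lambda smaller
    hi[inside] <- mid[inside]
    lo[!inside] <- mid[!inside]
  }
  (lo + hi) / 2
}

.layer_from_lambda <- function(lambda, fractions) {
  br <- cumsum(fractions)
  br[5] <- 1 + 1e-12
  findInterval(lambda, c(-Inf, br[1:4])) # 1..5
}

#' Build the five-layer two-ventricle voxel model
#'
#' Discretizes the ellipsoidal ventricles onto a cubic grid and labels every
#' myocardial voxel with its layer (L1 innermost .. L5 epicardial), ventricle,
#' long-axis third and circumferential sector. Cavity (blood pool) voxels are
#' recorded separately.
#'
#' @param grid A [grid_spec()].
#' @param params An [ellipsoid_params()].
#' @return An object of class `heart_model` with elements
#'   `coords` (N x 3 heart-local mm), `ijk` (N x 3 0-based voxel indices),
#'   `layer` (1..5), `ventricle` ("LV"/"RV"), `septum` (logical),
#'   `third` ("apical"/"mid"/"basal"), `sector` (AHA-style sector name
#'   relative to the voxel's own ventricle), `lambda` (transmural coordinate),
#'   `neighbors` (N x 6 row indices of the -x,+x,-y,+y,-z,+z neighbours,
#'   NA where the neighbour is not myocardium), cavity index sets, and the
#'   grid/parameter provenance.
#' @export
build_heart_model <- function(grid = grid_spec(), params = ellipsoid_params()) {
  stopifnot(inherits(grid, "grid_spec"), inherits(params, "ellipsoid_params"))
  res <- grid$resolution
  m <- grid$margin

  lo <- pmin(-params$lv_outer, params$rv_center - params$rv_outer) - m
  hi <- pmax(params$lv_outer, params$rv_center + params$rv_outer) + m
  hi[3] <- min(hi[3], params$base_z + m)
  origin <- floor(lo / res) * res
  dims <- as.integer(ceiling((hi - origin) / res))

  ax <- origin[1] + (seq_len(dims[1]) - 0.5) * res
  ay <- origin[2] + (seq_len(dims[2]) - 0.5) * res
  az <- origin[3] + (seq_len(dims[3]) - 0.5) * res

  # full grid coordinates, recycled in blocks (x fastest, then y, then z)
  cx <- rep(ax, times = dims[2] * dims[3])
  cy <- rep(rep(ay, each = dims[1]), times = dims[3])
  cz <- rep(az, each = dims[1] * dims[2])
  pts <- cbind(cx, cy, cz)

  lv_in <- params$lv_outer - params$lv_wall
  rv_in <- params$rv_outer - params$rv_wall

  r_lv_out <- .rho2(pts, c(0, 0, 0), params$lv_outer)
  r_lv_in  <- .rho2(pts, c(0, 0, 0), lv_in)
  r_rv_out <- .rho2(pts, params$rv_center, params$rv_outer)
  r_rv_in  <- .rho2(pts, params$rv_center, rv_in)
  below_base <- cz <= params$base_z

  in_lv_shell <- below_base & r_lv_out <= 1 & r_lv_in >= 1
  in_rv_shell <- below_base & r_rv_out <= 1 & r_rv_in >= 1 & r_lv_out > 1
  myo <- in_lv_shell | in_rv_shell
  if (!any(myo))
    stop("geometry error: parameters produce an empty myocardium", call. = FALSE)

  lv_cavity <- which(below_base & r_lv_in < 1)
  rv_cavity <- which(below_base & r_rv_in < 1 & r_lv_out > 1)

  idx <- which(myo)
  p_myo <- pts[idx, , drop = FALSE]
  is_lv <- in_lv_shell[idx]
  ventricle <- ifelse(is_lv, "LV", "RV")
  septum <- is_lv & (r_rv_out[idx] <= 1)

  lambda <- numeric(length(idx))
  if (any(is_lv))
    lambda[is_lv] <- .transmural_lambda(p_myo[is_lv, , drop = FALSE],
                                        c(0, 0, 0), params$lv_outer, params$lv_wall)
  if (any(!is_lv))
    lambda[!is_lv] <- .transmural_lambda(p_myo[!is_lv, , drop = FALSE],
                                         params$rv_center, params$rv_outer, params$rv_wall)

  layer <- integer(length(idx))
  layer[is_lv] <- .layer_from_lambda(lambda[is_lv], params$lv_layer_fractions)
  layer[!is_lv] <- .layer_from_lambda(lambda[!is_lv], params$rv_layer_fractions)

  # long-axis thirds over the myocardial extent; ties go to the lower third
  zr <- range(p_myo[, 3])
  tb <- zr[1] + diff(zr) * c(1, 2) / 3
  third <- c("apical", "mid", "basal")[findInterval(p_myo[, 3], tb) + 1L]

  # circumferential sector about the voxel's own ventricular axis, measured
  # from anterior (-y), increasing toward the free wall
  sec_names <- c("anterior", "anterolateral", "inferolateral",
                 "inferior", "inferoseptal", "anteroseptal")
  ang <- numeric(length(idx))
  ang[is_lv] <- atan2(p_myo[is_lv, 1], -p_myo[is_lv, 2])
  ang[!is_lv] <- atan2(-(p_myo[!is_lv, 1] - params$rv_center[1]),
                       -(p_myo[!is_lv, 2] - params$rv_center[2]))
  deg <- (ang * 180 / pi + 30) %% 360  # shift so sector 1 spans [-30, 30)
  sector <- sec_names[pmin(floor(deg / 60) + 1L, 6L)]

  # voxel indices and neighbour table (6-neighbourhood row indices)
  lin <- idx - 1L
  i <- lin %% dims[1]
  rest <- lin %/% dims[1]
  j <- rest %% dims[2]
  k <- rest %/% dims[2]

  row_of <- integer(prod(dims))
  row_of[idx] <- seq_along(idx)
  nbr <- matrix(NA_integer_, nrow = length(idx), ncol = 6L)
  offs <- list(c(-1L, 0L, 0L), c(1L, 0L, 0L), c(0L, -1L, 0L),
               c(0L, 1L, 0L), c(0L, 0L, -1L), c(0L, 0L, 1L))
  for (d in seq_along(offs)) {
    ii <- i + offs[[d]][1]; jj <- j + offs[[d]][2]; kk <- k + offs[[d]][3]
    ok <- ii >= 0L & ii < dims[1] & jj >= 0L & jj < dims[2] & kk >= 0L & kk < dims[3]
    lin2 <- ii[ok] + dims[1] * (jj[ok] + dims[2] * kk[ok]) + 1L
    r <- row_of[lin2]
    r[r == 0L] <- NA_integer_
    nbr[ok, d] <- r
  }

  model <- structure(list(
    dims = dims, origin = origin, resolution = res,
    grid_index = idx, ijk = cbind(i = i, j = j, k = k),
    coords = p_myo, lambda = lambda,
    layer = layer, ventricle = ventricle, septum = septum,
    third = third, sector = sector,
    neighbors = nbr,
    lv_cavity = lv_cavity, rv_cavity = rv_cavity,
    n_nodes = length(idx),
    grid = grid, params = params
  ), class = "heart_model")

  comp <- .connected_components(model)
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    stop(sprintf(
      "geometry error: myocardium splits into %d connected components (sizes %s)",
      max(comp), paste(sizes, collapse = ", ")), call. = FALSE)
  }
  model
}

# 6-neighbourhood connected components via iterative label propagation
.connected_components <- function(model) {
  n <- model$n_nodes
  lab <- seq_len(n)
  nbr <- model$neighbors
  repeat {
    new <- lab
    for (d in 1:6) {
      has <- !is.na(nbr[, d])
      new[has] <- pmin(new[has], lab[nbr[has, d]])
    }
    # pointer-jumping to speed convergence
    new <- new[new]
    if (identical(new, lab)) break
    lab <- new
  }
  match(lab, sort(unique(lab)))
}

#' @export
print.heart_model <- function(x, ...) {
  cat("Five-layer two-ventricle voxel model\n")
  cat(sprintf("  resolution : %.3g mm\n", x$resolution))
  cat(sprintf("  myocardial nodes: %d (volume %.1f cm^3)\n",
              x$n_nodes, x$n_nodes * x$resolution^3 / 1000))
  tab <- table(factor(x$layer, levels = 1:5, labels = paste0("L", 1:5)))
  cat("  layer counts: ", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  vt <- table(x$ventricle)
  cat("  ventricle counts: ", paste(names(vt), vt, sep = "=", collapse = "  "), "\n")
  invisible(x)
}

#' Transform heart-local points into torso coordinates
#'
#' @param model A `heart_model`.
#' @param pts N x 3 matrix of heart-local coordinates (mm); defaults to the
#'   model's own node coordinates.
#' @return N x 3 matrix in torso coordinates.
#' @export
heart_to_torso <- function(model, pts = model$coords) {
  p <- pts %*% t(model$params$orientation)
  sweep(p, 2, model$params$position, `+`)
}

.region_vocabulary <- c("CONC", "D_P/A", "D_L/R", "D_A/B",
                        "R_ANT", "R_INF", "R_LEF", "R_LAN", "R_LLA",
                        "R_POS", "R_RIG", "R_RAN", "R_SUP", "R_SEP")

#' Names of all supported alternans topologies
#' @return Character vector: concordant, the three discordant pairs, and the
#'   ten regional masks.
#' @export
region_names <- function() .region_vocabulary

#' Select a scenario region of the myocardium
#'
#' Returns the node mask for a named alternans topology: `"CONC"` (all
#' myocardium), a discordant pair (`"D_P/A"`, `"D_L/R"`, `"D_A/B"`; returned
#' as an ordered list of the two complementary masks), or one of the ten
#' AHA-style regional masks (`R_ANT`, `R_INF`, `R_LEF`, `R_LAN`, `R_LLA`,
#' `R_POS`, `R_RIG`, `R_RAN`, `R_SUP`, `R_SEP`).
#'
#' For the left/right split the septum counts as left ventricle; `R_SEP` is
#' defined independently on the septal wall (basal third, inferior half).
#'
#' @param model A `heart_model`.
#' @param name Region identifier.
#' @return A logical vector over myocardial nodes, or for discordant names a
#'   list with elements `a` and `b` (disjoint masks covering the myocardium).
#' @export
select_region <- function(model, name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% .region_vocabulary))
    stop(sprintf("unknown region name '%s'", paste(name, collapse = ",")), call. = FALSE)
  v <- model$ventricle
  z <- model$coords[, 3]
  y <- model$coords[, 2]
  switch(name,
    "CONC"  = rep(TRUE, model$n_nodes),
    "D_L/R" = list(a = v == "LV", b = v == "RV"),
    "D_A/B" = list(a = z < model$params$ab_split_z, b = z >= model$params$ab_split_z),
    "D_P/A" = list(a = y > model$params$pa_split_y, b = y <= model$params$pa_split_y),
    "R_ANT" = v == "RV" & model$third == "basal" & model$sector == "anterolateral",
    "R_INF" = v == "LV" & model$third == "mid" & model$sector == "inferior",
    "R_LEF" = v == "LV" & model$third == "mid" & model$sector == "anterolateral",
    "R_LAN" = v == "LV" & model$third == "apical" & model$sector == "anterior",
    "R_LLA" = v == "LV" & model$third == "mid" & model$sector == "inferolateral",
    "R_POS" = v == "LV" & model$third == "basal" & model$sector == "inferolateral",
    "R_RIG" = v == "RV" & model$third == "basal" & model$sector == "inferolateral",
    "R_RAN" = v == "RV" & model$third == "mid" & model$sector == "anterolateral",
    "R_SUP" = v == "LV" & model$third == "mid" & model$sector == "anterior",
    "R_SEP" = model$septum & model$third == "basal" & y > 0
  )
}

#' Layer-group volume fractions per scenario mask
#'
#' Tabulates, for each alternans topology mask, the percentage of the whole
#' myocardial model volume occupied by the mid-myocardial layer group
#' (L2+L3+L4) and by the epicardial layer (L5). Percentages are computed by
#' node counting (every voxel has equal volume).
#'
#' @param model A `heart_model`.
#' @return A data.frame with columns `mask`, `mid_pct`, `epi_pct`.
#' @export
layer_volume_fractions <- function(model) {
  if (!inherits(model, "heart_model") || model$n_nodes == 0L)
    stop("empty or invalid heart model", call. = FALSE)
  total <- model$n_nodes
  mid <- model$layer %in% 2:4
  epi <- model$layer == 5L
  pct <- function(mask) c(100 * sum(mask & mid) / total, 100 * sum(mask & epi) / total)

  rows <- list(CONC = rep(TRUE, total))
  for (nm in c("D_L/R", "D_A/B", "D_P/A")) {
    pair <- select_region(model, nm)
    side <- switch(nm, "D_L/R" = c("Left", "Right"),
                   "D_A/B" = c("Apex", "Base"), "D_P/A" = c("Post", "Anter"))
    rows[[paste0(nm, ":", side[1])]] <- pair$a
    rows[[paste0(nm, ":", side[2])]] <- pair$b
  }
  for (nm in grep("^R_", .region_vocabulary, value = TRUE))
    rows[[nm]] <- select_region(model, nm)

  out <- t(vapply(rows, pct, numeric(2)))
  data.frame(mask = names(rows), mid_pct = out[, 1], epi_pct = out[, 2],
             row.names = NULL)
}
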