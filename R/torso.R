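#' Torso volume-conductor parameters
#'
#' Analytic inhomogeneous torso: an elliptic cylinder with capped ends for
#' the outer boundary, two ellipsoidal lungs and the two ventricular blood
#' pools. Lungs conduct at one quarter of the mean torso conductivity, the
#' blood pools at three times the mean torso conductivity.
#'
#' Torso coordinates: +x left, +y posterior, +z cranial; origin on the
#' cylinder axis at mid-height.
#'
#' @param section_semi Semi-axes (mm) of the elliptic cross-section (x, y).
#' @param z_range Vertical extent (mm).
#' @param sigma_torso Mean torso conductivity (arbitrary units; only ratios
#'   matter for the lead fields up to a global scale).
#' @param lung_ratio,cavity_ratio Conductivity of lungs / blood pools
#'   relative to `sigma_torso` (defaults 1/4 and 3; set both to 1 for the
#'   homogeneous variant).
#' @param lung_center_left,lung_center_right,lung_semi Lung ellipsoid
#'   placement (mm).
#' @param n_phi,n_z Angular and vertical mesh density of the outer cylinder.
#' @param lung_subdiv,cavity_subdiv Icosphere subdivision of lungs and blood
#'   pools.
#' @return An object of class `torso_params`.
#' @export
torso_params <- function(section_semi = c(175, 125), z_range = c(-275, 275),
                         sigma_torso = 1, lung_ratio = 0.25, cavity_ratio = 3,
                         lung_center_left = c(108, 30, 110),
                         lung_center_right = c(-95, 18, 90),
                         lung_semi = c(40, 55, 145),
                         n_phi = 32, n_z = 20,
                         lung_subdiv = 2, cavity_subdiv = 2) {
  if (n_phi < 8 || n_z < 3) stop("mesh density below minimum", call. = FALSE)
  structure(as.list(environment()), class = "torso_params")
}

# blood-pool ellipsoids in heart-local coordinates, derived from the heart
# geometry: LV pool = the LV inner ellipsoid (slightly shrunk to keep the
# polyhedral surface clear of the endocardium); RV pool = an ellipsoid fitted
# into the crescent between the RV inner and the LV outer surface.
.cavity_ellipsoids <- function(heart) {
  lv_in <- heart$lv_outer - heart$lv_wall
  rv_in <- heart$rv_outer - heart$rv_wall
  list(
    LV = list(center = c(0, 0, 0), semi = 0.97 * lv_in),
    RV = list(center = heart$rv_center + c(-26, 0, 0),
              semi = c(8.5, 13, 26))
  )
}

.inside_ellipsoid <- function(p, center, semi, shrink = 1) {
  .rho2(p, center, semi * shrink) < 1
}

#' Build the inhomogeneous torso volume-conductor model
#'
#' Triangulates the five compartment surfaces, validates that they are
#' closed, mutually non-intersecting and correctly nested, and attaches the
#' electrode layouts (192-lead body-surface grid, the 9 electrodes of the
#' standard 12-lead system).
#'
#' @param params A [torso_params()].
#' @param heart An [ellipsoid_params()]; fixes the position, orientation and
#'   size of the ventricular blood pools.
#' @return An object of class `torso_model` with `surfaces` (named list of
#'   meshes), `sigma` (per-surface inside/outside conductivities),
#'   `electrodes` and the generating parameters.
#' @export
build_torso <- function(params = torso_params(), heart = ellipsoid_params()) {
  stopifnot(inherits(params, "torso_params"), inherits(heart, "ellipsoid_params"))
  s0 <- params$sigma_torso
  torso <- cylinder_mesh(params$section_semi[1], params$section_semi[2],
                         params$z_range[1], params$z_range[2],
                         params$n_phi, params$n_z)
  lungL <- ellipsoid_mesh(params$lung_center_left, params$lung_semi,
                          params$lung_subdiv)
  lungR <- ellipsoid_mesh(params$lung_center_right,
                          params$lung_semi * c(1, 1.05, 1),
                          params$lung_subdiv)
  cav <- .cavity_ellipsoids(heart)
  to_torso <- function(p) sweep(p %*% t(heart$orientation), 2, heart$position, `+`)
  cavLV <- ellipsoid_mesh(c(0, 0, 0), cav$LV$semi, params$cavity_subdiv)
  cavLV$vertices <- to_torso(sweep(cavLV$vertices, 2, cav$LV$center, `+`))
  cavRV <- ellipsoid_mesh(c(0, 0, 0), cav$RV$semi, params$cavity_subdiv)
  cavRV$vertices <- to_torso(sweep(cavRV$vertices, 2, cav$RV$center, `+`))

  surfaces <- list(torso = torso, lung_left = lungL, lung_right = lungR,
                   cavity_lv = cavLV, cavity_rv = cavRV)
  for (nm in names(surfaces)) {
    if (!mesh_is_closed(surfaces[[nm]]) || mesh_euler(surfaces[[nm]]) != 2L)
      stop(sprintf("surface '%s' is not a closed sphere-topology mesh", nm),
           call. = FALSE)
  }

  # nesting / intersection checks: all inner-compartment vertices strictly
  # inside the torso; no vertex of one inner compartment inside another
  in_torso <- function(p) {
    (p[, 1] / params$section_semi[1])^2 + (p[, 2] / params$section_semi[2])^2 < 1 &
      p[, 3] > params$z_range[1] & p[, 3] < params$z_range[2]
  }
  inner <- names(surfaces)[-1]
  for (nm in inner)
    if (!all(in_torso(surfaces[[nm]]$vertices)))
      stop(sprintf("compartment '%s' is not strictly inside the torso", nm),
           call. = FALSE)
  for (nm in inner) for (nm2 in setdiff(inner, nm)) {
    v <- surfaces[[nm]]$vertices
    w <- surfaces[[nm2]]$vertices
    # point-in-mesh via the ellipsoid analytics is exact for all compartments
    hit <- switch(nm2,
      lung_left = .inside_ellipsoid(v, params$lung_center_left, params$lung_semi),
      lung_right = .inside_ellipsoid(v, params$lung_center_right,
                                     params$lung_semi * c(1, 1.05, 1)),
      cavity_lv = {
        q <- sweep(v, 2, heart$position) %*% heart$orientation
        .inside_ellipsoid(q, cav$LV$center, cav$LV$semi)
      },
      cavity_rv = {
        q <- sweep(v, 2, heart$position) %*% heart$orientation
        .inside_ellipsoid(q, cav$RV$center, cav$RV$semi)
      })
    if (any(hit))
      stop(sprintf("compartments '%s' and '%s' intersect", nm, nm2),
           call. = FALSE)
  }

  sigma <- data.frame(
    surface = names(surfaces),
    sigma_in = c(s0, rep(s0 * params$lung_ratio, 2), rep(s0 * params$cavity_ratio, 2)),
    sigma_out = c(0, rep(s0, 4))
  )

  electrodes <- .electrode_layouts(params)
  structure(list(surfaces = surfaces, sigma = sigma, electrodes = electrodes,
                 params = params, heart = heart),
            class = "torso_model")
}

# point on the analytic torso surface at parameter angle phi (0 = anterior
# midline, increasing toward the left) and height z
.torso_surface_point <- function(params, phi_deg, z) {
  phi <- phi_deg * pi / 180
  c(params$section_semi[1] * sin(phi), -params$section_semi[2] * cos(phi), z)
}

.electrode_layouts <- function(params) {
  # 192-lead grid: 12 rows (cranial to caudal) x 16 columns (anterior
  # midline, then leftward around the circumference); row-major ordering
  rows <- seq(165, -165, length.out = 12)
  cols <- seq(0, 360 - 22.5, by = 22.5)
  bspm <- matrix(NA_real_, 192, 3)
  for (r in 1:12) for (cc in 1:16)
    bspm[(r - 1) * 16 + cc, ] <- .torso_surface_point(params, cols[cc], rows[r])
  # precordial electrodes at anatomical heights: V1/V2 right/left parasternal
  # at the 4th intercostal level (above the ventricular mass center), V3-V6
  # descending toward the apex and around the left flank
  std_def <- rbind(
    RA = c(-65, 245), LA = c(65, 245), LL = c(40, -245), RL = c(-40, -245),
    V1 = c(-10, 55), V2 = c(10, 55), V3 = c(22, 40), V4 = c(36, 25),
    V5 = c(54, 22), V6 = c(72, 20))
  std <- t(apply(std_def, 1, function(d)
    .torso_surface_point(params, d[1], d[2])))
  list(bspm = list(positions = bspm, n_rows = 12L, n_cols = 16L),
       std = std)
}

#' @export
print.torso_model <- function(x, ...) {
  nv <- vapply(x$surfaces, function(m) nrow(m$vertices), integer(1))
  nf <- vapply(x$surfaces, function(m) nrow(m$faces), integer(1))
  cat("Inhomogeneous torso model\n")
  for (i in seq_along(x$surfaces))
    cat(sprintf("  %-11s %4d vertices %5d faces  sigma %.2f | %.2f\n",
                names(x$surfaces)[i], nv[i], nf[i],
                x$sigma$sigma_in[i], x$sigma$sigma_out[i]))
  cat(sprintf("  electrodes: 192-lead grid + %d standard\n",
              nrow(x$electrodes$std)))
  invisible(x)
}
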