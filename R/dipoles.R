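#' Per-node AP template assignment
#'
#' Compact representation of "which AP template does each myocardial node
#' follow": an integer group id per node plus the list of distinct templates.
#' The reference assignment maps every node to its layer's template.
#'
#' @param model A `heart_model`.
#' @param layer_table A [layer_ap_table()].
#' @return An object of class `ap_assignment` with elements `group`
#'   (integer per node) and `templates` (list of `ap_template`).
#' @export
ap_assignment <- function(model, layer_table = layer_ap_table()) {
  stopifnot(inherits(model, "heart_model"), length(layer_table) == 5L)
  structure(list(group = model$layer, templates = unname(layer_table)),
            class = "ap_assignment")
}

.check_assignment <- function(model, assign) {
  stopifnot(inherits(assign, "ap_assignment"))
  if (length(assign$group) != model$n_nodes)
    stop("AP assignment does not match the model", call. = FALSE)
  if (max(assign$group) > length(assign$templates))
    stop("AP assignment references a missing template", call. = FALSE)
  invisible(TRUE)
}

# sample all assignment templates on a common fine grid for the C++ engine
.assignment_curves <- function(assign, dt = 0.5) {
  t_max <- max(vapply(assign$templates, function(x) x$t_full_repol, numeric(1))) + 2
  tt <- seq(0, t_max, by = dt)
  curves <- vapply(assign$templates, function(tpl) ap_value(tpl, tt),
                   numeric(length(tt)))
  list(curves = curves, dt = dt)
}

#' Source-density weights of the myocardial nodes
#'
#' Relative dipole source density per node. Working-myocardium layers L2-L5
#' have weight 1. The endocardial layer L1 stands in for the sub-endocardial
#' Purkinje network: it conducts fast but consists of sparse fiber strands
#' embedded in the wall, so its effective membrane-current density -- and
#' hence its contribution to the equivalent generator -- is a small fraction
#' of the layer volume it occupies. Faces of the voxel lattice inherit the
#' smaller weight of their two nodes, so a spatially uniform potential field
#' remains exactly silent.
#'
#' @param model A `heart_model`.
#' @param purkinje_weight Source weight of layer L1 (default 0.02, the order
#'   of the volume fraction of Purkinje strands within the subendocardial
#'   layer).
#' @return Numeric weight per myocardial node.
#' @export
source_weights <- function(model, purkinje_weight = 0.02) {
  w <- rep(1, model$n_nodes)
  w[model$layer == 1L] <- purkinje_weight
  w
}

#' Default global gain of the multiple-dipole generator
#'
#' Single scalar converting membrane-potential differences (mV) across voxel
#' faces into equivalent dipole moments such that the forward-solved
#' reference beat has a T wave of a few hundred microvolts in the best
#' precordial lead and imposed alternans lands in the tens-of-microvolts
#' range on the body surface. Calibrated once on the default model
#' (`scripts/calibrate_gain.R`) and frozen; scales with the voxel face area
#' so that signal amplitudes are resolution-independent.
#'
#' @param resolution Voxel edge length (mm).
#' @return Gain constant (per face, already including the face-area factor).
#' @export
default_dipole_gain <- function(resolution = 1) {
  0.30 * resolution^2
}

#' Cubic block aggregation of the myocardium
#'
#' Groups myocardial nodes into cubic blocks for transfer-matrix tractability;
#' block dipoles are the sums of their nodes' dipoles, placed at the block
#' center of mass.
#'
#' @param model A `heart_model`.
#' @param block_mm Block edge length (mm); use `model$resolution` for
#'   no aggregation.
#' @return List with `block` (id per node), `centers` (B x 3, heart-local
#'   node centroid of each block), `n_blocks`.
#' @export
source_blocks <- function(model, block_mm = 5) {
  if (block_mm < model$resolution) block_mm <- model$resolution
  f <- floor(model$coords / block_mm)
  key <- paste(f[, 1], f[, 2], f[, 3])
  id <- match(key, unique(key))
  centers <- rowsum(model$coords, id) / tabulate(id)
  list(block = id, centers = centers, n_blocks = max(id))
}

#' Instantaneous multiple-dipole generator
#'
#' Per-node dipole moments at one time point: every face between two
#' myocardial voxels contributes a moment proportional to the transmembrane
#' potential difference across it, split equally between the two voxels;
#' faces against non-myocardium contribute zero. Components are expressed in
#' heart-local grid axes.
#'
#' @param model A `heart_model`.
#' @param activation An `activation_map`.
#' @param assign An [ap_assignment()].
#' @param t Time (ms).
#' @param gain Global gain; defaults to [default_dipole_gain()] at the
#'   model resolution.
#' @param weights Per-node source-density weights ([source_weights()]).
#' @return N x 3 matrix of dipole moments.
#' @export
dipoles_at <- function(model, activation, assign, t,
                       gain = default_dipole_gain(model$resolution),
                       weights = source_weights(model)) {
  .check_assignment(model, assign)
  cv <- .assignment_curves(assign)
  nbr_plus <- model$neighbors[, c(2L, 4L, 6L), drop = FALSE]
  nbr_plus[is.na(nbr_plus)] <- 0L
  D <- dipole_sequence_cpp(nbr_plus, activation$time, as.integer(assign$group),
                           cv$curves, cv$dt, seq_len(model$n_nodes),
                           model$n_nodes, as.numeric(t)[1], gain, weights)
  matrix(D[, 1], ncol = 3, byrow = TRUE)
}

#' Dipole-moment time course of the equivalent cardiac generator
#'
#' Stacks the block-aggregated multiple-dipole generator over a uniform time
#' grid. Moments and block positions are rotated/translated into torso
#' coordinates so the sequence plugs directly into the torso forward map.
#'
#' @inheritParams dipoles_at
#' @param t_grid Uniform time grid (ms).
#' @param block_mm Aggregation block size (mm).
#' @return An object of class `dipole_sequence`: `times`, `moments`
#'   (3B x T matrix, torso axes), `positions` (B x 3, torso mm), `gain`.
#' @export
build_sequence <- function(model, activation, assign,
                           t_grid = seq(0, 540, by = 1),
                           gain = default_dipole_gain(model$resolution),
                           block_mm = 5,
                           weights = source_weights(model)) {
  .check_assignment(model, assign)
  if (length(t_grid) == 0L) stop("empty time grid", call. = FALSE)
  if (any(activation$unreachable))
    stop("activation map has unreachable nodes", call. = FALSE)
  cv <- .assignment_curves(assign)
  bl <- source_blocks(model, block_mm)
  nbr_plus <- model$neighbors[, c(2L, 4L, 6L), drop = FALSE]
  nbr_plus[is.na(nbr_plus)] <- 0L
  D <- dipole_sequence_cpp(nbr_plus, activation$time, as.integer(assign$group),
                           cv$curves, cv$dt, bl$block, bl$n_blocks,
                           as.numeric(t_grid), gain, weights)
  # rotate heart-local moments into torso axes
  R <- model$params$orientation
  Dm <- matrix(D, nrow = 3)          # 3 x (B*T), blocks fastest
  Dm <- R %*% Dm
  D <- matrix(Dm, nrow = 3 * bl$n_blocks)
  structure(list(times = as.numeric(t_grid), moments = D,
                 positions = heart_to_torso(model, bl$centers),
                 n_blocks = bl$n_blocks, gain = gain, block_mm = block_mm),
            class = "dipole_sequence")
}

#' @export
print.dipole_sequence <- function(x, ...) {
  cat(sprintf("Dipole sequence: %d blocks x %d time points (%.0f-%.0f ms)\n",
              x$n_blocks, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Total heart vector of a dipole sequence
#'
#' @param seq A `dipole_sequence`.
#' @return 3 x T matrix: the summed dipole moment (torso axes) per time step.
#' @export
total_heart_vector <- function(seq) {
  stopifnot(inherits(seq, "dipole_sequence"))
  idx <- rep(1:3, seq$n_blocks)
  rowsum(seq$moments, idx)
}
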