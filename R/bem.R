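# Boundary-element forward solution on the piecewise-homogeneous torso.
#
# Double-layer collocation at the surface vertices: for a collocation point
# r on surface k,
#
#   (sigma_k^- + sigma_k^+)/2 * phi(r)
#     = sigma_s * phi_inf(r)
#       + 1/(4 pi) * sum_l (sigma_l^- - sigma_l^+) * Int_{S_l} phi dOmega ,
#
# with phi_inf the infinite-medium dipole potential and dOmega the solid
# angle subtended at r. Triangle solid angles are analytic (van Oosterom &
# Strackee) and distributed in equal thirds to the triangle vertices; the
# singular self term is fixed by the auto-solid-angle condition (total angle
# of the own surface = 2 pi). The constant-potential null space is removed
# by deflation and the final potentials are referenced to a zero
# area-weighted mean over the outer torso surface.

# weak FNV-1a hash of an R object (used for cache identity of meshes/sources)
.obj_hash <- function(x) {
  raw <- serialize(x, NULL, xdr = TRUE)
  h <- 2166136261
  # fold bytes in chunks to keep the R loop short
  v <- as.integer(raw)
  chunk <- 4096L
  for (i in seq(1L, length(v), by = chunk)) {
    seg <- v[i:min(i + chunk - 1L, length(v))]
    h <- (h * 16777619 + sum(seg * seq_along(seg))) %% 2^31
  }
  sprintf("%08x-%d", as.integer(h), length(raw))
}

# stack all surfaces into one vertex/face set with per-vertex surface ids
.stack_surfaces <- function(torso) {
  vs <- lapply(torso$surfaces, `[[`, "vertices")
  fs <- lapply(torso$surfaces, `[[`, "faces")
  nv <- vapply(vs, nrow, integer(1))
  off <- cumsum(c(0L, nv[-length(nv)]))
  verts <- do.call(rbind, vs)
  faces <- do.call(rbind, Map(function(f, o) f + o, fs, off))
  surf_id <- rep(seq_along(vs), nv)
  list(verts = verts, faces = faces, surf_id = surf_id, offsets = off, nv = nv)
}

# barycentric interpolation matrix: each point is projected to the closest
# point of the closest triangle of the mesh
.interp_matrix <- function(mesh, points, n_total, offset) {
  v <- mesh$vertices
  f <- mesh$faces
  E <- matrix(0, nrow(points), n_total)
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
  den <- d00 * d11 - d01 * d01
  for (i in seq_len(nrow(points))) {
    ap <- sweep(a, 2, points[i, ], `-`) * -1
    d20 <- rowSums(ap * ab); d21 <- rowSums(ap * ac)
    w2 <- (d11 * d20 - d01 * d21) / den
    w3 <- (d00 * d21 - d01 * d20) / den
    w2c <- pmin(pmax(w2, 0), 1)
    w3c <- pmin(pmax(w3, 0), 1 - w2c)
    w1c <- 1 - w2c - w3c
    proj <- a + ab * w2c + ac * w3c
    d2 <- rowSums(sweep(proj, 2, points[i, ], `-`)^2)
    t_best <- which.min(d2)
    E[i, f[t_best, 1] + offset] <- w1c[t_best]
    E[i, f[t_best, 2] + offset] <- w2c[t_best]
    E[i, f[t_best, 3] + offset] <- w3c[t_best]
  }
  E
}

#' Assemble the time-independent transfer matrix
#'
#' Solves the boundary-element system once and returns the linear map from
#' source dipole moments (3 per source position, torso axes) to electrode
#' potentials at all 192 + 9 electrodes (zero area-weighted mean over the
#' torso surface as reference).
#'
#' @param torso A [build_torso()] result.
#' @param source_positions M x 3 matrix of source positions (torso mm); all
#'   must lie strictly inside the torso and outside lungs and blood pools.
#' @return An object of class `transfer_matrix`: `matrix`
#'   (n_electrodes x 3M), `electrode_names`, `bspm_rows`, `std_rows`,
#'   `source_positions`, `torso_hash`, `source_hash`.
#' @export
build_transfer_matrix <- function(torso, source_positions) {
  stopifnot(inherits(torso, "torso_model"))
  src <- as.matrix(source_positions)
  if (ncol(src) != 3L) stop("source_positions must be M x 3", call. = FALSE)

  st <- .stack_surfaces(torso)
  nV <- nrow(st$verts)

  W <- solid_angle_weights_cpp(st$verts, st$verts, st$faces)

  # auto-solid-angle: the own surface must subtend exactly 2 pi at each of
  # its vertices; assign the deficit to the vertex itself
  for (l in seq_along(torso$surfaces)) {
    colsel <- which(st$surf_id == l)
    rows <- which(st$surf_id == l)
    rs <- rowSums(W[rows, colsel, drop = FALSE])
    W[cbind(rows, rows)] <- W[cbind(rows, rows)] + (2 * pi - rs)
  }

  dsig <- torso$sigma$sigma_in - torso$sigma$sigma_out
  sbar <- (torso$sigma$sigma_in + torso$sigma$sigma_out) / 2
  A <- -sweep(W, 2, dsig[st$surf_id] / (4 * pi), `*`)
  diag(A) <- diag(A) + sbar[st$surf_id]

  # deflation against the constant null vector, weighted by torso vertex area
  torso_rows <- which(st$surf_id == 1L)
  va <- mesh_areas(torso$surfaces$torso)$vertex_areas
  w <- numeric(nV)
  w[torso_rows] <- va / sum(va)
  A <- A + mean(abs(diag(A))) * outer(rep(1, nV), w)

  # right-hand side sigma_s * phi_inf: the source conductivity cancels
  # against the 1/sigma_s of phi_inf, leaving the bare dipole kernel
  G <- dipole_kernel_cpp(st$verts, src)
  phi <- solve(A, G)

  # electrodes: barycentric interpolation on the torso mesh, zero-mean ref
  el_pos <- rbind(torso$electrodes$bspm$positions, torso$electrodes$std)
  E <- .interp_matrix(torso$surfaces$torso, el_pos, nV, 0L)
  Tm <- (E - outer(rep(1, nrow(E)), w)) %*% phi

  names_std <- rownames(torso$electrodes$std)
  structure(list(
    matrix = Tm,
    electrode_names = c(sprintf("B%03d", 1:192), names_std),
    bspm_rows = 1:192, std_rows = 192L + seq_along(names_std),
    source_positions = src,
    torso_hash = .obj_hash(torso[c("surfaces", "sigma")]),
    source_hash = .obj_hash(src)
  ), class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat(sprintf("Transfer matrix: %d electrodes x %d source moments (%d sources)\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$source_positions)))
  invisible(x)
}

#' Solve the BEM surface potential for one dipole
#'
#' Convenience wrapper used for validation: potentials at all surface
#' vertices of an arbitrary torso model for a single dipole source, without
#' the electrode interpolation step.
#'
#' @param torso A `torso_model`.
#' @param position Length-3 source position.
#' @param moment Length-3 dipole moment.
#' @return Numeric vector of vertex potentials (zero area-weighted mean over
#'   the outer surface).
#' @export
bem_surface_potential <- function(torso, position, moment) {
  tm <- build_transfer_matrix_vertices(torso, matrix(position, 1))
  as.numeric(tm$phi %*% as.numeric(moment))
}

# internal: like build_transfer_matrix but returning the full vertex solution
build_transfer_matrix_vertices <- function(torso, src) {
  st <- .stack_surfaces(torso)
  nV <- nrow(st$verts)
  W <- solid_angle_weights_cpp(st$verts, st$verts, st$faces)
  for (l in seq_along(torso$surfaces)) {
    rows <- which(st$surf_id == l)
    rs <- rowSums(W[rows, rows, drop = FALSE])
    W[cbind(rows, rows)] <- W[cbind(rows, rows)] + (2 * pi - rs)
  }
  dsig <- torso$sigma$sigma_in - torso$sigma$sigma_out
  sbar <- (torso$sigma$sigma_in + torso$sigma$sigma_out) / 2
  A <- -sweep(W, 2, dsig[st$surf_id] / (4 * pi), `*`)
  diag(A) <- diag(A) + sbar[st$surf_id]
  torso_rows <- which(st$surf_id == 1L)
  va <- mesh_areas(torso$surfaces$torso)$vertex_areas
  w <- numeric(nV)
  w[torso_rows] <- va / sum(va)
  A <- A + mean(abs(diag(A))) * outer(rep(1, nV), w)
  G <- dipole_kernel_cpp(st$verts, as.matrix(src))
  phi <- solve(A, G)
  phi <- phi - outer(rep(1, nV), as.numeric(w %*% phi))
  list(phi = phi, surf_id = st$surf_id, verts = st$verts, weights = w)
}

#' Forward-map a dipole sequence onto the electrodes
#'
#' Applies the time-independent transfer matrix to every time step of the
#' dipole sequence: `s(t) = T d(t)`.
#'
#' @param tm A [build_transfer_matrix()] result.
#' @param seq A [build_sequence()] result (torso-frame moments).
#' @return An [ecg_recording()] of raw electrode potentials (lead system
#'   `"electrodes"`).
#' @export
forward <- function(tm, seq) {
  stopifnot(inherits(tm, "transfer_matrix"), inherits(seq, "dipole_sequence"))
  if (ncol(tm$matrix) != nrow(seq$moments))
    stop(sprintf("dimension mismatch: transfer matrix has %d moment columns, sequence has %d",
                 ncol(tm$matrix), nrow(seq$moments)), call. = FALSE)
  sig <- tm$matrix %*% seq$moments
  ecg_recording(sig, seq$times, tm$electrode_names, "electrodes")
}
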