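# Triangulated closed-surface utilities for the torso volume conductor.
# A mesh is a list(vertices = V x 3, faces = F x 3 integer, 1-based), with
# faces oriented so normals point outward (positive signed volume).

.mesh <- function(vertices, faces) {
  storage.mode(faces) <- "integer"
  list(vertices = vertices, faces = faces)
}

#' Icosphere mesh of the unit sphere
#'
#' @param subdiv Number of 4-fold subdivision steps of the icosahedron
#'   (0 gives 20 triangles, each step quadruples the count).
#' @return A mesh: list with `vertices` (V x 3) and `faces` (F x 3).
#' @export
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- nrow(v)
    edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    uk <- unique(key)
    mid_id <- match(key, uk) + nv
    ue <- edges[!duplicated(key), , drop = FALSE]
    mids <- (v[ue[, 1], ] + v[ue[, 2], ]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
  }
  m <- .mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Ellipsoid mesh
#'
#' @param center Length-3 center (mm).
#' @param semi Length-3 semi-axes (mm).
#' @param subdiv Icosphere subdivision level.
#' @return A mesh.
#' @export
ellipsoid_mesh <- function(center = c(0, 0, 0), semi = c(1, 1, 1), subdiv = 2) {
  m <- icosphere(subdiv)
  m$vertices <- sweep(m$vertices %*% diag(semi), 2, center, `+`)
  m
}

#' Capped elliptic-cylinder mesh
#'
#' Lateral surface on a regular (angle x height) grid plus triangle-fan end
#' caps; used for the outer torso.
#'
#' @param a,b Semi-axes of the elliptic cross-section (mm); `a` along x
#'   (left), `b` along y (posterior).
#' @param zmin,zmax Vertical extent (mm).
#' @param n_phi Number of circumferential divisions.
#' @param n_z Number of vertical divisions of the lateral wall.
#' @return A mesh. The angle parameter starts at the anterior midline
#'   (phi = 0 at (0, -b)) and increases toward the left (+x).
#' @export
cylinder_mesh <- function(a = 175, b = 125, zmin = -275, zmax = 275,
                          n_phi = 32, n_z = 20) {
  phi <- seq(0, 2 * pi, length.out = n_phi + 1)[-(n_phi + 1)]
  zz <- seq(zmin, zmax, length.out = n_z + 1)
  ring <- cbind(a * sin(phi), -b * cos(phi))
  v <- cbind(ring[rep(seq_len(n_phi), times = n_z + 1), ],
             rep(zz, each = n_phi))
  id <- function(iphi, iz) (iz - 1) * n_phi + ((iphi - 1) %% n_phi) + 1
  f <- NULL
  for (iz in seq_len(n_z)) {
    i <- seq_len(n_phi)
    f <- rbind(f,
               cbind(id(i, iz), id(i + 1, iz), id(i + 1, iz + 1)),
               cbind(id(i, iz), id(i + 1, iz + 1), id(i, iz + 1)))
  }
  cb <- nrow(v) + 1L  # bottom center
  ct <- nrow(v) + 2L  # top center
  v <- rbind(v, c(0, 0, zmin), c(0, 0, zmax))
  i <- seq_len(n_phi)
  f <- rbind(f,
             cbind(cb, id(i + 1, 1), id(i, 1)),
             cbind(ct, id(i, n_z + 1), id(i + 1, n_z + 1)))
  m <- .mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Signed enclosed volume of a triangulated surface
#'
#' Positive for a closed surface with outward-oriented faces (divergence
#' theorem applied to the position field).
#'
#' @param mesh A mesh.
#' @return Volume (mm^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Euler characteristic of a mesh
#'
#' V - E + F; equals 2 for a closed surface of sphere topology.
#'
#' @param mesh A mesh.
#' @return Integer.
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  nrow(mesh$vertices) - length(unique(key)) + nrow(f)
}

#' Check that a mesh is a closed oriented surface
#'
#' Every undirected edge must be used by exactly two faces, once in each
#' direction.
#'
#' @param mesh A mesh.
#' @return Logical.
#' @export
mesh_is_closed <- function(mesh) {
  f <- mesh$faces
  dir_edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key_u <- paste(pmin(dir_edges[, 1], dir_edges[, 2]),
                 pmax(dir_edges[, 1], dir_edges[, 2]))
  cnt <- table(key_u)
  if (any(cnt != 2L)) return(FALSE)
  key_d <- paste(dir_edges[, 1], dir_edges[, 2])
  !any(duplicated(key_d))
}

#' Triangle areas and vertex area weights
#'
#' @param mesh A mesh.
#' @return List with `face_areas` and `vertex_areas` (one third of each
#'   incident triangle's area).
#' @export
mesh_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  va <- numeric(nrow(v))
  for (k in 1:3) {
    s <- rowsum(fa / 3, f[, k])
    va[as.integer(rownames(s))] <- va[as.integer(rownames(s))] + s
  }
  list(face_areas = fa, vertex_areas = va)
}

#' Write a mesh as an ASCII OFF file
#'
#' @param mesh A mesh.
#' @param path Output file path.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  utils::write.table(format(mesh$vertices, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ASCII OFF file
#'
#' @param path File path.
#' @return A mesh.
#' @export
read_off <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF") stop("not an OFF file", call. = FALSE)
  hd <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- hd[1]; nf <- hd[2]
  vv <- do.call(rbind, lapply(ln[2 + seq_len(nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  ff <- do.call(rbind, lapply(ln[2 + nv + seq_len(nf)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]])))
  stopifnot(all(ff[, 1] == 3L))
  .mesh(vv[, 1:3, drop = FALSE], ff[, 2:4, drop = FALSE] + 1L)
}
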