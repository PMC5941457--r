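#' Wavefront propagation configuration
#'
#' Conduction is modelled as expanding wavefronts: per-node activation times
#' are shortest travel times through the 26-neighbour voxel graph, with a
#' baseline conduction velocity everywhere and a faster endocardial layer L1
#' standing in for the sub-endocardial Purkinje network.
#'
#' @param velocity Baseline conduction velocity in m/s (default 0.5;
#'   1 m/s = 1 mm/ms).
#' @param l1_multiplier Speed multiplier of layer L1 (default 3).
#' @param sites Matrix (S x 3) of heart-local target coordinates for the
#'   pacing sites, or `NULL` for the default early-activation sites: three
#'   left-ventricular endocardial sites (anterior paraseptal, posterior,
#'   mid-septal) and one right-ventricular septal endocardial site. Each
#'   target is snapped to the nearest endocardial (L1) node of its ventricle.
#' @param onsets Onset time (ms) per site, recycled.
#' @return An object of class `propagation_config`.
#' @export
propagation_config <- function(velocity = 0.5, l1_multiplier = 3,
                               sites = NULL, onsets = 0) {
  if (velocity <= 0) stop("velocity must be positive", call. = FALSE)
  if (l1_multiplier < 1) stop("L1 speed multiplier must be >= 1", call. = FALSE)
  structure(list(velocity = velocity, l1_multiplier = l1_multiplier,
                 sites = sites, onsets = onsets),
            class = "propagation_config")
}

# default early-activation targets in heart-local mm, derived from the
# model geometry; ventricle restricts the snap
.default_sites <- function(model) {
  p <- model$params
  lv_in <- p$lv_outer - p$lv_wall
  rv_in <- p$rv_outer - p$rv_wall
  ang <- function(th) c(sin(th * pi / 180), -cos(th * pi / 180))
  mk <- function(th, z, semi) c(ang(th) * semi[1:2], z)
  rbind(
    LV_ant_paraseptal = c(mk(-50, -5, lv_in)),
    LV_posterior      = c(mk(180, -5, lv_in)),
    LV_midseptal      = c(mk(-95,  0, lv_in)),
    RV_septal         = c(p$rv_center[1] + rv_in[1], p$rv_center[2], 0)
  )
}

.snap_to_l1 <- function(model, target, ventricle) {
  cand <- which(model$layer == 1L & model$ventricle == ventricle)
  if (!length(cand)) cand <- which(model$layer == 1L)
  d2 <- colSums((t(model$coords[cand, , drop = FALSE]) - target)^2)
  cand[which.min(d2)]
}

#' Compute per-node activation times
#'
#' Runs a Dijkstra shortest-travel-time computation over the 26-neighbour
#' voxel graph; each edge costs its Euclidean length divided by the mean
#' conduction speed of its two endpoints.
#'
#' @param model A [build_heart_model()] result.
#' @param cfg A [propagation_config()].
#' @return An object of class `activation_map`: list with `time` (ms per
#'   node), `unreachable` (logical), `start_rows`, `cfg`.
#' @export
compute_activation <- function(model, cfg = propagation_config()) {
  stopifnot(inherits(model, "heart_model"), inherits(cfg, "propagation_config"))
  if (is.null(cfg$sites)) {
    tg <- .default_sites(model)
    vent <- c("LV", "LV", "LV", "RV")
    start_rows <- vapply(seq_len(nrow(tg)),
                         function(i) .snap_to_l1(model, tg[i, ], vent[i]),
                         integer(1))
  } else {
    sites <- as.matrix(cfg$sites)
    if (ncol(sites) != 3L || nrow(sites) < 1L)
      stop("`sites` must be an S x 3 coordinate matrix", call. = FALSE)
    start_rows <- apply(sites, 1, function(s) {
      d2 <- colSums((t(model$coords) - s)^2)
      r <- which.min(d2)
      if (d2[r] > (4 * model$resolution)^2)
        stop("starting point lies outside the myocardium", call. = FALSE)
      r
    })
  }
  onsets <- rep_len(cfg$onsets, length(start_rows))

  v0 <- cfg$velocity  # m/s == mm/ms
  speed <- rep(v0, model$n_nodes)
  speed[model$layer == 1L] <- v0 * cfg$l1_multiplier

  row_of <- integer(prod(model$dims))
  row_of[model$grid_index] <- seq_len(model$n_nodes)

  tm <- dijkstra_grid_cpp(model$ijk, model$dims, row_of, speed,
                          as.integer(start_rows), as.numeric(onsets),
                          model$resolution)
  structure(list(time = tm, unreachable = !is.finite(tm),
                 start_rows = start_rows, onsets = onsets, cfg = cfg),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("Activation map: %d nodes, %d pacing sites, range %.1f-%.1f ms",
              length(x$time), length(x$start_rows),
              min(x$time[is.finite(x$time)]), max(x$time[is.finite(x$time)])))
  if (any(x$unreachable)) cat(sprintf(", %d UNREACHABLE", sum(x$unreachable)))
  cat("\n")
  invisible(x)
}

#' End of the QRS complex
#'
#' The model-derived J-point anchor: the time at which the last node has
#' completed its upstroke.
#'
#' @param map An [compute_activation()] result.
#' @param upstroke Upstroke duration (ms) of the AP templates in use.
#' @return Time (ms).
#' @export
qrs_end <- function(map, upstroke = 2) {
  stopifnot(inherits(map, "activation_map"))
  if (any(map$unreachable))
    stop("activation map has unreachable nodes", call. = FALSE)
  max(map$time) + upstroke
}
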