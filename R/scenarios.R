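#' Alternans scenario specification
#'
#' Describes one beat-to-beat alternans pattern: the mechanism (APD
#' alternans or phase-II amplitude alternans), the spatial topology
#' (concordant, one of three discordant pairs, or one of ten regional
#' masks), the targeted wall layer and the magnitude.
#'
#' Default magnitudes follow the simulated protocols: +-4% APD for the
#' concordant and discordant APD scenarios, 10% APD prolongation for the
#' regional scenarios, and a 10% phase-II amplitude decrease for the
#' amplitude mechanism.
#'
#' @param mechanism `"APD"` or `"AMPLITUDE"`.
#' @param topology One of [region_names()].
#' @param layer Target layer, `"L2"`..`"L5"`.
#' @param magnitude Fractional change; `NULL` picks the mechanism/topology
#'   default. Zero gives a null scenario (no beat-to-beat change).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(mechanism = c("APD", "AMPLITUDE"),
                          topology = "CONC", layer = "L5",
                          magnitude = NULL) {
  mechanism <- match.arg(mechanism)
  if (!topology %in% .region_vocabulary)
    stop(sprintf("unknown topology '%s'", topology), call. = FALSE)
  if (!layer %in% paste0("L", 2:5))
    stop("target layer must be one of L2..L5", call. = FALSE)
  if (is.null(magnitude)) {
    magnitude <- if (mechanism == "AMPLITUDE") 0.10
    else if (startsWith(topology, "R_")) 0.10
    else 0.04
  }
  if (magnitude < 0) stop("magnitude must be non-negative", call. = FALSE)
  structure(list(mechanism = mechanism, topology = topology,
                 layer = layer, magnitude = magnitude),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario: %s / %s / %s, magnitude %.3g\n",
              x$mechanism, x$topology, x$layer, x$magnitude))
  invisible(x)
}

#' Scenario label (stable identifier)
#' @param spec A `scenario_spec`.
#' @return A single string like `"APD_CONC_L5"`.
#' @export
scenario_id <- function(spec) {
  id <- gsub("[/]", "", sprintf("%s_%s_%s", spec$mechanism, spec$topology, spec$layer))
  def <- if (spec$mechanism == "AMPLITUDE") 0.10
  else if (startsWith(spec$topology, "R_")) 0.10 else 0.04
  if (spec$magnitude != def) id <- sprintf("%s_m%g", id, spec$magnitude)
  id
}

#' Per-node AP assignment of one beat of an alternans scenario
#'
#' Starting from the reference per-layer templates, applies the scenario's
#' transformation to the targeted topology-layer intersection for the given
#' beat parity:
#' \itemize{
#'   \item APD concordant: target nodes shortened (x(1-m)) on even beats and
#'     lengthened (x(1+m)) on odd beats;
#'   \item APD discordant: the two complementary regions change in opposite
#'     phase and swap with parity;
#'   \item APD regional: one-sided prolongation (x(1+m)) on odd beats,
#'     reference on even beats;
#'   \item amplitude: phase-II plateau scaled by (1-m) on odd beats
#'     (for discordant topologies region A on odd and region B on even
#'     beats, mirroring the discordant APD construction).
#' }
#' All other nodes keep their layer's reference template.
#'
#' @param model A `heart_model`.
#' @param layer_table Reference [layer_ap_table()].
#' @param spec A [scenario_spec()].
#' @param parity `"even"` or `"odd"`.
#' @return An [ap_assignment()].
#' @export
assign_ap <- function(model, layer_table, spec, parity = c("even", "odd")) {
  parity <- match.arg(parity)
  stopifnot(inherits(spec, "scenario_spec"))
  assign <- ap_assignment(model, layer_table)
  m <- spec$magnitude
  if (m == 0) return(assign)

  layer_idx <- as.integer(substring(spec$layer, 2))
  in_layer <- model$layer == layer_idx
  region <- select_region(model, spec$topology)
  discordant <- is.list(region)

  add_group <- function(assign, mask, transform) {
    if (!any(mask)) stop("empty scenario mask", call. = FALSE)
    gid <- length(assign$templates) + 1L
    assign$templates[[gid]] <- transform(assign$templates[[layer_idx]])
    assign$group[mask] <- gid
    assign
  }

  if (spec$mechanism == "APD") {
    if (discordant) {
      fa <- if (parity == "even") 1 - m else 1 + m
      fb <- if (parity == "even") 1 + m else 1 - m
      assign <- add_group(assign, region$a & in_layer,
                          function(t) scale_apd(t, fa))
      assign <- add_group(assign, region$b & in_layer,
                          function(t) scale_apd(t, fb))
    } else if (spec$topology == "CONC") {
      f <- if (parity == "even") 1 - m else 1 + m
      assign <- add_group(assign, in_layer, function(t) scale_apd(t, f))
    } else {
      if (parity == "odd")
        assign <- add_group(assign, region & in_layer,
                            function(t) scale_apd(t, 1 + m))
      else if (!any(region & in_layer)) stop("empty scenario mask", call. = FALSE)
    }
  } else { # AMPLITUDE
    if (discordant) {
      mask <- if (parity == "odd") region$a & in_layer else region$b & in_layer
      assign <- add_group(assign, mask, function(t) scale_phase2(t, 1 - m))
    } else {
      mask <- (if (spec$topology == "CONC") rep(TRUE, model$n_nodes) else region) &
        in_layer
      if (parity == "odd")
        assign <- add_group(assign, mask, function(t) scale_phase2(t, 1 - m))
      else if (!any(mask)) stop("empty scenario mask", call. = FALSE)
    }
  }
  assign
}

#' Simulate the even/odd beat pair of a scenario
#'
#' Both beats share the activation map and the transfer matrix; only the AP
#' templates differ. Each beat is simulated on its own time window starting
#' at its QRS onset (no restitution coupling between beats).
#'
#' @param model A `heart_model`.
#' @param activation A [compute_activation()] result.
#' @param tm A [build_transfer_matrix()] result (or `NULL` for VCG-only use).
#' @param spec A [scenario_spec()].
#' @param layer_table Reference templates.
#' @param t_grid Beat sampling grid (ms, 1 ms step by default).
#' @param gain Dipole gain.
#' @param block_mm Source aggregation block size (mm).
#' @return An object of class `beat_pair`: raw electrode recordings
#'   (`even`, `odd`), VCG recordings (`vcg_even`, `vcg_odd`), the scenario
#'   and the shared annotations.
#' @export
simulate_beat_pair <- function(model, activation, tm, spec,
                               layer_table = layer_ap_table(),
                               t_grid = seq(0, 540, by = 1),
                               gain = default_dipole_gain(model$resolution),
                               block_mm = 5) {
  stopifnot(inherits(spec, "scenario_spec"))
  upstroke <- layer_table[[1]]$upstroke
  jp <- qrs_end(activation, upstroke)
  q0 <- min(activation$onsets)

  one <- function(parity) {
    asg <- assign_ap(model, layer_table, spec, parity)
    sq <- build_sequence(model, activation, asg, t_grid, gain, block_mm)
    rec <- if (!is.null(tm)) forward(tm, sq) else NULL
    if (!is.null(rec)) { rec$qrs_onset <- q0; rec$j_point <- jp }
    list(rec = rec, vcg = derive_vcg(sq, qrs_onset = q0, j_point = jp))
  }
  ev <- one("even"); od <- one("odd")
  structure(list(even = ev$rec, odd = od$rec,
                 vcg_even = ev$vcg, vcg_odd = od$vcg,
                 spec = spec, qrs_onset = q0, j_point = jp),
            class = "beat_pair")
}

#' @export
print.beat_pair <- function(x, ...) {
  cat("Beat pair for ")
  print(x$spec)
  invisible(x)
}

#' Lead-system view of a beat pair
#'
#' @param pair A [simulate_beat_pair()] result.
#' @param lead_system `"12lead"`, `"bspm"`, `"vcg"` or `"electrodes"`.
#' @return List with `even` and `odd` `ecg_recording`s.
#' @export
beat_pair_leads <- function(pair, lead_system = c("12lead", "bspm", "vcg", "electrodes")) {
  lead_system <- match.arg(lead_system)
  stopifnot(inherits(pair, "beat_pair"))
  if (lead_system == "vcg")
    return(list(even = pair$vcg_even, odd = pair$vcg_odd))
  if (is.null(pair$even))
    stop("beat pair was simulated without a transfer matrix", call. = FALSE)
  if (lead_system == "electrodes")
    return(list(even = pair$even, odd = pair$odd))
  list(even = derive_leads(pair$even, lead_system),
       odd = derive_leads(pair$odd, lead_system))
}

#' Full scenario catalog
#'
#' The cross product of mechanisms, topologies and target layers as
#' simulated in the study protocol: APD alternans over all 14 topologies
#' (concordant, 3 discordant, 10 regional) and amplitude alternans over the
#' concordant and discordant topologies, each in layers L2..L5 -- 72
#' scenarios in a deterministic order.
#'
#' @param mechanisms Subset of `c("APD", "AMPLITUDE")`.
#' @param layers Subset of `paste0("L", 2:5)`.
#' @return List of `scenario_spec`s.
#' @export
scenario_catalog <- function(mechanisms = c("APD", "AMPLITUDE"),
                             layers = paste0("L", 2:5)) {
  stopifnot(all(mechanisms %in% c("APD", "AMPLITUDE")),
            all(layers %in% paste0("L", 2:5)))
  out <- list()
  for (mech in mechanisms) {
    topos <- if (mech == "APD") .region_vocabulary
    else c("CONC", "D_P/A", "D_L/R", "D_A/B")
    for (tp in topos) for (ly in layers)
      out[[length(out) + 1L]] <- scenario_spec(mech, tp, ly)
  }
  out
}
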