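#' Run configuration
#'
#' Config-driven orchestration of the full simulation pipeline. The
#' configuration is a named list (or YAML file) with optional blocks:
#' \describe{
#'   \item{heart}{`resolution` (mm) plus any [ellipsoid_params()] override.}
#'   \item{torso}{any [torso_params()] override.}
#'   \item{action_potentials}{`apd`: named L1..L5 APD90 values (ms).}
#'   \item{propagation}{`velocity` (m/s), `l1_multiplier`.}
#'   \item{simulation}{`t_max` (ms), `block_mm`, `gain`,
#'     `purkinje_weight`.}
#'   \item{scenarios}{list of scenario blocks (`mechanism`, `topology`,
#'     `layer`, optional `magnitude`), or `catalog: true` with optional
#'     `mechanisms` / `layers` restriction.}
#'   \item{lead_systems}{subset of `c("12lead", "bspm", "vcg")`.}
#' }
#'
#' @param config A named list or the path of a YAML file.
#' @return An object of class `run_config` (the completed list).
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()  # empty YAML file
  stopifnot(is.list(config))
  def <- list(
    heart = list(resolution = 2),
    torso = list(),
    action_potentials = list(),
    propagation = list(velocity = 0.5, l1_multiplier = 3),
    simulation = list(t_max = 540, block_mm = 5, gain = NULL,
                      purkinje_weight = 0.02),
    scenarios = list(catalog = TRUE),
    lead_systems = c("12lead", "bspm", "vcg"),
    seed = 1L
  )
  deep <- c("heart", "torso", "propagation", "simulation")
  for (nm in names(def))
    if (is.null(config[[nm]])) config[[nm]] <- def[[nm]]
    else if (nm %in% deep && is.list(config[[nm]]))
      for (k in setdiff(names(def[[nm]]), names(config[[nm]])))
        config[[nm]][[k]] <- def[[nm]][[k]]
  structure(config, class = "run_config")
}

.config_scenarios <- function(config) {
  sc <- config$scenarios
  if (isTRUE(sc$catalog) || isTRUE(sc[["catalog"]])) {
    mech <- sc$mechanisms %||% c("APD", "AMPLITUDE")
    lay <- sc$layers %||% paste0("L", 2:5)
    return(scenario_catalog(mech, lay))
  }
  lapply(sc, function(s)
    scenario_spec(s$mechanism %||% "APD", s$topology %||% "CONC",
                  s$layer %||% "L5", s$magnitude))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# build (or fetch from cache) the static stage: model, activation, torso,
# transfer matrix
.build_stage <- function(config, cache_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  hp <- config$heart
  res <- hp$resolution %||% 2
  ep <- do.call(ellipsoid_params, hp[setdiff(names(hp), "resolution")])
  t0 <- Sys.time()
  model <- build_heart_model(grid_spec(res), ep)
  say("heart model: %d nodes at %.3g mm [%.1f s]", model$n_nodes, res,
      as.numeric(Sys.time() - t0, units = "secs"))

  apcfg <- config$action_potentials
  layer_table <- if (!is.null(apcfg$apd))
    layer_ap_table(apd = unlist(apcfg$apd)) else layer_ap_table()

  pcfg <- config$propagation
  act <- compute_activation(model, propagation_config(pcfg$velocity,
                                                      pcfg$l1_multiplier))

  tp <- do.call(torso_params, config$torso)
  torso <- build_torso(tp, ep)

  bl <- source_blocks(model, config$simulation$block_mm)
  src <- heart_to_torso(model, bl$centers)

  tm <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    key <- .obj_hash(list(torso[c("surfaces", "sigma")], src))
    cache_file <- file.path(cache_dir, paste0("transfer-", key, ".rds"))
    if (file.exists(cache_file)) {
      tm <- readRDS(cache_file)
      say("transfer matrix: cache hit (%s)", basename(cache_file))
    }
  }
  if (is.null(tm)) {
    t0 <- Sys.time()
    tm <- build_transfer_matrix(torso, src)
    say("transfer matrix: %d x %d [%.1f s]", nrow(tm$matrix), ncol(tm$matrix),
        as.numeric(Sys.time() - t0, units = "secs"))
    if (!is.null(cache_dir)) saveRDS(tm, cache_file)
  }
  gain <- config$simulation$gain %||% default_dipole_gain(res)
  list(model = model, layer_table = layer_table, activation = act,
       torso = torso, tm = tm, gain = gain,
       weights = source_weights(model, config$simulation$purkinje_weight),
       t_grid = seq(0, config$simulation$t_max, by = 1),
       block_mm = config$simulation$block_mm)
}

.write_signals_csv <- function(rec, parity, path, append = FALSE) {
  df <- data.frame(time_ms = rep(rec$times, each = length(rec$leads)),
                   lead = rep(rec$leads, times = length(rec$times)),
                   parity = parity,
                   mV = as.numeric(rec$signals))
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = !append, append = append, quote = FALSE)
}

#' Run the simulation pipeline described by a configuration
#'
#' Builds the heart and torso once, assembles (and caches) the transfer
#' matrix, simulates every configured scenario and writes, per scenario,
#' tidy signal CSVs, a metrics JSON and (for BSPM) the TWA amplitude map
#' CSV, plus a catalog-level summary table and a provenance manifest.
#' A failing scenario is recorded and skipped; the run continues.
#'
#' @param config A [run_config()] (or list / YAML path accepted by it).
#' @param out_dir Output directory.
#' @param cache_dir Optional cache directory for the transfer matrix.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the summary data.frame (one row per scenario) with an
#'   attribute `failures` naming failed scenarios.
#' @export
run_pipeline <- function(config = run_config(), out_dir, cache_dir = NULL,
                         quiet = FALSE) {
  config <- run_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  stage <- .build_stage(config, cache_dir, quiet)
  specs <- .config_scenarios(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  rows <- list(); failures <- character(0)
  for (sp in specs) {
    sid <- scenario_id(sp)
    res <- tryCatch({
      t0 <- Sys.time()
      pair <- simulate_beat_pair(stage$model, stage$activation, stage$tm, sp,
                                 layer_table = stage$layer_table,
                                 t_grid = stage$t_grid, gain = stage$gain,
                                 block_mm = stage$block_mm)
      sdir <- file.path(out_dir, sid)
      dir.create(sdir, showWarnings = FALSE)
      metrics <- list(scenario = unclass(sp))
      for (ls in config$lead_systems) {
        tw <- compute_twa(pair, ls)
        leads <- beat_pair_leads(pair, ls)
        .write_signals_csv(leads$even, "even",
                           file.path(sdir, paste0("signals_", ls, ".csv")))
        .write_signals_csv(leads$odd, "odd",
                           file.path(sdir, paste0("signals_", ls, ".csv")),
                           append = TRUE)
        metrics[[ls]] <- list(
          vma_mV = tw$vma, vaa_rad = tw$vaa,
          max_amplitude_mV = max(tw$amplitudes),
          max_lead = tw$max_lead,
          detected_leads = names(tw$amplitudes)[tw$detected],
          qt_alternans_ms = if (is.na(tw$qt_alternans)) NULL else tw$qt_alternans,
          window_ms = unlist(tw$window))
        if (ls == "bspm") {
          mp <- bspm_twa_map(tw$amplitudes)
          utils::write.table(mp$map,
                             file.path(sdir, "twa_map_bspm.csv"),
                             sep = ",", row.names = FALSE, col.names = FALSE)
        }
      }
      jsonlite::write_json(metrics, file.path(sdir, "metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      tw12 <- if ("12lead" %in% config$lead_systems)
        metrics[["12lead"]] else metrics[[config$lead_systems[1]]]
      say("%-18s max %s %.1f uV [%.1f s]", sid,
          tw12$max_lead, 1e3 * tw12$max_amplitude_mV,
          as.numeric(Sys.time() - t0, units = "secs"))
      data.frame(scenario = sid, mechanism = sp$mechanism,
                 topology = sp$topology, layer = sp$layer,
                 magnitude = sp$magnitude,
                 vma_mV = tw12$vma_mV, vaa_rad = tw12$vaa_rad,
                 max_amplitude_mV = tw12$max_amplitude_mV,
                 max_lead = tw12$max_lead,
                 qt_alternans_ms = tw12$qt_alternans_ms %||% NA_real_)
    }, error = function(e) {
      warning(sprintf("scenario %s failed: %s", sid, conditionMessage(e)),
              call. = FALSE)
      failures <<- c(failures, sid)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }

  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scenario = character(0))
  utils::write.table(summary, file.path(out_dir, "summary.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("twasim")),
    config = unclass(config),
    n_scenarios = length(specs), n_failed = length(failures),
    failed = failures,
    model_nodes = stage$model$n_nodes,
    transfer_hash = stage$tm$torso_hash
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(summary, "failures") <- failures
  invisible(summary)
}

#' Miniature models for fast end-to-end runs
#'
#' Coarse versions of the full pipeline inputs used by the test suite and
#' for quick experiments: `"tiny"` is a 4 mm heart with a low-density torso
#' (sub-second beats), `"small"` a 2 mm heart with the default torso.
#'
#' @param size `"tiny"` or `"small"`.
#' @return List with `model`, `layer_table`, `activation`, `torso`, `tm`,
#'   `gain`, `block_mm`.
#' @export
make_fixtures <- function(size = c("tiny", "small")) {
  size <- match.arg(size)
  if (size == "tiny") {
    res <- 4
    tp <- torso_params(n_phi = 16, n_z = 8, lung_subdiv = 1, cavity_subdiv = 1)
    block <- 8
  } else {
    res <- 2
    tp <- torso_params()
    block <- 5
  }
  ep <- ellipsoid_params()
  model <- build_heart_model(grid_spec(res), ep)
  act <- compute_activation(model)
  torso <- build_torso(tp, ep)
  bl <- source_blocks(model, block)
  tm <- build_transfer_matrix(torso, heart_to_torso(model, bl$centers))
  list(model = model, layer_table = layer_ap_table(), activation = act,
       torso = torso, tm = tm, gain = default_dipole_gain(res),
       block_mm = block)
}

#' Save / load a heart model with provenance checking
#'
#' The model is serialized with a hash of its generating parameters; loading
#' verifies the hash so silently mismatched geometry cannot sneak into a
#' cached pipeline.
#'
#' @param model A `heart_model`.
#' @param path File path (.rds).
#' @return `save_heart_model` returns the path invisibly;
#'   `load_heart_model` the model.
#' @export
save_heart_model <- function(model, path) {
  stopifnot(inherits(model, "heart_model"))
  payload <- list(model = model,
                  params_hash = .obj_hash(list(model$grid, model$params)))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_heart_model
#' @export
load_heart_model <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$params_hash,
                 .obj_hash(list(payload$model$grid, payload$model$params))))
    stop("heart model file is corrupt: parameter hash mismatch", call. = FALSE)
  payload$model
}

#' Export an activation map as CSV
#'
#' Writes one row per myocardial node: voxel indices, heart-local
#' coordinates and the activation time (ms).
#'
#' @param model The `heart_model` the map was computed on.
#' @param map An [compute_activation()] result.
#' @param path Output CSV path.
#' @export
write_activation_csv <- function(model, map, path) {
  stopifnot(inherits(map, "activation_map"),
            length(map$time) == model$n_nodes)
  df <- data.frame(node = seq_len(model$n_nodes),
                   i = model$ijk[, 1], j = model$ijk[, 2], k = model$ijk[, 3],
                   x_mm = model$coords[, 1], y_mm = model$coords[, 2],
                   z_mm = model$coords[, 3],
                   activation_ms = map$time)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
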