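tiny_cfg <- function(scenarios) {
  run_config(list(
    heart = list(resolution = 4),
    torso = list(n_phi = 16, n_z = 8, lung_subdiv = 1, cavity_subdiv = 1),
    simulation = list(block_mm = 8),
    lead_systems = c("12lead", "bspm", "vcg"),
    scenarios = scenarios))
}

test_that("an empty scenario list yields an empty summary and a manifest", {
  out <- file.path(tempdir(), "twasim-empty")
  s <- run_pipeline(tiny_cfg(list()), out_dir = out, quiet = TRUE)
  expect_equal(nrow(s), 0)
  expect_length(attr(s, "failures"), 0)
  expect_true(file.exists(file.path(out, "summary.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
})

test_that("a null scenario produces an all-zero metrics row", {
  out <- file.path(tempdir(), "twasim-null")
  cfg <- tiny_cfg(list(list(mechanism = "APD", topology = "CONC",
                            layer = "L5", magnitude = 0)))
  s <- run_pipeline(cfg, out_dir = out, quiet = TRUE)
  expect_equal(nrow(s), 1)
  expect_equal(s$vma_mV, 0)
  expect_equal(s$vaa_rad, 0)
  expect_equal(s$max_amplitude_mV, 0)
  expect_equal(s$qt_alternans_ms, 0)
})

test_that("reruns with an identical config write byte-identical metrics", {
  cfg <- tiny_cfg(list(list(mechanism = "APD", topology = "CONC", layer = "L5")))
  cache <- file.path(tempdir(), "twasim-cache")
  o1 <- file.path(tempdir(), "twasim-r1")
  o2 <- file.path(tempdir(), "twasim-r2")
  run_pipeline(cfg, out_dir = o1, cache_dir = cache, quiet = TRUE)
  run_pipeline(cfg, out_dir = o2, cache_dir = cache, quiet = TRUE)
  f1 <- readLines(file.path(o1, "APD_CONC_L5", "metrics.json"))
  f2 <- readLines(file.path(o2, "APD_CONC_L5", "metrics.json"))
  expect_identical(f1, f2)
  expect_gt(length(list.files(cache)), 0)  # transfer matrix was cached
})

test_that("tiny end-to-end run produces nonzero alternans for CONC/APD/L5", {
  out <- file.path(tempdir(), "twasim-e2e")
  cfg <- tiny_cfg(list(list(mechanism = "APD", topology = "CONC", layer = "L5")))
  s <- run_pipeline(cfg, out_dir = out, quiet = TRUE)
  expect_gt(s$vma_mV, 0)
  expect_true(file.exists(file.path(out, "APD_CONC_L5", "twa_map_bspm.csv")))
  mp <- as.matrix(utils::read.csv(file.path(out, "APD_CONC_L5", "twa_map_bspm.csv"),
                                  header = FALSE))
  expect_equal(dim(mp), c(12, 16))
  sig <- utils::read.csv(file.path(out, "APD_CONC_L5", "signals_12lead.csv"))
  expect_setequal(unique(sig$lead),
                  c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6)))
  expect_setequal(unique(sig$parity), c("even", "odd"))
})

test_that("a failing scenario is isolated and reported without aborting the run", {
  # a beat window that ends before the J-point makes the T-wave window
  # detection fail inside the scenario loop
  cfg <- run_config(list(
    heart = list(resolution = 4),
    torso = list(n_phi = 16, n_z = 8, lung_subdiv = 1, cavity_subdiv = 1),
    simulation = list(block_mm = 8, t_max = 40),
    lead_systems = "12lead",
    scenarios = list(list(mechanism = "APD", topology = "CONC", layer = "L5"))))
  out <- file.path(tempdir(), "twasim-fail")
  expect_warning(
    s <- run_pipeline(cfg, out_dir = out, quiet = TRUE),
    "failed")
  expect_equal(nrow(s), 0)
  expect_equal(attr(s, "failures"), "APD_CONC_L5")
  manifest <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(manifest$n_failed, 1)
})

test_that("fixture sizes build end-to-end", {
  f <- fixture("tiny")
  expect_s3_class(f$model, "heart_model")
  expect_s3_class(f$tm, "transfer_matrix")
  expect_false(any(f$activation$unreachable))
})

test_that("heart models round-trip through disk with provenance checking", {
  m <- fixture("tiny")$model
  path <- tempfile(fileext = ".rds")
  save_heart_model(m, path)
  m2 <- load_heart_model(path)
  expect_identical(m2$layer, m$layer)
  expect_identical(m2$grid_index, m$grid_index)
  # tampering with the stored parameters is detected
  payload <- readRDS(path)
  payload$model$params$lv_wall <- 99
  saveRDS(payload, path)
  expect_error(load_heart_model(path), "hash mismatch")
})

test_that("activation maps export as per-node CSV", {
  f <- fixture("tiny")
  path <- tempfile(fileext = ".csv")
  write_activation_csv(f$model, f$activation, path)
  df <- utils::read.csv(path)
  expect_equal(nrow(df), f$model$n_nodes)
  expect_equal(df$activation_ms, f$activation$time, tolerance = 1e-9)
})
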