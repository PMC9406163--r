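small_session <- function(seed = 6L) {
  spec <- protocol_spec(n_trials = 2L, sample_rate = 100)
  simulate_session("P01", "passive", participant_profile("healthy"), spec,
                   default_library(), seed = seed)
}

test_that("bundled session files round-trip losslessly", {
  ses <- small_session()
  f <- tempfile(fileext = ".json")
  write_session(ses, f, bundle = TRUE)
  back <- read_session(f)
  expect_equal(back$participant_id, ses$participant_id)
  expect_equal(back$condition, ses$condition)
  for (i in seq_along(ses$trials)) {
    a <- ses$trials[[i]]; b <- back$trials[[i]]
    expect_identical(b$identified_shape_id, a$identified_shape_id)
    expect_identical(b$certainty, a$certainty)
    expect_equal(b$plan$option_ids, a$plan$option_ids, ignore_attr = TRUE)
    for (ph in c("exploration", "reproduction")) {
      expect_lt(max(abs(b[[ph]]$x - a[[ph]]$x)), 1e-9)
      expect_lt(max(abs(b[[ph]]$y - a[[ph]]$y)), 1e-9)
      expect_lt(max(abs(b[[ph]]$t - a[[ph]]$t)), 1e-9)
    }
  }
  unlink(f)
})

test_that("directory session layout round-trips and validates its CSVs", {
  ses <- small_session(7L)
  d <- tempfile("sessdir")
  write_session(ses, d, bundle = FALSE)
  back <- read_session(d)
  tr <- ses$trials[[1L]]$exploration
  expect_lt(max(abs(back$trials[[1L]]$exploration$x - tr$x)), 1e-9)

  # schema violation: a trajectory file losing its time column
  f1 <- file.path(d, "trial01_exploration.csv")
  lines <- readLines(f1)
  lines[1L] <- sub("t_s", "time", lines[1L])
  writeLines(lines, f1)
  expect_error(read_session(d), "t_s")

  # non-monotone timestamps
  write_session(ses, d, bundle = FALSE)
  lines <- readLines(f1)
  lines[3L] <- lines[2L]
  writeLines(lines, f1)
  expect_error(read_session(d), "non-monotone")
  unlink(d, recursive = TRUE)
})

test_that("shape library, parameter table and factor model files round-trip", {
  lib <- default_library()
  f <- tempfile(fileext = ".json")
  write_shape_library(lib, f)
  back <- read_shape_library(f)
  expect_equal(names(back), names(lib))
  for (id in names(lib)) {
    expect_equal(back[[id]]$vertices, lib[[id]]$vertices, ignore_attr = TRUE)
    expect_equal(back[[id]]$class_label, lib[[id]]$class_label)
  }
  expect_equal(attr(back, "seed"), attr(lib, "seed"))

  tab <- one_factor_table(40, c(0.9, 0.8, 0.7, 0.6, 0.5), seed = 51)
  tab <- cbind(participant_id = sprintf("H%02d", 1:40), group = "healthy",
               condition = "passive", tab, procrustes_scale = 1.41,
               certainty_mean = 2.2, n_valid_trials = 15L)
  fp <- tempfile(fileext = ".csv")
  write_parameter_table(tab, fp)
  tback <- read_parameter_table(fp)
  expect_equal(names(tback)[1:3], c("participant_id", "group", "condition"))
  expect_equal(tback$dtw, tab$dtw, tolerance = 1e-12)

  model <- fit_paf(tab)
  fm <- tempfile(fileext = ".json")
  write_factor_model(model, fm)
  mback <- read_factor_model(fm)
  expect_equal(mback$loadings, model$loadings, tolerance = 1e-12)
  expect_equal(weighted_z_factor_scores(mback, tab[1:5, ]),
               weighted_z_factor_scores(model, tab[1:5, ]),
               tolerance = 1e-10)
  unlink(c(f, fp, fm))
})

test_that("pipeline configs validate their keys", {
  f <- tempfile(fileext = ".json")
  writeLines('{"n_healthy": 12, "seed": 3}', f)
  cfg <- read_pipeline_config(f)
  expect_equal(cfg$n_healthy, 12L)
  expect_equal(cfg$seed, 3L)
  writeLines('{"n_healthy": 12, "frobnicate": 1}', f)
  expect_error(read_pipeline_config(f), "frobnicate")
  expect_error(pipeline_config(gamma = 0.7))
  unlink(f)
})

test_that("the end-to-end pipeline is deterministic and guards its artifacts", {
  out <- file.path(tempdir(), "pipe_out")
  unlink(out, recursive = TRUE)
  cfg <- pipeline_config(n_healthy = 10L, n_stroke = 2L, seed = 9L,
                         spec = protocol_spec(n_trials = 4L,
                                              sample_rate = 200),
                         n_samples = 200L, output_dir = out)
  res <- run_pipeline(cfg, quiet = TRUE)
  expect_true(file.exists(file.path(out, "parameters.csv")))
  expect_true(file.exists(file.path(out, "factor_passive.json")))
  expect_true(file.exists(file.path(out, "norms_active.csv")))
  expect_true(file.exists(file.path(out, "flags_passive.csv")))
  expect_true(file.exists(file.path(out, "stats.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 9L)
  expect_equal(man$n_sessions, 24L)
  hrows <- res$parameters$group == "healthy" &
    res$parameters$condition == "passive"
  expect_equal(mean(res$parameters$factor_score[hrows]), 0,
               tolerance = 1e-10)

  bytes1 <- readBin(file.path(out, "parameters.csv"), "raw", 1e6)
  res2 <- run_pipeline(cfg, quiet = TRUE)
  bytes2 <- readBin(file.path(out, "parameters.csv"), "raw", 1e6)
  expect_identical(bytes1, bytes2)

  cfg2 <- cfg
  cfg2$seed <- 10L
  expect_error(run_pipeline(cfg2, quiet = TRUE), "hash")
  unlink(out, recursive = TRUE)
})

test_that("a cohort without patients still yields norms but no patient outputs", {
  out <- file.path(tempdir(), "pipe_h")
  unlink(out, recursive = TRUE)
  cfg <- pipeline_config(n_healthy = 10L, n_stroke = 0L, seed = 2L,
                         conditions = "passive",
                         spec = protocol_spec(n_trials = 4L,
                                              sample_rate = 200),
                         n_samples = 200L, output_dir = out)
  expect_message(run_pipeline(cfg), "no stroke")
  expect_true(file.exists(file.path(out, "norms_passive.csv")))
  expect_false(file.exists(file.path(out, "flags_passive.csv")))
  expect_false(file.exists(file.path(out, "stats.json")))
  unlink(out, recursive = TRUE)
})
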