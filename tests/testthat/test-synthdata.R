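test_that("passive traversal is a minimum-jerk bell peaking at the protocol speed", {
  lib <- default_library()
  spec <- protocol_spec()
  for (s in lib[c(1, 6, 11)]) {
    tr <- simulate_passive_exploration(s, spec)
    v <- sensproc:::finite_diff_speed(tr$t, cbind(tr$x, tr$y))
    expect_equal(max(v), 0.67, tolerance = 0.005 / 0.67)
    expect_lt(v[1L], 0.005)
    expect_lt(v[length(v)], 0.005)
    expect_equal(sensproc:::arc_length(cbind(tr$x, tr$y)) * 100,
                 shape_perimeter(s), tolerance = 1e-3)
  }
  degenerate <- make_shape(rbind(c(0, 0), c(0, 0), c(0, 0)))
  expect_error(simulate_passive_exploration(degenerate, spec), "perimeter")
})

test_that("active exploration stays inside the zero-force corridor", {
  lib <- default_library()
  spec <- quick_spec()
  prof <- participant_profile("healthy")
  tr <- simulate_active_exploration(lib[[2]], prof, spec, seed = 9)
  d_cm <- dist_to_polyline(cbind(tr$x, tr$y) * 100, shape_path(lib[[2]]))
  expect_true(all(d_cm <= spec$corridor_half_width + 1e-6))
  expect_identical(tr, simulate_active_exploration(lib[[2]], prof, spec,
                                                   seed = 9))
})

test_that("deterministic active traversal lasts perimeter / speed seconds", {
  lib <- default_library()
  spec <- quick_spec()
  prof <- participant_profile("healthy", path_noise_sd = 0,
                              active_speed_sd = 0)
  tr <- simulate_active_exploration(lib[[1]], prof, spec, seed = 1)
  P_m <- shape_perimeter(lib[[1]]) / 100
  expect_equal(tr$t[length(tr$t)], P_m / prof$active_speed_mean,
               tolerance = 1e-6)
  v <- sensproc:::finite_diff_speed(tr$t, cbind(tr$x, tr$y))
  expect_equal(stats::median(v), prof$active_speed_mean, tolerance = 1e-3)
})

test_that("noise-free reproduction retraces the explored geometry", {
  lib <- default_library()
  spec <- protocol_spec()
  prof0 <- participant_profile("healthy", scale_mean = 1, scale_sd = 0,
                               rotation_sd = 0, vertex_jitter_sd = 0,
                               path_noise_sd = 0, shape_confusion_prob = 0)
  for (s in lib[c(4, 12)]) {
    rp <- simulate_reproduction(s, prof0, spec, seed = 2)
    A <- arc_resample(shape_path(s), 500L)
    B <- arc_resample(cbind(rp$x, rp$y) * 100, 500L)
    expect_lt(max(sqrt(rowSums((A - B)^2))), 0.01)
    expect_equal(c(rp$x[1L], rp$y[1L]), c(0, 0))
    expect_equal(c(rp$x[length(rp$x)], rp$y[length(rp$y)]), c(0, 0),
                 tolerance = 1e-9)
  }
})

test_that("pure scale-1.41 reproduction is recovered by the Procrustes fit", {
  lib <- default_library()
  spec <- protocol_spec()
  prof <- participant_profile("healthy", scale_mean = 1.41, scale_sd = 0,
                              rotation_sd = 0, vertex_jitter_sd = 0,
                              path_noise_sd = 0, shape_confusion_prob = 0)
  # the fixed 1 cm crop disc spans different relative arc fractions of the
  # exploration and the enlarged reproduction, so single-trial estimates
  # carry a small crop-asymmetry bias (see the methods vignette); the
  # cohort-level recovery at +/- 0.02 is asserted in the acceptance suite
  scales <- vapply(c(3, 5, 12), function(i) {
    ex <- simulate_passive_exploration(lib[[i]], spec)
    rp <- simulate_reproduction(lib[[i]], prof, spec, seed = 11)
    pf <- procrustes_fit(time_normalize(segment_phase(ex)),
                         time_normalize(segment_phase(rp)))
    expect_lt(pf$d, 0.02)
    pf$scale
  }, numeric(1))
  expect_equal(mean(scales), 1.41, tolerance = 0.03 / 1.41)
})

test_that("the stroke profile degrades similarity more than the healthy one", {
  lib <- default_library()
  spec <- quick_spec()
  ex <- simulate_passive_exploration(lib[[7]], spec)
  E <- time_normalize(segment_phase(ex), 200L)
  dtw_of <- function(profile, seeds) {
    vapply(seeds, function(s) {
      rp <- simulate_reproduction(lib[[7]], profile, spec, seed = s,
                                  library = lib)
      dtw_distance(E, time_normalize(segment_phase(rp), 200L))
    }, numeric(1))
  }
  h <- dtw_of(participant_profile("healthy"), 1:100)
  st <- dtw_of(participant_profile("stroke"), 101:200)
  expect_gt(mean(st), mean(h))
})

test_that("identification follows the stated response model", {
  lib <- default_library()
  spec <- protocol_spec(rng_seed = 4L)
  plan <- build_protocol(lib, spec, "passive")[[1L]]
  sure <- participant_profile("healthy", identification_error_prob = 0)
  never <- participant_profile("healthy", identification_error_prob = 1)
  for (s in 1:20) {
    expect_identical(
      simulate_identification(plan, TRUE, sure, seed = s, lib)$shape_id,
      plan$shape_id)
    wrong <- simulate_identification(plan, TRUE, never, seed = s, lib)
    expect_false(wrong$shape_id == plan$shape_id)
    expect_true(wrong$shape_id %in% plan$option_ids)
    expect_true(wrong$certainty %in% 0:3)
  }
  p40 <- participant_profile("healthy", identification_error_prob = 0.4)
  hits <- vapply(seq_len(10000L), function(s) {
    simulate_identification(plan, TRUE, p40, seed = s, lib)$shape_id ==
      plan$shape_id
  }, logical(1))
  expect_equal(mean(hits), 0.6, tolerance = 0.02 / 0.6)
})

test_that("cohort simulation is reproducible with the expected layout", {
  lib <- default_library()
  spec <- quick_spec(n_trials = 2L)
  ses <- simulate_cohort(3, 2, spec = spec, library = lib, seed = 5)
  expect_length(ses, 10L)
  expect_equal(sum(vapply(ses, `[[`, "", "group") == "healthy"), 6L)
  conds <- vapply(ses, `[[`, "", "condition")
  expect_equal(sum(conds == "passive"), 5L)
  for (s in ses) {
    expect_length(s$trials, 2L)
    for (tr in s$trials) {
      expect_true(tr$identified_shape_id %in% tr$plan$option_ids)
      expect_true(tr$certainty %in% 0:3)
      expect_true(all(diff(tr$exploration$t) > 0))
      expect_true(all(diff(tr$reproduction$t) > 0))
    }
  }
  ses2 <- simulate_cohort(3, 2, spec = spec, library = lib, seed = 5)
  expect_identical(ses, ses2)
})
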