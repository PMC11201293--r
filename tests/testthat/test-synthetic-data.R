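test_that("transition matrix hits the target stationary profile and switch rate", {
  fo <- c(0.3, 0.2, 0.5)
  for (rate in c(0.02, 0.06, 0.08, 0.3)) {
    A <- switching_transition_matrix(fo, rate)
    expect_equal(rowSums(A), rep(1, 3))
    expect_equal(drop(fo %*% A), fo, tolerance = 1e-12)
    expect_equal(sum(fo * (1 - diag(A))), rate, tolerance = 1e-12)
  }
  expect_equal(switching_transition_matrix(c(0.5, 0.5), 0), diag(2))
  expect_error(switching_transition_matrix(c(0.9, 0.1), 0.9), "infeasible")
})

test_that("zero switch rate gives constant-state paths; one state is degenerate", {
  cfg <- sim_config(n_patients = 5, n_controls = 0, n_parcels = 4,
                    n_volumes = 50, n_states = 4, patient_switch_rate = 0,
                    seed = 1)
  set.seed(1)
  p <- generate_state_paths(cfg, "patient")
  expect_true(all(apply(p, 1, function(r) length(unique(r)) == 1)))
  cfg1 <- sim_config(n_patients = 2, n_controls = 0, n_parcels = 3,
                     n_volumes = 30, n_states = 1, patient_switch_rate = 0,
                     control_switch_rate = 0, seed = 1)
  set.seed(1)
  p1 <- generate_state_paths(cfg1, "patient")
  expect_true(all(p1 == 1L))
})

test_that("empirical group switch rate converges to the configured rate", {
  cfg <- sim_config(n_patients = 0, n_controls = 200, n_parcels = 4,
                    n_volumes = 230, n_states = 6,
                    control_switch_rate = 0.06, seed = 1)
  set.seed(10)
  p <- generate_state_paths(cfg, "control")
  sr <- apply(p, 1, function(r) mean(r[-1] != r[-length(r)]))
  expect_lt(abs(mean(sr) - 0.06), 0.01)
  # occupancy converges to the stationary target too
  fo <- colMeans(t(apply(p, 1, tabulate, nbins = 6)) / 230)
  expect_lt(max(abs(fo - 1 / 6)), 0.02)
})

test_that("noise-free single-state emission is constant at the state mean", {
  cfg <- sim_config(n_patients = 0, n_controls = 1, n_parcels = 5,
                    n_volumes = 40, n_states = 1, noise_sd = 0,
                    control_switch_rate = 0, seed = 3)
  set.seed(3)
  means <- state_mean_patterns(cfg)
  paths <- generate_state_paths(cfg, "control")
  x <- render_node_series(paths, cfg, "control", means)[[1]]
  expect_equal(unname(x), matrix(means[1, ], 40, 5, byrow = TRUE))
})

test_that("planted amplitude deficit lowers patient f1ALFF in affected parcels", {
  cfg <- sim_config(n_patients = 40, n_controls = 40, n_parcels = 6,
                    n_volumes = 230, n_states = 3,
                    affected_parcels = 1:2, effect_amplitude = 0.4,
                    effect_extra_noise_sd = 0, noise_sd = 0.5, seed = 7)
  co <- simulate_cohort(cfg)
  f1 <- t(vapply(co$node_series, function(x)
    as.numeric(falff(detrend_linear(x, 2)$data, c(0.01, 0.027), 2)),
    numeric(6)))
  pat <- co$manifest$group == "patient"
  for (p in 1:2)
    expect_lt(mean(f1[pat, p]), mean(f1[!pat, p]))
})

test_that("regeneration under a fixed seed is identical", {
  cfg <- sim_config(n_patients = 3, n_controls = 3, n_parcels = 5,
                    n_volumes = 60, n_states = 3, seed = 11)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
})

test_that("cohort truth is internally consistent", {
  cfg <- sim_config(n_patients = 6, n_controls = 5, n_parcels = 4,
                    n_volumes = 80, n_states = 4, seed = 5)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$manifest), 11)
  expect_false(anyDuplicated(co$manifest$subject) > 0)
  sr <- apply(co$truth$paths, 1, function(p) mean(p[-1] != p[-length(p)]))
  expect_equal(unname(co$truth$sr), unname(sr))
  expect_equal(unname(rowSums(co$truth$fo)), rep(1, 11))
})

test_that("atlas hosts every parcel with at least 27 voxels; sizing errors are explicit", {
  atlas <- make_atlas(c(14, 14, 14), 90)
  counts <- table(atlas[atlas > 0])
  expect_equal(sort(as.integer(names(counts))), 1:90)
  expect_true(all(counts >= 27))
  expect_error(make_atlas(c(12, 12, 12), 90), "2430")
})

test_that("parcel means of noise-free volumes reproduce the node series exactly", {
  cfg <- sim_config(n_patients = 1, n_controls = 1, n_parcels = 6,
                    n_volumes = 40, n_states = 2, voxel_noise_sd = 0, seed = 9)
  co <- simulate_cohort(cfg, volumes = TRUE)
  for (id in co$manifest$subject) {
    ex <- extract_parcel_series(co$volumes[[id]], co$atlas)
    expect_equal(unname(ex), unname(co$node_series[[id]]), tolerance = 1e-12)
  }
})

test_that("written cohorts round-trip through TSV", {
  cfg <- sim_config(n_patients = 2, n_controls = 1, n_parcels = 4,
                    n_volumes = 30, n_states = 2, seed = 13)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- as.matrix(utils::read.table(
    file.path(dir, "sub001_series.tsv"), header = TRUE, sep = "\t"))
  expect_equal(unname(back), unname(co$node_series[["sub001"]]),
               tolerance = 1e-6)
})
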