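test_that("template maps are zero-mean, unit-norm, distinct and reproducible", {
  ts <- make_templates(64, 4, seed = 1)
  expect_equal(nrow(ts$maps), 4)
  expect_lt(max(abs(rowMeans(ts$maps))), 1e-12)
  expect_equal(unname(rowSums(ts$maps^2)), rep(1, 4), tolerance = 1e-12)
  # pairwise spatial correlation stays well below the identifiability bound
  R <- abs(stats::cor(t(ts$maps)))
  expect_lt(max(R[upper.tri(R)]), 0.9)
  expect_identical(ts$maps, make_templates(64, 4, seed = 1)$maps)
  expect_false(identical(ts$maps, make_templates(64, 4, seed = 2)$maps))
  ts2 <- make_templates(8, 2, seed = 7)
  expect_lt(spatial_correlation(ts2$maps[1, ], ts2$maps[2, ]), 0.9)
  expect_error(make_templates(8, 8, seed = 1), "rank limit")
})

test_that("simulated run lengths follow the requested mean duration", {
  ts <- make_templates(16, 4, seed = 1)
  sim <- simulate_recording(ts, 60, 250, mean_durations_ms = 40, snr = 5,
                            seed = 11)
  runs <- sim$truth$runs
  n <- length(sim$truth$labels)
  expect_equal(n, 15000)
  interior <- runs$start > 1 & (runs$start + runs$length - 1) < n
  emp_ms <- mean(runs$length[interior]) * 1000 / 250
  expect_lt(abs(emp_ms - 40) / 40, 0.15)
  # no immediate self-transitions, all runs at least one sample
  expect_true(all(diff(runs$class) != 0))
  expect_true(all(runs$length >= 1))
})

test_that("simulation is seed-deterministic and validates snr", {
  ts <- make_templates(16, 4, seed = 1)
  a <- simulate_recording(ts, 5, 250, snr = 5, seed = 3)
  b <- simulate_recording(ts, 5, 250, snr = 5, seed = 3)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_error(simulate_recording(ts, 5, 250, snr = 0, seed = 1), "snr")
  expect_error(simulate_recording(ts, 5, 250, mean_durations_ms = 4,
                                  seed = 1), "2 samples")
})

test_that("noise-free single-class recording backfits to that class everywhere", {
  maps <- orthonormal_maps(2, 16, seed = 4)
  ts <- ms_templates(maps)
  one <- ms_templates(maps[1, , drop = FALSE])
  sim <- simulate_recording(one, 4, 250, mean_durations_ms = 40, snr = Inf,
                            seed = 5)
  ep <- average_reference(epoch_and_select(sim$recording, 2, 2))
  lab <- backfit(ep, ts)
  expect_true(all(lab$labels == 1L))
})

test_that("ground-truth parameters are internally consistent", {
  ts <- make_templates(16, 4, seed = 2)
  sim <- simulate_recording(ts, 60, 250, mean_durations_ms = c(35, 40, 45, 50),
                            snr = 5, seed = 6)
  runs <- sim$truth$runs
  n <- length(sim$truth$labels)
  rtt <- vapply(1:4, function(j)
    sum(runs$length[runs$class == j]) / n, numeric(1))
  expect_equal(sum(rtt), 1, tolerance = 1e-12)
  # occurrence x MMD / 1000 ~ RTT per class (interior runs only)
  interior <- runs$start > 1 & (runs$start + runs$length - 1) < n
  for (j in 1:4) {
    sel <- runs$class == j & interior
    mmd <- mean(runs$length[sel]) * 4
    occ <- sum(sel) / 60
    rtt_int <- sum(runs$length[sel]) / n
    expect_lt(abs(occ * mmd / 1000 - rtt_int) / rtt_int, 0.05)
  }
})

test_that("group study applies effects in the right direction with covariates", {
  study <- simulate_group_study(n_patients = 12, n_controls = 10, seed = 8,
                                duration_s = 30, n_channels = 16,
                                signals = FALSE)
  expect_s3_class(study, "ms_study")
  expect_equal(as.vector(table(study$group)), c(10, 12))
  expect_equal(nrow(study$covariates), 22)
  expect_false(anyNA(study$covariates))
  # same seed gives a byte-identical covariate table
  study2 <- simulate_group_study(n_patients = 12, n_controls = 10, seed = 8,
                                 duration_s = 30, n_channels = 16,
                                 signals = FALSE)
  expect_identical(study$covariates, study2$covariates)
  expect_error(
    simulate_group_study(4, 4, effects = effect_spec(
      duration_shift_ms = c(-39, 0, 0, 0)), n_channels = 16),
    "degenerate")
})

test_that("null effect specification yields nominal t-test rejection rates", {
  null_spec <- effect_spec(duration_shift_ms = rep(0, 4),
                           amplitude_scale = rep(1, 4))
  rej <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    st <- simulate_group_study(n_patients = 12, n_controls = 10,
                               effects = null_spec, seed = 1000 + r,
                               duration_s = 30, n_channels = 16,
                               signals = FALSE)
    mmd_a <- vapply(st$ground_truth, function(g) g$parameters$mmd_ms[1],
                    numeric(1))
    tt <- ttest_from_data(mmd_a[st$group == "patient"],
                          mmd_a[st$group == "control"])
    if (tt$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.01)
  expect_lte(rej / n_rep, 0.10)
})

test_that("synthetic lead field is average-referenced, smooth and full rank", {
  lf <- make_leadfield(64, 200, seed = 3)
  expect_equal(dim(lf$matrix), c(64, 200))
  expect_lt(max(abs(colMeans(lf$matrix))), 1e-12)
  expect_true(all(colSums(lf$matrix^2) > 0))
  lf2 <- make_leadfield(16, 10, seed = 3)
  expect_equal(qr(lf2$matrix)$rank, 10)
  expect_identical(lf$matrix, make_leadfield(64, 200, seed = 3)$matrix)
})
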