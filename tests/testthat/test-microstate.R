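test_that("GFP is the spatial RMS of average-referenced maps", {
  g <- gfp(one_epoch(matrix(c(1, -1), 2, 1)))
  expect_equal(g$values[1, 1], 1.0)
  g2 <- gfp(one_epoch(matrix(c(2, 0, -2, 0), 4, 1)))
  expect_equal(g2$values[1, 1], sqrt(2))
  g3 <- gfp(one_epoch(matrix(0, 4, 3)))
  expect_equal(unname(g3$values[1, ]), c(0, 0, 0))
})

test_that("GFP peak picking finds strict local maxima with distance pruning", {
  pk <- gfp_peaks(c(0, 1, 0, 1, 0), min_distance_ms = 0, fs = 250)
  expect_equal(pk$sample, c(2, 4))
  expect_error(gfp_peaks(c(1, 2, 3, 4, 5), fs = 250), "no GFP peaks")
  # two close peaks inside the minimum distance: the larger survives
  pk2 <- gfp_peaks(c(0, 1, 0, 2, 0), min_distance_ms = 12, fs = 250)
  expect_equal(pk2$sample, 4)
  # boundaries are never peaks
  pk3 <- gfp_peaks(c(5, 1, 2, 1, 5), min_distance_ms = 0, fs = 250)
  expect_equal(pk3$sample, 3)
})

test_that("spatial correlation is polarity-invariant and validates input", {
  u <- c(1, -2, 1, 0.5)
  expect_equal(spatial_correlation(u, u), 1.0)
  expect_equal(spatial_correlation(u, -u), 1.0)
  expect_equal(spatial_correlation(u, -u, polarity_invariant = FALSE), -1.0)
  M <- orthonormal_maps(2, 16)
  expect_equal(spatial_correlation(M[1, ], M[2, ]), 0, tolerance = 1e-10)
  expect_error(spatial_correlation(u, rep(3, 4)), "zero-variance")
})

test_that("modified k-means recovers planted templates from sign-flipped copies", {
  M <- orthonormal_maps(4, 32, seed = 9)
  sgn <- withr::with_seed(13, sample(c(-1, 1), 40, replace = TRUE))
  X <- M[rep(1:4, each = 10), ] * rep(sgn, times = 32)
  km <- modified_kmeans(X, k = 4, restarts = 20, seed = 2)
  expect_gt(km$gev_total, 0.999)
  # every planted map matched by some template despite the sign flips
  best <- apply(abs(stats::cor(t(M), t(km$templates$maps))), 1, max)
  expect_true(all(best > 0.999))
})

test_that("modified k-means attains GEV 1 when n = k and is seed-stable", {
  X <- orthonormal_maps(3, 16, seed = 5) * 3
  km <- modified_kmeans(X, k = 3, restarts = 10, seed = 1)
  expect_equal(km$gev_total, 1.0, tolerance = 1e-9)
  km2 <- modified_kmeans(X, k = 3, restarts = 10, seed = 1)
  expect_identical(km$templates$maps, km2$templates$maps)
  expect_identical(km$assignments, km2$assignments)
  expect_error(modified_kmeans(X, k = 5), "at least k")
})

test_that("modified k-means matches exhaustive bipartition search at k = 2", {
  for (s in 1:3) {
    X <- withr::with_seed(s, matrix(stats::rnorm(10 * 16), 10, 16))
    km <- modified_kmeans(X, k = 2, restarts = 60, seed = 7)
    expect_equal(km$gev_total, exhaustive_bipartition_gev(X),
                 tolerance = 1e-9)
  }
})

test_that("class ordering maximizes total correlation over all permutations", {
  M <- orthonormal_maps(4, 32, seed = 3)
  canonical <- ms_templates(M, LETTERS[1:4])
  # shuffled, sign-flipped copy of the canonical set recovers identity
  shuf <- ms_templates(M[c(3, 1, 4, 2), ] * c(-1, 1, -1, 1))
  ord <- order_classes(shuf, canonical)
  expect_equal(matched_abs_r(ord, canonical), rep(1, 4), tolerance = 1e-12)
  # signs aligned to positive correlation with the canonical maps
  for (j in 1:4)
    expect_gt(spatial_correlation(ord$maps[j, ], M[j, ],
                                  polarity_invariant = FALSE), 0.99)
  # a case where greedy row-wise matching fails but exhaustive succeeds
  u <- orthonormal_maps(2, 16, seed = 8)
  t1 <- 0.9 * u[1, ] + 0.85 * u[2, ]
  t2 <- 0.88 * u[1, ] + 0.10 * u[2, ]
  ord2 <- order_classes(ms_templates(rbind(t1, t2)),
                        ms_templates(u, c("A", "B")))
  expect_gt(spatial_correlation(ord2$maps[1, ], t2), 0.999)  # t2 -> A
  expect_gt(spatial_correlation(ord2$maps[2, ], t1), 0.999)  # t1 -> B
  # templates orthogonal to every canonical map: still a bijection, warned
  W <- orthonormal_maps(4, 16, seed = 8)[3:4, ]
  expect_warning(ord3 <- order_classes(ms_templates(W),
                                       ms_templates(u, c("A", "B"))),
                 "weak match")
  expect_setequal(ord3$class_labels, c("A", "B"))
})

test_that("backfitting labels noise-free data correctly and permutes with templates", {
  ts <- make_templates(16, 4, seed = 1)
  sim <- simulate_recording(ts, 20, 250, mean_durations_ms = 40, snr = Inf,
                            seed = 4)
  ep <- average_reference(epoch_and_select(sim$recording, 2, 10))
  lab <- backfit(ep, ts)
  truth <- matrix(sim$truth$labels[1:5000], 10, 500, byrow = TRUE)
  expect_gt(mean(lab$labels == truth), 0.99)
  # swapping template order permutes labels identically
  ts_swap <- ms_templates(ts$maps[c(2, 1, 4, 3), ])
  lab2 <- backfit(ep, ts_swap)
  expect_equal(c(2L, 1L, 4L, 3L)[lab$labels], as.vector(lab2$labels))
  # sign flip of a template leaves labels unchanged
  ts_flip <- ms_templates(ts$maps * c(-1, 1, 1, -1))
  lab3 <- backfit(ep, ts_flip)
  expect_identical(lab$labels, lab3$labels)
})

test_that("microstate parameters match hand-computable label patterns", {
  M <- orthonormal_maps(2, 16, seed = 6)
  ts <- ms_templates(M, c("A", "B"))
  # constant single-class epoch: RTT 1, GEV ~ 1 for that class
  X <- tcrossprod(M[1, ], rep(1, 500)) * 5
  ep <- one_epoch(X, fs = 250)
  lab <- backfit(ep, ts)
  pars <- microstate_parameters(lab, ep, ts)
  expect_equal(pars$rtt, c(1, 0))
  expect_equal(pars$gev[1], 1, tolerance = 1e-9)
  expect_true(is.na(pars$mmd_ms[2]))
  # strict alternation ABAB...: every interior run is one sample = 4 ms
  alt <- M[rep(c(1, 2), 250), ] * 3
  ep2 <- one_epoch(t(alt), fs = 250)
  lab2 <- backfit(ep2, ts)
  expect_equal(as.vector(lab2$labels), rep(c(1L, 2L), 250))
  pars2 <- microstate_parameters(lab2, ep2, ts)
  expect_equal(pars2$mmd_ms, c(4, 4))
  expect_equal(pars2$rtt, c(0.5, 0.5))
})

test_that("parameter invariants hold on simulated data", {
  ts <- make_templates(16, 4, seed = 3)
  sim <- simulate_recording(ts, 30, 250, mean_durations_ms = 40, snr = 5,
                            seed = 12)
  ep <- average_reference(epoch_and_select(bandpass(sim$recording), 2, 14))
  lab <- backfit(ep, ts)
  pars <- microstate_parameters(lab, ep, ts)
  expect_equal(sum(pars$rtt), 1, tolerance = 1e-9)
  expect_lte(sum(pars$gev), 1 + 1e-9)
  expect_true(all(pars$mmd_ms >= 1000 / 250, na.rm = TRUE))
  # consistent channel permutation leaves parameters unchanged
  perm <- withr::with_seed(1, sample(16))
  ep_p <- eeg_epochs(ep$epochs[, perm, , drop = FALSE], ep$fs)
  ts_p <- ms_templates(ts$maps[, perm])
  pars_p <- microstate_parameters(backfit(ep_p, ts_p), ep_p, ts_p)
  expect_equal(pars$mmd_ms, pars_p$mmd_ms)
  expect_equal(pars$gev, pars_p$gev, tolerance = 1e-9)
  # recovered MMD near the generating mean duration
  expect_lt(max(abs(pars$mmd_ms - 40)) / 40, 0.15)
})

test_that("two-level clustering recovers shared templates per group", {
  ts <- make_templates(16, 4, seed = 2)
  eps <- list()
  grp <- rep(c("patient", "control"), each = 3)
  for (s in 1:6) {
    sim <- simulate_recording(ts, 24, 250, mean_durations_ms = 40, snr = 5,
                              seed = 100 + s)
    eps[[sprintf("S%02d", s)]] <- average_reference(
      epoch_and_select(bandpass(sim$recording), 2, 10))
  }
  cl <- two_level_clustering(eps, grp, k = 4, restarts = 20, seed = 5)
  for (g in c("patient", "control")) {
    ord <- order_classes(cl$group[[g]], ts)
    expect_true(all(matched_abs_r(ord, ts) > 0.95))
  }
  # single-subject group: group templates equal that subject's templates
  cl1 <- two_level_clustering(eps[1], group = NULL, k = 4, restarts = 20,
                              seed = 5)
  r <- abs(stats::cor(t(cl1$group[["all"]]$maps), t(cl1$individual[[1]]$maps)))
  expect_true(all(apply(r, 1, max) > 1 - 1e-6))
  # permuting subject order leaves group templates unchanged up to sign/order
  perm <- c(4, 1, 3, 6, 2, 5)
  cl_p <- two_level_clustering(eps[perm], grp[perm], k = 4, restarts = 20,
                               seed = 5)
  for (g in c("patient", "control")) {
    a <- order_classes(cl$group[[g]], ts)
    b <- order_classes(cl_p$group[[g]], ts)
    expect_true(all(vapply(1:4, function(j)
      spatial_correlation(a$maps[j, ], b$maps[j, ]), numeric(1)) > 0.999))
  }
})
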