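# construct a sample with exactly the requested mean and sd
sample_with_summary <- function(n, mean, sd, seed) {
  x <- withr::with_seed(seed, stats::rnorm(n))
  x <- (x - mean(x)) / stats::sd(x)
  x * sd + mean
}

test_that("summary t-test reproduces printed group comparisons", {
  # microstate duration row: lower mean duration in the patient group
  tt <- ttest_from_summary(37.42, 2.56, 55, 39.54, 4.37, 27)
  expect_equal(tt$statistic, -2.77, tolerance = 0.01)
  expect_equal(tt$df, 80)
  # problem-solving task errors: higher in the patient group
  tt2 <- ttest_from_summary(60.84, 19.10, 55, 47.81, 28.01, 27)
  expect_equal(tt2$statistic, 2.48, tolerance = 0.01)
  # equal summaries give t = 0, p = 1
  tt0 <- ttest_from_summary(5, 1, 10, 5, 1, 12)
  expect_equal(tt0$statistic, 0)
  expect_equal(tt0$p, 1)
  expect_error(ttest_from_summary(1, 1, 1, 2, 1, 30), "n >= 2")
})

test_that("data t-test equals the summary t-test on the samples' own summaries", {
  x <- sample_with_summary(55, 37.97, 2.91, 1)
  y <- sample_with_summary(27, 40.29, 3.15, 2)
  tt <- ttest_from_data(x, y)
  expect_equal(tt$statistic, -3.30, tolerance = 0.01)
  ref <- ttest_from_summary(mean(x), stats::sd(x), 55,
                            mean(y), stats::sd(y), 27)
  expect_equal(tt$statistic, ref$statistic, tolerance = 1e-9)
  expect_equal(tt$p, ref$p, tolerance = 1e-9)
  z <- sample_with_summary(20, 3, 1, 3)
  expect_equal(ttest_from_data(z, z)$statistic, 0)
})

test_that("Bonferroni correction multiplies and caps", {
  p <- ttest_from_summary(37.42, 2.56, 55, 39.54, 4.37, 27)$p
  expect_equal(round(bonferroni(p, 4), 2), 0.03)
  expect_equal(bonferroni(0.5, 4), 1)
  expect_equal(bonferroni(0, 7), 0)
  expect_true(all(bonferroni(c(0.2, 0.01)) >= c(0.2, 0.01)))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("mixed ANOVA matches hand-computed split-plot sums of squares", {
  # 2 groups x 2 subjects x 2 classes, hand-computable
  vals <- rbind(c(10, 14), c(12, 18), c(20, 22), c(24, 28))
  grp <- c("g1", "g1", "g2", "g2")
  res <- mixed_anova(vals, grp)
  n_s <- 4; n_c <- 2
  gm <- mean(vals)
  subj_m <- rowMeans(vals); class_m <- colMeans(vals)
  grp_m <- as.vector(tapply(rowMeans(vals), grp, mean))
  cell_m <- rbind(colMeans(vals[1:2, ]), colMeans(vals[3:4, ]))
  ss_group <- n_c * 2 * sum((grp_m - gm)^2)
  ss_subj_within <- n_c * sum((subj_m - grp_m[c(1, 1, 2, 2)])^2)
  ss_class <- n_s * sum((class_m - gm)^2)
  ss_int <- 2 * sum((cell_m - outer(grp_m - gm, class_m - gm, "+") - gm)^2)
  ss_resid <- sum((vals - subj_m -
                     (cell_m[c(1, 1, 2, 2), ] - grp_m[c(1, 1, 2, 2)]))^2)
  f_group <- (ss_group / 1) / (ss_subj_within / 2)
  f_class <- (ss_class / 1) / (ss_resid / 2)
  f_int <- (ss_int / 1) / (ss_resid / 2)
  expect_equal(res$group$statistic, f_group, tolerance = 1e-9)
  expect_equal(res$class$statistic, f_class, tolerance = 1e-9)
  expect_equal(res$interaction$statistic, f_int, tolerance = 1e-9)
  expect_equal(res$group$df, c(1, 2))
  expect_equal(res$interaction$df, c(1, 2))
})

test_that("mixed ANOVA is shift-invariant and rejects incomplete designs", {
  withr::with_seed(21, vals <- matrix(stats::rnorm(30 * 4), 30, 4))
  grp <- rep(c("p", "c"), 15)
  a <- mixed_anova(vals, grp)
  b <- mixed_anova(vals + 17.3, grp)
  expect_equal(a$group$statistic, b$group$statistic, tolerance = 1e-9)
  expect_equal(a$class$statistic, b$class$statistic, tolerance = 1e-9)
  expect_equal(a$interaction$statistic, b$interaction$statistic,
               tolerance = 1e-9)
  vals[2, 3] <- NA
  expect_error(mixed_anova(vals, grp), "missing cells")
})

test_that("Greenhouse-Geisser correction shrinks df without changing F", {
  withr::with_seed(31, {
    vals <- matrix(stats::rnorm(24 * 4), 24, 4)
    vals[, 1] <- vals[, 1] * 3          # heterogeneous variances
  })
  grp <- rep(c("p", "c"), 12)
  plain <- mixed_anova(vals, grp)
  gg <- mixed_anova(vals, grp, sphericity = "greenhouse-geisser")
  expect_equal(gg$interaction$statistic, plain$interaction$statistic)
  expect_gte(gg$interaction$epsilon, 1 / 3)
  expect_lt(gg$interaction$epsilon, 1)
  # p recomputed at epsilon-scaled degrees of freedom
  eps <- gg$class$epsilon
  expect_equal(gg$class$p,
               stats::pf(plain$class$statistic, eps * plain$class$df[1],
                         eps * plain$class$df[2], lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("GLM recovers exact coefficients and flags collinearity", {
  withr::with_seed(22, x <- stats::rnorm(40))
  g <- glm_fit(2 * x, data.frame(x = x))
  expect_equal(g$beta[g$term == "x"], 2, tolerance = 1e-10)
  expect_true(all(g$ci_low <= g$beta & g$beta <= g$ci_high))
  g0 <- glm_fit(c(4, 6, 5, 5, 4, 6), data.frame(row.names = 1:6))
  expect_equal(g0$beta, 5)
  dup <- data.frame(a = x, b = 2 * x)
  expect_error(glm_fit(stats::rnorm(40), dup), "collinear.*b")
})

test_that("GLM recovers an injected covariate link in the group study", {
  hits <- 0
  for (r in 1:20) {
    st <- simulate_group_study(n_patients = 55, n_controls = 27,
                               seed = 400 + r, duration_s = 30,
                               n_channels = 16, signals = FALSE)
    mmd_b <- vapply(st$ground_truth, function(g) g$parameters$mmd_ms[2],
                    numeric(1))
    g <- glm_fit(scale(mmd_b)[, 1],
                 st$covariates[, c("ma_use_frequency", "twob",
                                   "ma_word_error")])
    row <- g[g$term == "twob", ]
    if (row$beta > 0 && row$ci_low > 0) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.8)
})

test_that("chi-square matches the direct expected-count formula", {
  counts <- matrix(c(37, 18, 18, 9), 2)  # male/female by group
  res <- chisq_2x2(counts)
  expect_lt(res$statistic, 0.01)   # prints as 0.00
  exp_counts <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  expect_equal(res$statistic, sum((counts - exp_counts)^2 / exp_counts),
               tolerance = 1e-12)
  expect_equal(res$df, 1)
  same <- matrix(c(20, 10, 40, 20), 2)
  expect_equal(chisq_2x2(same)$statistic, 0, tolerance = 1e-12)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 3), 2, byrow = TRUE)), "margin")
})

test_that("post-hoc power behaves like a proper power function", {
  expect_equal(posthoc_power(5, 1, 20, 5, 1, 20, alpha = 0.05), 0.05,
               tolerance = 1e-9)
  deltas <- seq(0, 2, by = 0.25)
  pw <- vapply(deltas, function(d)
    posthoc_power(5 + d, 1, 20, 5, 1, 20), numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_gt(posthoc_power(5.2, 1, 5000, 5, 1, 5000), 0.999)
  # observed study-scale difference yields usable power
  expect_gt(posthoc_power(37.42, 2.56, 55, 39.54, 4.37, 27), 0.5)
})

test_that("parameter table reports both groups with corrected p-values", {
  withr::with_seed(23, {
    params <- data.frame(
      subject = rep(sprintf("S%02d", 1:20), each = 4),
      group = rep(c("control", "patient"), each = 40),
      class = rep(LETTERS[1:4], 20),
      mmd_ms = stats::rnorm(80, 40, 3),
      gev = stats::runif(80, 0.1, 0.3))
  })
  tab <- parameter_table(params, bonferroni_m = 4)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$corrected_p >= tab$p))
  expect_true(all(tab$df == 18))
  expect_true(all(c("mean_patient", "sd_control") %in% names(tab)))
})
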