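test_that("noise-free data collapse the rank-inversion interval onto the point estimate", {
  # the sign-score statistic can only reject once enough observations
  # can change sign: at the median a small sample suffices, in the 5%
  # tail a larger one is needed (below that the interval is honestly
  # unbounded)
  df <- data.frame(age = seq(20, 80, length.out = 30))
  df$g_GCLplus <- 90 - 0.15 * df$age
  ci <- coefficient_ci(df, "g_GCLplus", 0.5)
  width <- ci$intervals$upper - ci$intervals$lower
  expect_true(all(width < 1e-4))
  expect_true(all(ci$intervals$lower <= ci$estimate &
                    ci$estimate <= ci$intervals$upper))

  df2 <- data.frame(age = seq(20, 80, length.out = 300))
  df2$g_GCLplus <- 90 - 0.15 * df2$age
  ci2 <- coefficient_ci(df2, "g_GCLplus", 0.05)
  expect_true(all(ci2$intervals$upper - ci2$intervals$lower < 1e-4))
})

test_that("bootstrap interval demands enough replicates and keeps its draws", {
  coh <- generate_healthy_cohort(rdb_cohort_config("small_rdb", n = 120,
                                                   seed = 8))
  expect_error(coefficient_ci(coh, "g_GCLplus", 0.05, method = "bootstrap",
                              B = 50), "B >= 100")
  ci <- coefficient_ci(coh, "g_GCLplus", 0.05, method = "bootstrap",
                       B = 120, seed = 1)
  expect_equal(dim(ci$replicates), c(120, 2))
  expect_true(all(ci$intervals$lower <= ci$estimate &
                    ci$estimate <= ci$intervals$upper))
})

test_that("rank-inversion and bootstrap intervals overlap and agree on the true slope", {
  true_slope <- default_metric_models()$beta_age[
    default_metric_models()$metric == "g_GCLplus"]
  agree <- overlap <- logical(40)
  for (i in seq_len(40)) {
    coh <- generate_healthy_cohort(
      rdb_cohort_config("small_rdb", n = 250, seed = 5000 + i))
    ri <- coefficient_ci(coh, "g_GCLplus", 0.05, coefficients = "age")
    bo <- coefficient_ci(coh, "g_GCLplus", 0.05, method = "bootstrap",
                         B = 120, seed = i)
    r <- ri$intervals[1, ]
    b <- bo$intervals[bo$intervals$coefficient == "age", ]
    overlap[i] <- r$lower <= b$upper && b$lower <= r$upper
    agree[i] <- (r$lower <= true_slope && true_slope <= r$upper) ==
      (b$lower <= true_slope && true_slope <= b$upper)
  }
  expect_true(all(overlap))
  expect_gte(mean(agree), 0.9)
})

test_that("rank inversion warns on very large samples", {
  coh <- rw_cohort()
  expect_warning(
    coefficient_ci(coh[seq_len(1500), ], "g_GCLplus", 0.05,
                   coefficients = "age"),
    "designed for smaller samples")
})

test_that("cutoff bands contain the point line and never narrow when intervals widen", {
  coh <- small_cohort()
  fit <- fit_qrl(coh, "g_GCLplus", 0.05)
  ci <- coefficient_ci(coh, "g_GCLplus", 0.05)
  band <- cutoff_band(fit, ci, age_grid = seq(25, 80, 5))
  expect_true(all(band$lower <= band$cutoff & band$cutoff <= band$upper))

  # zero-width intervals give a band equal to the line
  ci0 <- ci
  ci0$intervals$lower <- ci0$estimate
  ci0$intervals$upper <- ci0$estimate
  b0 <- cutoff_band(fit, ci0, age_grid = seq(25, 80, 5))
  expect_equal(b0$lower, b0$cutoff, tolerance = 1e-12)
  expect_equal(b0$upper, b0$cutoff, tolerance = 1e-12)

  # widening every coefficient interval by 10% never narrows the band
  wide <- ci
  mid <- (ci$intervals$lower + ci$intervals$upper) / 2
  half <- (ci$intervals$upper - ci$intervals$lower) / 2
  wide$intervals$lower <- mid - 1.1 * half
  wide$intervals$upper <- mid + 1.1 * half
  bw <- cutoff_band(fit, wide, age_grid = seq(25, 80, 5))
  expect_true(all(bw$lower <= band$lower + 1e-9))
  expect_true(all(bw$upper >= band$upper - 1e-9))

  expect_error(cutoff_band(fit, coefficient_ci(coh, "g_GCLplus", 0.01)),
               "disagree")
})

test_that("bootstrap band equals the percentile rule applied to replicate cutoff evaluations", {
  coh <- generate_healthy_cohort(rdb_cohort_config("small_rdb", n = 150,
                                                   seed = 31))
  fit <- fit_qrl(coh, "g_GCLplus", 0.05)
  ci <- coefficient_ci(coh, "g_GCLplus", 0.05, method = "bootstrap",
                       B = 600, seed = 2)
  band <- cutoff_band(fit, ci, age_grid = 60)
  evals <- ci$replicates[, "intercept"] + 60 * ci$replicates[, "age"]
  expect_equal(band$lower, min(oracle_quantile7(evals, 0.025), band$cutoff),
               tolerance = 1e-9)
  expect_equal(band$upper, max(oracle_quantile7(evals, 0.975), band$cutoff),
               tolerance = 1e-9)
})
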