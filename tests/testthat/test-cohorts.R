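test_that("healthy generation handles the empty and noise-free cases exactly", {
  cfg <- cohort_config(n = 0, age_mean = 50, age_sd = 10,
                       age_min = 20, age_max = 80, seed = 1)
  expect_equal(nrow(generate_healthy_cohort(cfg)), 0)

  # one eye, no noise, pinned age and disc area: exact linear arithmetic
  models <- default_metric_models()
  models <- models[models$metric == "g_cpRNFL", ]
  models$beta0 <- 110; models$beta_age <- -0.2
  models$beta_disc <- 2.0; models$sigma0 <- 0
  cfg <- cohort_config(n = 1, age_mean = 50, age_sd = 0,
                       age_min = 20, age_max = 80,
                       disc_mean = 2.0, disc_sd = 0,
                       models = models, seed = 1)
  eye <- generate_healthy_cohort(cfg)
  expect_equal(eye$g_cpRNFL, 110 - 0.2 * 50 + 2.0 * 2.0)  # 104.0
})

test_that("configuration invariants are enforced with a named violation", {
  expect_error(cohort_config(n = -1, age_mean = 50, age_sd = 10,
                             age_min = 20, age_max = 80), "n must be")
  expect_error(cohort_config(n = 5, age_mean = 50, age_sd = 10,
                             age_min = 80, age_max = 20), "age_min")
  expect_error(cohort_config(n = 5, age_mean = 50, age_sd = 10,
                             age_min = 20, age_max = 80,
                             hetero_slope = 0.1), "stay positive")
  expect_error(disease_config(loss_mean = -1, loss_sd = 1), "loss_mean")
  expect_error(disease_config(loss_mean = 1, loss_sd = 1, loss_floor = 0),
               "loss_floor")
})

test_that("generation is deterministic given the seed and respects truncation", {
  cfg <- rdb_cohort_config("small_rdb", n = 150, seed = 77)
  a <- generate_healthy_cohort(cfg)
  b <- generate_healthy_cohort(cfg)
  expect_identical(a, b)
  expect_true(all(a$age >= cfg$age_min & a$age <= cfg$age_max))
  expect_true(all(a$disc_area >= cfg$disc_min))

  dis <- disease_config(loss_mean = 30, loss_sd = 15, loss_floor = 25,
                        seed = 3)
  d <- generate_disease_cohort(rdb_cohort_config("disease", n = 200,
                                                 seed = 9), dis)
  reg <- metric_registry()
  for (m in reg$metric) expect_true(all(d[[m]] >= 25))
  expect_true(all(d$age >= 60 & d$age <= 92))
  expect_equal(unique(d$cohort), "disease_test")
})

test_that("zero disease effect reproduces healthy generation on the same seed", {
  cfg <- rdb_cohort_config("disease", n = 40, seed = 123)
  healthy <- generate_healthy_cohort(cfg)
  diseased <- generate_disease_cohort(cfg, disease_config(0, 0))
  for (m in metric_registry()$metric) {
    expect_equal(diseased[[m]], healthy[[m]])
  }
})

test_that("a fixed deficit is plain subtraction clipped at the floor", {
  models <- default_metric_models()
  models <- models[models$metric == "g_cpRNFL", ]
  models$beta0 <- 100; models$beta_age <- 0; models$beta_disc <- 0
  models$sigma0 <- 0
  cfg <- cohort_config(n = 1, age_mean = 70, age_sd = 0,
                       age_min = 60, age_max = 92, models = models,
                       seed = 1)
  d <- generate_disease_cohort(cfg, disease_config(25, 0, loss_floor = 20))
  expect_equal(d$g_cpRNFL, 75)
  d2 <- generate_disease_cohort(cfg, disease_config(95, 0, loss_floor = 20))
  expect_equal(d2$g_cpRNFL, 20)  # floored
})

test_that("summarize_cohort returns two-pass moments and flags degenerate input", {
  df <- data.frame(g_GCLplus = c(60, 70, 80))
  s <- summarize_cohort(df, "g_GCLplus")
  expect_equal(s$mean, 70)
  expect_equal(s$sd, 10)

  one <- summarize_cohort(data.frame(g_GCLplus = 71.3), "g_GCLplus")
  expect_equal(one$mean, 71.3)
  expect_true(is.na(one$sd))

  expect_error(summarize_cohort(data.frame(g_GCLplus = numeric(0)),
                                "g_GCLplus"), "empty cohort")

  coh <- small_cohort()
  s <- summarize_cohort(coh, "g_cpRNFL")
  o <- oracle_moments(coh$g_cpRNFL)
  expect_identical(s$mean, o$mean)
  expect_identical(s$sd, o$sd)
})

test_that("large reference cohort reproduces the real-world marginals", {
  rw <- rw_cohort()
  s_cp <- summarize_cohort(rw, "g_cpRNFL")
  expect_lt(abs(s_cp$mean - 103.3), 1.0)
  expect_lt(abs(s_cp$sd - 10.9), 1.0)
  s_gc <- summarize_cohort(rw, "g_GCLplus")
  expect_lt(abs(s_gc$mean - 71.1), 1.0)
  expect_lt(abs(s_gc$sd - 5.8), 1.0)
})

test_that("disease cohort reproduces the glaucomatous test-set marginals", {
  ong <- generate_disease_cohort(rdb_cohort_config("disease", seed = 183),
                                 rdb_disease_config())
  expect_lt(abs(summarize_cohort(ong, "g_cpRNFL")$mean - 81.0), 3)
  expect_lt(abs(summarize_cohort(ong, "g_GCLplus")$mean - 61.3), 3)
})

test_that("residual SD of a homoscedastic cohort matches sigma0 within 2%", {
  cfg <- rdb_cohort_config("large_rdb", n = 50000, seed = 50)
  models <- cfg$models
  coh <- generate_healthy_cohort(cfg)
  m <- models[models$metric == "g_GCLplus", ]
  resid_sd <- stats::sd(stats::residuals(stats::lm(g_GCLplus ~ age,
                                                   data = coh)))
  expect_lt(abs(resid_sd - m$sigma0) / m$sigma0, 0.02)
})

test_that("heteroscedastic option widens the residual spread with age", {
  cfg <- rdb_cohort_config("large_rdb", n = 20000, seed = 51,
                           hetero_slope = 0.01)
  coh <- generate_healthy_cohort(cfg)
  r <- stats::residuals(stats::lm(g_GCLplus ~ age, data = coh))
  young <- stats::sd(r[coh$age < 40])
  old <- stats::sd(r[coh$age > 60])
  expect_gt(old, young)
})
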