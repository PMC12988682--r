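make_fit <- function(metric, coefficients, tau) {
  structure(
    list(metric = metric, spec = metric_spec(metric), tau = tau,
         coefficients = coefficients, loss = NA_real_, n = NA_integer_,
         method = "quantile", degenerate = FALSE),
    class = "qrl_fit")
}

test_that("cutoff evaluation is plain linear arithmetic with covariate checks", {
  f_age <- make_fit("g_GCLplus", c(intercept = 80, age = -0.2), 0.05)
  expect_equal(evaluate_cutoff(f_age, age = 50), 70)
  f_cp <- make_fit("g_cpRNFL",
                   c(intercept = 80, age = -0.2, disc_area = 2.0), 0.05)
  expect_equal(evaluate_cutoff(f_cp, age = 50, disc_area = 2.0), 74)
  expect_error(evaluate_cutoff(f_cp, age = 50), "disc_area is required")
})

test_that("classification follows the strict-below color rule", {
  expect_equal(classify_eye(65, 70, 80), "red")
  expect_equal(classify_eye(75, 70, 80), "yellow")
  expect_equal(classify_eye(85, 70, 80), "green")
  # boundary: flagging means strictly below the percentile line
  expect_equal(classify_eye(80, 70, 80), "green")
  expect_equal(classify_eye(70, 70, 80), "yellow")
  # monotone in value
  v <- sort(runif(50, 60, 90))
  colors <- classify_eye(v, 70, 80)
  ranks <- match(colors, c("red", "yellow", "green"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("crossed cutoffs raise an informative error unless clamping is requested", {
  expect_error(classify_eye(75, cutoff_1 = 81, cutoff_5 = 80),
               "quantile crossing")
  clamped <- classify_eye(c(75, 79.5), cutoff_1 = 81, cutoff_5 = 80,
                          on_crossing = "clamp")
  expect_equal(clamped, c("red", "red"))
})

test_that("flagging a cohort partitions it and matches the in-sample quantile mass", {
  coh <- small_cohort()
  cs <- cutoff_set(coh, "g_GCLplus", rdb = "self")
  flags <- flag_cohort(coh, cs)
  expect_equal(nrow(flags), nrow(coh))
  counts <- flag_counts(flags)
  expect_equal(sum(counts), nrow(coh))
  # below-5th fraction close to 5% by the in-sample quantile property
  n <- nrow(coh); p <- 2
  frac_5 <- (counts[["yellow"]] + counts[["red"]]) / n
  expect_gte(frac_5, 0.05 - p / n)
  expect_lte(frac_5, 0.05 + p / n)
  frac_1 <- counts[["red"]] / n
  expect_gte(frac_1, 0.01 - p / n)
  expect_lte(frac_1, 0.01 + p / n)
})

test_that("lowering the first-percentile line never increases the red count", {
  coh <- small_cohort()
  cs <- cutoff_set(coh, "g_GCLplus", rdb = "self")
  base <- flag_counts(flag_cohort(coh, cs))
  lower <- cs
  lower$fits[["0.01"]]$coefficients[["intercept"]] <-
    lower$fits[["0.01"]]$coefficients[["intercept"]] - 5
  shifted <- flag_counts(flag_cohort(coh, lower))
  expect_lte(shifted[["red"]], base[["red"]])
})

test_that("far-away cutoffs flag everything green", {
  coh <- small_cohort()
  cs <- cutoff_set(coh, "g_GCLplus", rdb = "self")
  for (k in c("0.05", "0.01")) {
    cs$fits[[k]]$coefficients[["intercept"]] <-
      cs$fits[[k]]$coefficients[["intercept"]] - 200
  }
  counts <- flag_counts(flag_cohort(coh, cs))
  expect_equal(unname(counts[["green"]]), nrow(coh))
})

test_that("gaussian cutoff sets are parallel offsets of one mean line", {
  coh <- small_cohort()
  cs <- cutoff_set(coh, "g_GCLplus", method = "gaussian", rdb = "self")
  sep_51 <- cs$fits[["0.05"]]$coefficients[["intercept"]] -
    cs$fits[["0.01"]]$coefficients[["intercept"]]
  gm <- fit_gaussian_model(coh, "g_GCLplus")
  expect_equal(sep_51, (qnorm(0.05) - qnorm(0.01)) * gm$sigma,
               tolerance = 1e-10)
  expect_equal(cs$fits[["0.05"]]$coefficients[["age"]],
               cs$fits[["0.01"]]$coefficients[["age"]])
})

test_that("disc-area adjustment is a display identity for flagging", {
  expect_equal(adjust_for_disc_area(100, 2.0, 2.0, 2.0), 100)
  expect_equal(adjust_for_disc_area(100, 2.5, 2.0, 2.0), 99)

  # flag from the full 3-covariate comparison equals flag from the
  # adjusted value against the age-only line at the reference disc area
  coh <- small_cohort()
  cs <- cutoff_set(coh, "g_cpRNFL", rdb = "self")
  disc_ref <- 2.0
  f5 <- cs$fits[["0.05"]]; f1 <- cs$fits[["0.01"]]
  test <- coh[1:50, ]
  full_c5 <- evaluate_cutoff(f5, test$age, test$disc_area)
  full_c1 <- evaluate_cutoff(f1, test$age, test$disc_area)
  full <- classify_eye(test$g_cpRNFL, full_c1, full_c5, "clamp")
  adj5 <- adjust_for_disc_area(test$g_cpRNFL, test$disc_area, disc_ref,
                               f5$coefficients[["disc_area"]])
  line5 <- evaluate_cutoff(f5, test$age, disc_ref)
  # per-level agreement, each adjusted with that fit's own disc slope
  expect_equal(adj5 < line5, test$g_cpRNFL < full_c5)
  adj1 <- adjust_for_disc_area(test$g_cpRNFL, test$disc_area, disc_ref,
                               f1$coefficients[["disc_area"]])
  line1 <- evaluate_cutoff(f1, test$age, disc_ref)
  expect_equal(adj1 < line1, test$g_cpRNFL < full_c1)
})
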