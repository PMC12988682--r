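random_flags <- function(n, seed, rdb) {
  set.seed(seed)
  structure(
    data.frame(
      eye_id = sprintf("eye_%03d", seq_len(n)),
      metric = "g_cpRNFL",
      rdb = rdb,
      value = runif(n, 60, 120),
      cutoff_5 = 90, cutoff_1 = 80,
      color = sample(c("green", "yellow", "red"), n, replace = TRUE,
                     prob = c(0.7, 0.2, 0.1)),
      stringsAsFactors = FALSE),
    class = c("eye_flags", "data.frame"))
}

test_that("identical flags give an all-diagonal transition table", {
  f <- random_flags(100, 1, "A")
  tt <- transition_table(f, f)
  expect_equal(sum(unclass(tt)) - sum(diag(unclass(tt))), 0)
  expect_equal(transition_summary(tt)$percent_changed, 0)
})

test_that("transition counts match an explicit pair-counting loop", {
  for (seed in 1:5) {
    fa <- random_flags(80, seed, "A")
    fb <- random_flags(80, seed + 100, "B")
    tt <- transition_table(fa, fb)
    m <- unclass(tt)
    attributes(m) <- attributes(m)[c("dim", "dimnames")]
    expect_equal(m, oracle_transitions(fa$color, fb$color))
    expect_equal(attr(tt, "n"), 80)
    # conservation: every eye sits in exactly one cell
    expect_equal(sum(unclass(tt)), 80)
  }
  fa <- random_flags(80, 1, "A")
  expect_error(transition_table(fa, random_flags(79, 2, "B")),
               "different eyes")
})

test_that("published ON-G transition arithmetic is reproduced", {
  # 183 glaucomatous eyes: 8 green-to-yellow, 22 yellow-to-red
  ttD <- transition_table_from_counts(n = 183, g_to_y = 8, y_to_r = 22)
  s <- transition_summary(ttD)
  expect_equal(s$total_changed, 30)
  expect_equal(s$percent_changed, 16.4)

  ttH <- transition_table_from_counts(n = 175, g_to_y = 1)
  d5 <- delta_confusion(ttH, ttD, 0.05)
  expect_equal(d5$dTP, 8)
  expect_equal(d5$delta_sensitivity_pct, 4.4)
  d1 <- delta_confusion(ttH, ttD, 0.01)
  expect_equal(d1$dTP, 22)
  expect_equal(d1$delta_sensitivity_pct, 12.0)
})

test_that("published healthy-eye specificity changes are reproduced", {
  # g-cpRNFL: one green-to-yellow among 175 healthy eyes
  ttH <- transition_table_from_counts(n = 175, g_to_y = 1)
  ttD <- transition_table_from_counts(n = 183)
  d5 <- delta_confusion(ttH, ttD, 0.05)
  expect_equal(d5$dFP, 1)
  expect_equal(d5$delta_specificity_pct, -0.6)
  expect_equal(delta_confusion(ttH, ttD, 0.01)$delta_specificity_pct, 0)

  # g-GCL+: one green-to-yellow and one red-to-yellow
  ttH2 <- transition_table_from_counts(n = 175, g_to_y = 1, r_to_y = 1)
  d5b <- delta_confusion(ttH2, ttD, 0.05)
  expect_equal(d5b$delta_specificity_pct, -0.6)
  d1b <- delta_confusion(ttH2, ttD, 0.01)
  expect_equal(d1b$dFP, -1)  # one fewer red healthy eye
  expect_equal(d1b$delta_specificity_pct, 0.6)
})

test_that("accuracy deltas are emitted under both conventions", {
  ttH_cp <- transition_table_from_counts(n = 175, g_to_y = 1)
  ttD_cp <- transition_table_from_counts(n = 183, g_to_y = 8, y_to_r = 22)
  # 1% level: +22 TPs, no healthy change -> +6.1% under both conventions
  d1 <- delta_confusion(ttH_cp, ttD_cp, 0.01)
  expect_equal(d1$delta_accuracy_pct, 6.1)
  expect_equal(d1$delta_accuracy_tp_only_pct, 6.1)
  # 5% level: +8 TPs, -1 TN -> +2.0% full convention
  d5 <- delta_confusion(ttH_cp, ttD_cp, 0.05)
  expect_equal(d5$delta_accuracy_pct, 2.0)

  ttH_gc <- transition_table_from_counts(n = 175, g_to_y = 1, r_to_y = 1)
  ttD_gc <- transition_table_from_counts(n = 183, g_to_y = 2, y_to_r = 10)
  # 5% level: +2 TPs, -1 TN -> +0.3%
  expect_equal(delta_confusion(ttH_gc, ttD_gc, 0.05)$delta_accuracy_pct, 0.3)
  # 1% level: +10 TPs; TP-only convention gives +2.8%, the full
  # convention (which also credits the healthy eye leaving red) +3.1%
  d1g <- delta_confusion(ttH_gc, ttD_gc, 0.01)
  expect_equal(d1g$delta_accuracy_tp_only_pct, 2.8)
  expect_equal(d1g$delta_accuracy_pct, 3.1)

  expect_error(delta_confusion(ttH_gc, ttD_gc, 0.10), "0.05 or 0.01")
})

test_that("deltas from transitions equal deltas from before/after confusion counts", {
  for (seed in 1:5) {
    fhA <- random_flags(60, seed, "A"); fhB <- random_flags(60, seed + 10, "B")
    fdA <- random_flags(90, seed + 20, "A"); fdB <- random_flags(90, seed + 30, "B")
    ttH <- transition_table(fhA, fhB)
    ttD <- transition_table(fdA, fdB)
    positive <- function(col, level) {
      if (level == 0.05) col %in% c("yellow", "red") else col == "red"
    }
    for (lv in c(0.05, 0.01)) {
      d <- delta_confusion(ttH, ttD, lv)
      expect_equal(d$dTP,
                   sum(positive(fdB$color, lv)) - sum(positive(fdA$color, lv)))
      expect_equal(d$dFP,
                   sum(positive(fhB$color, lv)) - sum(positive(fhA$color, lv)))
      # swapping the databases negates every signed delta
      drev <- delta_confusion(transition_table(fhB, fhA),
                              transition_table(fdB, fdA), lv)
      expect_equal(drev$dTP, -d$dTP)
      expect_equal(drev$delta_accuracy, -d$delta_accuracy)
    }
  }
})

test_that("flag discordance equals one minus the transition-table trace fraction", {
  fa <- random_flags(120, 3, "A")
  fb <- random_flags(120, 33, "B")
  truth <- data.frame(eye_id = fa$eye_id,
                      truth = rep(c("healthy", "disease"), each = 60),
                      stringsAsFactors = FALSE)
  acc <- accuracy_of_flagging(fa, fb, truth)
  tt <- transition_table(fa, fb)
  expect_equal(acc$fraction_discordant,
               1 - sum(diag(unclass(tt))) / attr(tt, "n"))
  expect_equal(acc$healthy$n, 60)
  expect_equal(acc$disease$n, 60)
  expect_equal(accuracy_of_flagging(fa, fa, truth)$percent_discordant, 0)
  expect_error(accuracy_of_flagging(fa, fb, truth[-1, ]), "missing truth")
})

test_that("screening projection turns a sensitivity gain into detected cases", {
  p <- screening_projection(1000, 0.03, 0.164)
  expect_equal(p$cases, 30)
  expect_equal(p$additional_detected, 5)
  expect_equal(p$percent_of_population, 0.5)
  expect_equal(p$percent_of_disease, 16.4)
  expect_equal(screening_projection(1000, 0.03, 0)$additional_detected, 0)
  expect_equal(screening_projection(2000, 0.03, 0.164)$additional_detected, 10)
  expect_error(screening_projection(1000, 1.5, 0.1), "prevalence")
})

test_that("percent formatting rounds halves away from zero to one decimal", {
  expect_equal(qrlnorm:::round_half_up(16.39, 1), 16.4)
  expect_equal(qrlnorm:::round_half_up(0.55, 1), 0.6)
  expect_equal(qrlnorm:::round_half_up(-0.55, 1), -0.6)
  expect_equal(qrlnorm:::round_half_up(12.02, 1), 12.0)
})
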