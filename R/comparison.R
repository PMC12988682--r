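COLORS <- c("green", "yellow", "red")

#' Flag-transition table between two reference databases
#'
#' Cross-tabulates, eye by eye, the color assigned under reference
#' database A against the color assigned under reference database B.
#' The full 3x3 matrix is kept: the four transitions commonly reported
#' (G to Y, Y to G, Y to R, R to Y) are projections of it, and the
#' two-step transitions G to R / R to G are counted as well since they
#' are possible when the two databases' cutoff lines are far apart.
#'
#' @param flagsA,flagsB `eye_flags` from [flag_cohort()] for the same
#'   eyes and metric under the two databases.
#' @param cohort Optional cohort label attached to the table.
#' @return Object of class `transition_table`: a 3x3 integer matrix
#'   (rows: color under A; columns: color under B) with attributes `n`
#'   and `cohort`.
#' @export
transition_table <- function(flagsA, flagsB, cohort = NULL) {
  if (!setequal(flagsA$eye_id, flagsB$eye_id) ||
      anyDuplicated(flagsA$eye_id) || anyDuplicated(flagsB$eye_id)) {
    extra <- c(setdiff(flagsA$eye_id, flagsB$eye_id),
               setdiff(flagsB$eye_id, flagsA$eye_id))
    stop("flag sets cover different eyes: ",
         paste(utils::head(unique(extra), 5), collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(c(flagsA$metric, flagsB$metric))) != 1) {
    stop("flag sets are for different metrics", call. = FALSE)
  }
  b <- flagsB[match(flagsA$eye_id, flagsB$eye_id), ]
  tab <- table(
    factor(flagsA$color, levels = COLORS),
    factor(b$color, levels = COLORS)
  )
  m <- matrix(as.integer(tab), 3, 3, dimnames = list(from = COLORS,
                                                     to = COLORS))
  structure(m, class = "transition_table", n = nrow(flagsA),
            cohort = cohort %||% flagsA$cohort[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a transition table directly from transition counts
#'
#' For working from published transition counts rather than raw flags
#' (the diagonal, which carries no information about change, absorbs
#' the remaining eyes).
#'
#' @param n Total eyes.
#' @param g_to_y,y_to_g,y_to_r,r_to_y,g_to_r,r_to_g Off-diagonal counts.
#' @param cohort Optional label.
#' @return A `transition_table`.
#' @examples
#' # published ON-G g-cpRNFL transitions: 8 G->Y, 22 Y->R among 183 eyes
#' tt <- transition_table_from_counts(n = 183, g_to_y = 8, y_to_r = 22)
#' transition_summary(tt)$total_changed  # 30
#' @export
transition_table_from_counts <- function(n, g_to_y = 0, y_to_g = 0,
                                         y_to_r = 0, r_to_y = 0,
                                         g_to_r = 0, r_to_g = 0,
                                         cohort = NULL) {
  m <- matrix(0L, 3, 3, dimnames = list(from = COLORS, to = COLORS))
  m["green", "yellow"] <- as.integer(g_to_y)
  m["yellow", "green"] <- as.integer(y_to_g)
  m["yellow", "red"] <- as.integer(y_to_r)
  m["red", "yellow"] <- as.integer(r_to_y)
  m["green", "red"] <- as.integer(g_to_r)
  m["red", "green"] <- as.integer(r_to_g)
  changed <- sum(m)
  if (changed > n) stop("transition counts exceed n", call. = FALSE)
  m["green", "green"] <- as.integer(n - changed)
  structure(m, class = "transition_table", n = as.integer(n),
            cohort = cohort)
}

#' Totals and percentages of a transition table
#'
#' @param x A `transition_table`.
#' @return List: `n`, `total_changed`, `percent_changed` (half-up, one
#'   decimal), `fraction_changed`, and the six off-diagonal counts.
#' @export
transition_summary <- function(x) {
  stopifnot(inherits(x, "transition_table"))
  n <- attr(x, "n")
  changed <- n - sum(diag(unclass(x)))
  list(
    n = n,
    total_changed = changed,
    fraction_changed = changed / n,
    percent_changed = round_half_up(100 * changed / n, 1),
    g_to_y = x["green", "yellow"], y_to_g = x["yellow", "green"],
    y_to_r = x["yellow", "red"], r_to_y = x["red", "yellow"],
    g_to_r = x["green", "red"], r_to_g = x["red", "green"]
  )
}

#' @export
print.transition_table <- function(x, ...) {
  cat("<transition_table>",
      if (!is.null(attr(x, "cohort"))) paste0(" (", attr(x, "cohort"), ")"),
      "  n = ", attr(x, "n"), "\n", sep = "")
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  print(m)
  s <- transition_summary(x)
  cat("changed: ", s$total_changed, " (", s$percent_changed, "%)\n",
      sep = "")
  invisible(x)
}

# Published-style rounding: one decimal, halves away from zero.
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Net flow of eyes into "positive" status at a flagging level.
net_into_positive <- function(tab, level) {
  m <- unclass(tab)
  if (abs(level - 0.05) < 1e-12) {
    # positive = yellow or red
    into <- m["green", "yellow"] + m["green", "red"]
    out <- m["yellow", "green"] + m["red", "green"]
  } else if (abs(level - 0.01) < 1e-12) {
    # positive = red
    into <- m["green", "red"] + m["yellow", "red"]
    out <- m["red", "green"] + m["red", "yellow"]
  } else {
    stop("level must be 0.05 or 0.01", call. = FALSE)
  }
  as.integer(into - out)
}

#' Sensitivity/specificity/accuracy change implied by flag transitions
#'
#' At the 5% level an eye is test-positive when flagged yellow or red;
#' at the 1% level when flagged red.  The net flow of disease eyes into
#' positive status is the change in true positives, and the net flow of
#' healthy eyes out of positive status is the change in true negatives,
#' so
#' `Dsensitivity = DTP / n_disease`, `Dspecificity = DTN / n_healthy`,
#' `Daccuracy = (DTP + DTN) / (n_disease + n_healthy)`
#' (all reported in percent).  Because published accuracy gains are
#' sometimes quoted from the true-positive change alone,
#' `delta_accuracy_tp_only = DTP / (n_disease + n_healthy)` is emitted
#' alongside the full convention rather than adjudicated.
#'
#' @param tableH Transition table of the healthy test cohort.
#' @param tableD Transition table of the disease test cohort.
#' @param level Flagging level: 0.05 or 0.01.
#' @return Object of class `confusion_delta`: signed count changes
#'   `dTP`, `dFN`, `dTN`, `dFP`; cohort sizes; `delta_sensitivity`,
#'   `delta_specificity`, `delta_accuracy`, `delta_accuracy_tp_only`
#'   (signed percents, full precision) and their half-up one-decimal
#'   `*_pct` displays.
#' @export
delta_confusion <- function(tableH, tableD, level) {
  stopifnot(inherits(tableH, "transition_table"),
            inherits(tableD, "transition_table"))
  dTP <- net_into_positive(tableD, level)
  dFP <- net_into_positive(tableH, level)
  dTN <- -dFP
  nD <- attr(tableD, "n")
  nH <- attr(tableH, "n")
  ds <- 100 * dTP / nD
  dp <- 100 * dTN / nH
  da <- 100 * (dTP + dTN) / (nD + nH)
  da_tp <- 100 * dTP / (nD + nH)
  structure(
    list(
      level = level,
      dTP = dTP, dFN = -dTP, dTN = dTN, dFP = dFP,
      n_disease = nD, n_healthy = nH,
      delta_sensitivity = ds,
      delta_specificity = dp,
      delta_accuracy = da,
      delta_accuracy_tp_only = da_tp,
      delta_sensitivity_pct = round_half_up(ds, 1),
      delta_specificity_pct = round_half_up(dp, 1),
      delta_accuracy_pct = round_half_up(da, 1),
      delta_accuracy_tp_only_pct = round_half_up(da_tp, 1)
    ),
    class = "confusion_delta"
  )
}

#' @export
print.confusion_delta <- function(x, ...) {
  cat("<confusion_delta> level ", format(100 * x$level), "%\n", sep = "")
  cat(sprintf("  dTP %+d (sensitivity %+.1f%%)   dFP %+d (specificity %+.1f%%)\n",
              x$dTP, x$delta_sensitivity_pct,
              x$dFP, x$delta_specificity_pct))
  cat(sprintf("  accuracy %+.1f%% (TP-only convention %+.1f%%)\n",
              x$delta_accuracy_pct, x$delta_accuracy_tp_only_pct))
  invisible(x)
}

#' Discordance of flagging between two reference databases
#'
#' The fraction of eyes whose color changes when the reference database
#' changes -- the "accuracy of flagging" lens: two databases can have
#' nearly identical overall test accuracy yet flag different
#' individual eyes.  Equals `1 - trace(T) / n` of the transition table.
#'
#' @param flagsA,flagsB `eye_flags` for the same eyes under the two
#'   databases.
#' @param truth_labels Data frame `eye_id`, `truth` with truth in
#'   `c("healthy", "disease")`, or a named character vector.
#' @return List: `percent_discordant` (overall, half-up 1 dp),
#'   `fraction_discordant`, and per-cohort `healthy` / `disease`
#'   sublists with `n`, `changed`, `percent`.
#' @export
accuracy_of_flagging <- function(flagsA, flagsB, truth_labels) {
  if (is.data.frame(truth_labels)) {
    truth <- stats::setNames(truth_labels$truth, truth_labels$eye_id)
  } else {
    truth <- truth_labels
  }
  miss <- setdiff(flagsA$eye_id, names(truth))
  if (length(miss) > 0) {
    stop("missing truth labels for: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  b <- flagsB[match(flagsA$eye_id, flagsB$eye_id), ]
  changed <- flagsA$color != b$color
  lab <- truth[flagsA$eye_id]
  per <- lapply(c(healthy = "healthy", disease = "disease"), function(g) {
    i <- lab == g
    list(n = sum(i), changed = sum(changed[i]),
         percent = if (any(i)) round_half_up(100 * mean(changed[i]), 1)
                   else NA_real_)
  })
  list(
    fraction_discordant = mean(changed),
    percent_discordant = round_half_up(100 * mean(changed), 1),
    healthy = per$healthy,
    disease = per$disease
  )
}

#' Screening-population projection of a sensitivity change
#'
#' Translates a sensitivity gain into detected cases in a hypothetical
#' screening population: with `pop_size` individuals at a given disease
#' prevalence, `cases = round(pop_size * prevalence)` and a sensitivity
#' change `delta_sensitivity` detects `round(cases * delta_sensitivity)`
#' additional patients.
#'
#' @param pop_size Screening population size.
#' @param prevalence Disease prevalence in `[0, 1]`.
#' @param delta_sensitivity Sensitivity change as a fraction (0.164 for
#'   a 16.4% gain).
#' @return List: `cases`, `additional_detected`,
#'   `percent_of_population`, `percent_of_disease`.
#' @examples
#' screening_projection(1000, 0.03, 0.164)  # ~5 additional cases
#' @export
screening_projection <- function(pop_size, prevalence, delta_sensitivity) {
  if (pop_size < 0 || prevalence < 0 || prevalence > 1) {
    stop("pop_size must be >= 0 and prevalence in [0, 1]", call. = FALSE)
  }
  cases <- round(pop_size * prevalence)
  additional <- round(cases * delta_sensitivity)
  list(
    cases = cases,
    additional_detected = additional,
    percent_of_population = round_half_up(100 * additional / pop_size, 1),
    percent_of_disease = round_half_up(100 * delta_sensitivity, 1)
  )
}
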