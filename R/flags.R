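#' Build the 50th/5th/1st percentile cutoff models for one metric
#'
#' A cutoff set bundles, for one metric and one reference database, the
#' three percentile lines that drive the green/yellow/red flags.  With
#' `method = "quantile"` each line is a separately fitted QRL; with
#' `method = "gaussian"` all three are parallel offsets of the
#' least-squares mean line (`z_tau * sigma`).
#'
#' Quantile crossing -- a lower-tau line lying above a higher-tau line
#' -- is not repaired: the fitted lines are returned as-is, and any
#' crossing inside the observed age range is recorded in the
#' `crossings` field and signalled as a warning, since it flags a model
#' pathology the user should see.
#'
#' @param records Reference cohort data frame.
#' @param metric Metric name.
#' @param method `"quantile"` or `"gaussian"`.
#' @param taus Quantile levels; must include 0.50, 0.05 and 0.01.
#' @param rdb Label of the source reference database.
#' @param disc_ref Reference disc area used only for the crossing scan.
#' @return Object of class `cutoff_set` with per-tau coefficient fits.
#' @export
cutoff_set <- function(records, metric,
                       method = c("quantile", "gaussian"),
                       taus = c(0.50, 0.05, 0.01),
                       rdb = "reference", disc_ref = 2.0) {
  method <- match.arg(method)
  spec <- metric_spec(metric)
  if (!all(c(0.50, 0.05, 0.01) %in% taus)) {
    stop("taus must include 0.50, 0.05 and 0.01", call. = FALSE)
  }
  fits <- if (method == "quantile") {
    lapply(taus, function(tt) fit_qrl(records, spec, tt))
  } else {
    gm <- fit_gaussian_model(records, spec)
    lapply(taus, function(tt) {
      cf <- gm$coefficients
      cf[["intercept"]] <- cf[["intercept"]] + stats::qnorm(tt) * gm$sigma
      structure(
        list(metric = metric, spec = spec, tau = tt, coefficients = cf,
             loss = NA_real_, n = gm$n, method = "gaussian",
             degenerate = FALSE),
        class = "qrl_fit"
      )
    })
  }
  names(fits) <- tau_key(taus)
  cs <- structure(
    list(metric = metric, spec = spec, method = method, taus = taus,
         fits = fits, rdb = rdb),
    class = "cutoff_set"
  )
  cs$crossings <- scan_crossings(cs, range(records$age), disc_ref)
  if (nrow(cs$crossings) > 0) {
    warning("quantile crossing inside the observed age range for ",
            metric, " (", rdb, "); see $crossings", call. = FALSE)
  }
  cs
}

# Detect tau-ordering violations of the cutoff lines over an age range.
scan_crossings <- function(cs, age_range, disc_ref = 2.0) {
  grid <- seq(age_range[1], age_range[2], length.out = 101)
  da <- if ("disc_area" %in% cs$spec$covariates) disc_ref else NULL
  taus <- sort(cs$taus)  # ascending: 0.01, 0.05, 0.50
  vals <- sapply(taus, function(tt) {
    evaluate_linear(cs$fits[[tau_key(tt)]]$coefficients, cs$spec, grid, da)
  })
  out <- data.frame(tau_low = numeric(0), tau_high = numeric(0),
                    age = numeric(0))
  for (k in seq_len(length(taus) - 1)) {
    bad <- vals[, k] > vals[, k + 1] + 1e-9
    if (any(bad)) {
      out <- rbind(out, data.frame(tau_low = taus[k], tau_high = taus[k + 1],
                                   age = grid[which(bad)[1]]))
    }
  }
  out
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("<cutoff_set> ", x$metric, "  method = ", x$method,
      "  rdb = ", x$rdb, "\n", sep = "")
  for (f in x$fits) {
    cat("  tau ", format(f$tau), ": ",
        paste(sprintf("%s = %.4f", names(f$coefficients), f$coefficients),
              collapse = ", "), "\n", sep = "")
  }
  if (nrow(x$crossings) > 0) cat("  ! quantile crossing detected\n")
  invisible(x)
}

#' Evaluate a fitted cutoff line at an eye's covariates
#'
#' @param fit A `qrl_fit` (from [fit_qrl()] or inside a [cutoff_set()]).
#' @param age Age(s), years.
#' @param disc_area Disc area(s), mm^2; required for cpRNFL metrics.
#' @return Cutoff thickness(es), um.
#' @examples
#' f <- structure(list(metric = "g_GCLplus", spec = metric_spec("g_GCLplus"),
#'                     coefficients = c(intercept = 80, age = -0.2), tau = 0.05),
#'                class = "qrl_fit")
#' evaluate_cutoff(f, age = 50)  # 70
#' @export
evaluate_cutoff <- function(fit, age, disc_area = NULL) {
  stopifnot(inherits(fit, "qrl_fit"))
  evaluate_linear(fit$coefficients, fit$spec, age, disc_area)
}

#' Assign the green/yellow/red flag
#'
#' An eye is red when its value lies strictly below the 1st percentile
#' cutoff, yellow when below the 5th but not the 1st, green otherwise.
#' "Below" is strict: a value exactly on a cutoff is not flagged (ties
#' have probability zero for continuous thicknesses).  Vectorized.
#'
#' By default, crossed cutoffs (`cutoff_1 > cutoff_5`) raise an error
#' carrying both values: a silent reorder would hide a model pathology
#' that small-sample first-percentile QRLs do exhibit.  Pipelines that
#' must proceed anyway can set `on_crossing = "clamp"`, which flags
#' against `min(cutoff_1, cutoff_5)` at the 1% level and reports which
#' eyes were affected (see [flag_cohort()]).
#'
#' @param value Measured thickness(es), um.
#' @param cutoff_1 First-percentile cutoff(s), um.
#' @param cutoff_5 Fifth-percentile cutoff(s), um.
#' @param on_crossing `"error"` (default) or `"clamp"`.
#' @return Character vector in `c("green", "yellow", "red")`.
#' @examples
#' classify_eye(c(65, 75, 85, 80), cutoff_1 = 70, cutoff_5 = 80)
#' @export
classify_eye <- function(value, cutoff_1, cutoff_5,
                         on_crossing = c("error", "clamp")) {
  on_crossing <- match.arg(on_crossing)
  k <- max(length(value), length(cutoff_1), length(cutoff_5))
  value <- rep_len(value, k)
  cutoff_1 <- rep_len(cutoff_1, k)
  cutoff_5 <- rep_len(cutoff_5, k)
  crossed <- cutoff_1 > cutoff_5
  if (any(crossed)) {
    if (on_crossing == "error") {
      i <- which(crossed)[1]
      stop(sprintf(paste0("quantile crossing: cutoff_1 (%.4f) exceeds ",
                          "cutoff_5 (%.4f)"), cutoff_1[i], cutoff_5[i]),
           call. = FALSE)
    }
    cutoff_1 <- pmin(cutoff_1, cutoff_5)
  }
  ifelse(value < cutoff_1, "red",
         ifelse(value < cutoff_5, "yellow", "green"))
}

#' Flag every eye of a cohort against a cutoff set
#'
#' @param records Test cohort data frame; must contain the cutoff set's
#'   metric and required covariates.
#' @param cutoffs A [cutoff_set()].
#' @param on_crossing Passed to [classify_eye()]; with `"clamp"`, eyes
#'   whose cutoffs crossed are listed in attribute `"crossed_eyes"` and
#'   a warning names how many were affected.
#' @return Object of class `eye_flags`: a data frame `eye_id`, `metric`,
#'   `rdb`, `value`, `cutoff_5`, `cutoff_1`, `color`, with the per-color
#'   counts in attribute `"counts"` (see [flag_counts()]).
#' @export
flag_cohort <- function(records, cutoffs,
                        on_crossing = c("error", "clamp")) {
  stopifnot(inherits(cutoffs, "cutoff_set"))
  metric <- cutoffs$metric
  if (!metric %in% names(records)) {
    stop("metric column '", metric, "' missing for eyes: ",
         paste(utils::head(records$eye_id, 5), collapse = ", "),
         call. = FALSE)
  }
  da <- if ("disc_area" %in% cutoffs$spec$covariates) records$disc_area
        else NULL
  c5 <- evaluate_cutoff(cutoffs$fits[["0.05"]], records$age, da)
  c1 <- evaluate_cutoff(cutoffs$fits[["0.01"]], records$age, da)
  color <- classify_eye(records[[metric]], c1, c5, on_crossing)
  crossed <- c1 > c5
  if (any(crossed)) {
    warning("cutoffs crossed at ", sum(crossed), " of ", nrow(records),
            " eyes for ", metric, " (", cutoffs$rdb,
            "); 1% cutoff clamped to the 5% cutoff there", call. = FALSE)
  }
  out <- data.frame(
    eye_id = records$eye_id,
    metric = metric,
    rdb = cutoffs$rdb,
    value = records[[metric]],
    cutoff_5 = c5,
    cutoff_1 = c1,
    color = color,
    stringsAsFactors = FALSE
  )
  counts <- table(factor(color, levels = c("green", "yellow", "red")))
  attr(out, "counts") <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "crossed_eyes") <- records$eye_id[crossed]
  class(out) <- c("eye_flags", "data.frame")
  out
}

#' Per-color counts of a flagged cohort
#'
#' @param flags An `eye_flags` object from [flag_cohort()].
#' @return Named integer vector (green, yellow, red); sums to the
#'   number of eyes.
#' @export
flag_counts <- function(flags) {
  counts <- attr(flags, "counts")
  if (is.null(counts)) {
    tab <- table(factor(flags$color, levels = c("green", "yellow", "red")))
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  counts
}

#' Adjust a thickness for disc area (display convention)
#'
#' Projects a cpRNFL thickness to a reference disc area so that
#' two-dimensional age-vs-thickness plots are consistent with fits that
#' also condition on disc area:
#' `value - disc_slope * (disc_area - disc_ref)`.  When the adjustment
#' uses a fit's own disc slope, flagging the adjusted value against the
#' age-only cutoff line (evaluated at `disc_ref`) is algebraically
#' identical to flagging the raw value against the full cutoff.
#'
#' @param value Thickness(es), um.
#' @param disc_area Eye's disc area, mm^2.
#' @param disc_ref Reference disc area, mm^2.
#' @param disc_slope Disc-area slope of the fit, um/mm^2.
#' @return Adjusted thickness(es), um.
#' @examples
#' adjust_for_disc_area(100, disc_area = 2.5, disc_ref = 2.0, disc_slope = 2.0)
#' @export
adjust_for_disc_area <- function(value, disc_area, disc_ref, disc_slope) {
  stopifnot(all(is.finite(value)), all(is.finite(disc_area)),
            is.finite(disc_ref), is.finite(disc_slope))
  value - disc_slope * (disc_area - disc_ref)
}
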