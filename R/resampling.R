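#' Monte Carlo subsampling configuration
#'
#' @param m Subsample size drawn in each iteration (the study draws 398,
#'   the size of the small commercial database).
#' @param iterations Number of subsamples (the study uses 1000).
#' @param taus Quantile levels to fit per subsample.
#' @param seed Integer seed; the index sequence is deterministic given
#'   the seed.
#' @param replacement Draw with replacement?  `FALSE` (the default, as
#'   in the study) makes each iteration a distinct-eye subsample.
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(m = 398, iterations = 1000,
                      taus = c(0.05, 0.01), seed = NULL,
                      replacement = FALSE) {
  if (m <= 1) stop("invalid mc config: m must exceed 1", call. = FALSE)
  if (iterations < 1) stop("invalid mc config: iterations must be >= 1",
                           call. = FALSE)
  structure(
    list(m = as.integer(m), iterations = as.integer(iterations),
         taus = taus, seed = seed, replacement = isTRUE(replacement)),
    class = "mc_config"
  )
}

#' Sampling distribution of QRL coefficients under subsampling
#'
#' Draws `iterations` subsamples of `m` eyes from a large reference
#' cohort (without replacement by default), refits the QRLs at each
#' configured tau, and returns the empirical distribution of every
#' coefficient together with its percentile confidence interval.  This
#' is the sampling-variability benchmark against which a small
#' reference database's coefficients are judged (see
#' [membership_check()]): if the small database's slopes and intercepts
#' sit inside these intervals, its deviations are explainable by sample
#' size alone.
#'
#' Subsamples with a singular design are re-drawn (up to 10 times per
#' iteration, then the run aborts); with continuous ages such failures
#' have probability zero and the re-draw count is reported.
#'
#' @param source_records Large reference cohort data frame.
#' @param spec A [metric_spec()] or metric name.
#' @param mc An [mc_config()].
#' @param level Confidence level of the percentile intervals.
#' @return Object of class `mc_distribution`: `estimates` (long data
#'   frame `tau`, `coefficient`, `iteration`, `estimate`), `ci` (data
#'   frame `tau`, `coefficient`, `mean`, `lower`, `upper`), `config`,
#'   `metric`, `n_source`, `redraws`.
#' @export
run_subsample_study <- function(source_records, spec, mc, level = 0.95) {
  stopifnot(inherits(mc, "mc_config"))
  if (is.character(spec)) spec <- metric_spec(spec)
  n <- nrow(source_records)
  if (mc$m > n) {
    stop("invalid mc config: m = ", mc$m, " exceeds source size ", n,
         call. = FALSE)
  }
  if (!is.null(mc$seed)) set.seed(mc$seed)
  X <- design_matrix(source_records, spec)
  y <- source_records[[spec$name]]
  p <- ncol(X)
  taus <- mc$taus
  est <- array(NA_real_, dim = c(mc$iterations, length(taus), p),
               dimnames = list(NULL, format(taus), colnames(X)))
  redraws <- 0L
  for (it in seq_len(mc$iterations)) {
    tries <- 0L
    repeat {
      idx <- sample.int(n, mc$m, replace = mc$replacement)
      fits <- tryCatch(
        lapply(taus, function(tt) {
          rq_solve(X[idx, , drop = FALSE], y[idx], tt)$coefficients
        }),
        error = function(e) NULL
      )
      if (!is.null(fits)) break
      tries <- tries + 1L
      redraws <- redraws + 1L
      if (tries >= 10L) {
        stop("subsample iteration ", it,
             " failed 10 times with a singular design", call. = FALSE)
      }
    }
    for (k in seq_along(taus)) est[it, k, ] <- fits[[k]]
  }
  long <- expand.grid(
    iteration = seq_len(mc$iterations),
    tau = taus,
    coefficient = colnames(X),
    KEEP.OUT.ATTRS = FALSE,
    stringsAsFactors = FALSE
  )
  long$estimate <- as.vector(est)
  ci <- do.call(rbind, lapply(seq_along(taus), function(k) {
    do.call(rbind, lapply(seq_len(p), function(jj) {
      x <- est[, k, jj]
      iv <- if (length(x) >= 2) percentile_interval(x, level)
            else { warning("single iteration: degenerate CI", call. = FALSE)
                   c(x, x) }
      data.frame(tau = taus[k], coefficient = colnames(X)[jj],
                 mean = mean(x), lower = iv[1], upper = iv[2],
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(
    list(metric = spec$name, spec = spec, estimates = long, ci = ci,
         config = mc, level = level, n_source = n, redraws = redraws),
    class = "mc_distribution"
  )
}

#' @export
print.mc_distribution <- function(x, ...) {
  cat("<mc_distribution> ", x$metric, ": ", x$config$iterations,
      " subsamples of m = ", x$config$m, " from n = ", x$n_source,
      if (x$config$replacement) " (with replacement)" else
        " (without replacement)", "\n", sep = "")
  print(x$ci, digits = 5)
  invisible(x)
}

#' Empirical percentile interval
#'
#' The central interval of a Monte Carlo or bootstrap distribution:
#' the empirical `alpha/2` and `1 - alpha/2` quantiles of the samples,
#' computed by linear interpolation of the order statistics
#' (`x_(h)` with `h = (n - 1) p + 1`, interpolating between adjacent
#' order statistics; R's default type-7 scheme).  Endpoints therefore
#' shift by O(1/n) between interpolation conventions.
#'
#' @param samples Numeric vector of at least 2 draws.
#' @param level Confidence level (default 0.95: the 2.5th and 97.5th
#'   percentiles).
#' @return Numeric `c(lower, upper)`.
#' @export
percentile_interval <- function(samples, level = 0.95) {
  if (length(samples) < 2) {
    stop("need at least 2 samples for a percentile interval",
         call. = FALSE)
  }
  a <- (1 - level) / 2
  unname(stats::quantile(samples, c(a, 1 - a), type = 7, names = FALSE))
}

#' Are a small database's coefficients inside the subsampling CIs?
#'
#' Checks, coefficient by coefficient, whether the QRL estimates from a
#' small reference database fall inside the percentile confidence
#' intervals of the subsampling distribution.  Intervals are treated as
#' closed: an estimate exactly on an endpoint counts as inside.
#'
#' @param fits A `qrl_fit`, a list of `qrl_fit`s (one per tau), or a
#'   `cutoff_set`, all for the distribution's metric.
#' @param dist An `mc_distribution` from [run_subsample_study()].
#' @return Object of class `membership_check`: data frame `tau`,
#'   `coefficient`, `estimate`, `lower`, `upper`, `inside`, with
#'   attribute `"counts"` = `c(inside, total)`.
#' @export
membership_check <- function(fits, dist) {
  stopifnot(inherits(dist, "mc_distribution"))
  if (inherits(fits, "cutoff_set")) fits <- fits$fits
  if (inherits(fits, "qrl_fit")) fits <- list(fits)
  rows <- list()
  for (fit in fits) {
    if (!isTRUE(any(abs(dist$config$taus - fit$tau) < 1e-12))) next
    if (fit$metric != dist$metric) {
      stop("metric mismatch: fit is for '", fit$metric,
           "', distribution for '", dist$metric, "'", call. = FALSE)
    }
    for (cf in names(fit$coefficients)) {
      ci <- dist$ci[abs(dist$ci$tau - fit$tau) < 1e-12 &
                      dist$ci$coefficient == cf, ]
      if (nrow(ci) != 1) {
        stop("no subsampling distribution for tau = ", fit$tau,
             ", coefficient '", cf, "'", call. = FALSE)
      }
      b <- unname(fit$coefficients[[cf]])
      rows[[length(rows) + 1]] <- data.frame(
        tau = fit$tau, coefficient = cf, estimate = b,
        lower = ci$lower, upper = ci$upper,
        inside = b >= ci$lower & b <= ci$upper,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    stop("no fitted taus match the distribution's taus", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "counts") <- c(inside = sum(out$inside), total = nrow(out))
  class(out) <- c("membership_check", "data.frame")
  out
}

#' @export
print.membership_check <- function(x, ...) {
  cnt <- attr(x, "counts")
  NextMethod()
  cat(cnt["inside"], "of", cnt["total"],
      "coefficients inside the subsampling CIs\n")
  invisible(x)
}
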