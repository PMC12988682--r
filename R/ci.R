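#' Confidence intervals for QRL coefficients
#'
#' Two methods are provided.
#'
#' `"rank_inversion"` inverts a regression rank-score test with the
#' sign-score function for the fitted tau: to test `H0: beta_j = b`,
#' the restricted model (the remaining covariates, with `b * x_j`
#' subtracted from the response) is refit by quantile regression, the
#' sign scores `a_i = tau - 1[r_i < 0]` of its residuals are formed,
#' and the statistic `T(b) = x~_j' a / sqrt(tau (1 - tau) x~_j' x~_j)`
#' -- where `x~_j` is the component of `x_j` orthogonal to the other
#' covariates -- is referred to N(0, 1).  The interval is the set of
#' `b` not rejected at the stated level, found by bisection from the
#' point estimate outward.  Being distribution-free in the errors, this
#' is the method of choice for reference databases of modest size; a
#' warning is issued above `large_n_threshold` observations, where the
#' bootstrap is preferred.  Rank intervals can be half-open: when the
#' bounded sign-score statistic cannot reach the critical value in one
#' direction (far-tail quantiles at small n), that endpoint is
#' reported as `Inf`/`-Inf` rather than a spuriously finite limit.
#'
#' `"bootstrap"` draws `B` case resamples (eyes resampled with
#' replacement), refits, and applies the percentile rule per
#' coefficient.  The replicate coefficient draws are retained so that
#' [cutoff_band()] can form pointwise bands on the cutoff line.
#'
#' @param records Cohort data frame.
#' @param spec A [metric_spec()] or metric name.
#' @param tau Quantile level in (0, 1).
#' @param level Confidence level (default 0.95).
#' @param method `"rank_inversion"` or `"bootstrap"`.
#' @param B Bootstrap replicates (>= 100).
#' @param seed Optional seed for the bootstrap resampling.
#' @param large_n_threshold Sample size above which rank inversion
#'   warns (default 1000).
#' @param coefficients Optional subset of coefficient names to invert
#'   (rank inversion is per-coefficient, so restricting it saves the
#'   other inversions); default all.
#' @return Object of class `qrl_ci`: `metric`, `tau`, `level`,
#'   `method`, `estimate` (named coefficients), `intervals` (data frame
#'   `coefficient`, `lower`, `upper`), and for the bootstrap a
#'   `replicates` matrix (`B` x p).
#' @export
coefficient_ci <- function(records, spec, tau, level = 0.95,
                           method = c("rank_inversion", "bootstrap"),
                           B = 400, seed = NULL,
                           large_n_threshold = 1000,
                           coefficients = NULL) {
  method <- match.arg(method)
  if (is.character(spec)) spec <- metric_spec(spec)
  check_tau(tau)
  X <- design_matrix(records, spec)
  y <- records[[spec$name]]
  fit <- rq_solve(X, y, tau)
  est <- fit$coefficients
  p <- ncol(X)
  keep <- if (is.null(coefficients)) seq_len(p)
          else match(coefficients, colnames(X))
  if (anyNA(keep)) stop("unknown coefficient name(s)", call. = FALSE)

  if (method == "rank_inversion") {
    if (nrow(X) > large_n_threshold) {
      warning("rank inversion with n = ", nrow(X), " > ",
              large_n_threshold,
              "; the method is designed for smaller samples", call. = FALSE)
    }
    iv <- matrix(NA_real_, p, 2)
    for (j in keep) {
      iv[j, ] <- rank_inversion_interval(X, y, tau, j, est, level)
    }
    replicates <- NULL
  } else {
    if (B < 100) stop("bootstrap requires B >= 100 replicates",
                      call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(X)
    replicates <- matrix(NA_real_, B, p,
                         dimnames = list(NULL, colnames(X)))
    for (bb in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        res <- tryCatch(rq_solve(X[idx, , drop = FALSE], y[idx], tau),
                        error = function(e) NULL)
        if (!is.null(res)) break
      }
      replicates[bb, ] <- res$coefficients
    }
    iv <- t(apply(replicates, 2, percentile_interval, level = level))
  }
  # the point estimate is always inside its own interval
  iv[, 1] <- pmin(iv[, 1], est, na.rm = FALSE)
  iv[, 2] <- pmax(iv[, 2], est, na.rm = FALSE)
  iv <- iv[keep, , drop = FALSE]
  structure(
    list(
      metric = spec$name,
      spec = spec,
      tau = tau,
      level = level,
      method = method,
      estimate = est,
      intervals = data.frame(
        coefficient = colnames(X)[keep],
        lower = iv[, 1],
        upper = iv[, 2],
        row.names = NULL,
        stringsAsFactors = FALSE
      ),
      replicates = replicates
    ),
    class = "qrl_ci"
  )
}

#' @export
print.qrl_ci <- function(x, ...) {
  cat("<qrl_ci> ", x$metric, "  tau = ", format(x$tau), "  ",
      format(100 * x$level), "% (", x$method, ")\n", sep = "")
  df <- x$intervals
  df$estimate <- x$estimate
  print(df[, c("coefficient", "lower", "estimate", "upper")], digits = 5)
  invisible(x)
}

# Residuals of the restricted quantile fit of (y - b * x_j) on the
# remaining columns.  Intercept-only restricted designs reduce to an
# order statistic, the hot path when inverting the age-slope test.
restricted_residuals <- function(Xr, yr, tau) {
  n <- length(yr)
  if (ncol(Xr) == 0) return(yr)
  one_col <- ncol(Xr) == 1
  if (one_col && diff(range(Xr[, 1])) == 0) {
    q <- sort(yr)[max(1L, ceiling(n * tau))] / Xr[1, 1]
    return(yr - Xr[, 1] * q)
  }
  rq_solve(Xr, yr, tau)$residuals
}

rank_inversion_interval <- function(X, y, tau, j, est, level) {
  n <- nrow(X)
  xj <- X[, j]
  Xr <- X[, -j, drop = FALSE]
  # component of x_j orthogonal to the other covariates
  xt <- if (ncol(Xr) > 0) qr.resid(qr(Xr), xj) else xj
  denom <- sqrt(tau * (1 - tau) * sum(xt^2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  # residuals at machine-noise level count as zero, not negative
  res_tol <- 1e-9 * (1 + mean(abs(y)))
  Tstat <- function(b) {
    r <- restricted_residuals(Xr, y - b * xj, tau)
    sum(xt * (tau - (r < -res_tol))) / denom
  }
  # crude scale for the bracket: asymptotic order sd(resid)/sqrt(n)
  fit_res <- y - drop(X %*% est)
  h0 <- max(2 * stats::sd(fit_res) / sqrt(n) /
              sqrt(mean(xt^2)), 1e-8 * (1 + abs(est[j])))
  b0 <- est[j]
  tol <- 1e-7 * (1 + abs(b0))
  find_edge <- function(direction) {
    # direction +1: upper endpoint where T drops below -z
    # direction -1: lower endpoint where T rises above +z
    target <- -direction * z
    h <- h0
    bnd <- b0 + direction * h
    f0 <- Tstat(b0) - target
    for (k in 1:80) {
      f1 <- Tstat(bnd) - target
      if (sign(f1) != sign(f0) || f1 == 0) {
        lo <- min(b0 + direction * h / 1.7, bnd, b0)
        hi <- max(b0 + direction * h / 1.7, bnd, b0)
        r <- stats::uniroot(function(b) Tstat(b) - target,
                            lower = min(b0, bnd), upper = max(b0, bnd),
                            tol = tol)
        return(r$root)
      }
      h <- h * 1.7
      bnd <- b0 + direction * h
    }
    direction * Inf  # test never rejects in this direction
  }
  lower <- find_edge(-1)
  upper <- find_edge(+1)
  c(lower, upper)
}

#' Pointwise confidence band for a percentile cutoff line
#'
#' Evaluates the cutoff line of `fit` over an age grid (cpRNFL metrics
#' at a fixed reference disc area) together with a pointwise band at
#' the level of `ci`.  When `ci` carries bootstrap replicates, the band
#' is the percentile interval of the replicate cutoff evaluations at
#' each age.  For rank-inversion intervals, which carry no joint
#' information, the band is the conservative interval hull of the
#' per-coefficient box: at covariate vector `x`,
#' `[sum_k min(L_k x_k, U_k x_k), sum_k max(L_k x_k, U_k x_k)]`.
#' The band always contains the point cutoff line.
#'
#' @param fit A `qrl_fit`.
#' @param ci The matching `qrl_ci` (same metric and tau).
#' @param age_grid Ages (years).
#' @param disc_ref Reference disc area (mm^2), for cpRNFL metrics.
#' @return Data frame `age`, `cutoff`, `lower`, `upper` (um).
#' @export
cutoff_band <- function(fit, ci, age_grid = seq(20, 80), disc_ref = 2.0) {
  stopifnot(inherits(fit, "qrl_fit"), inherits(ci, "qrl_ci"))
  if (fit$metric != ci$metric || !isTRUE(all.equal(fit$tau, ci$tau))) {
    stop("fit and ci disagree on metric or tau", call. = FALSE)
  }
  spec <- fit$spec
  Xg <- cbind(1, age_grid)
  if ("disc_area" %in% spec$covariates) Xg <- cbind(Xg, disc_ref)
  colnames(Xg) <- coef_names(spec)
  point <- drop(Xg %*% fit$coefficients)
  if (!is.null(ci$replicates)) {
    lines <- ci$replicates %*% t(Xg)  # B x length(grid)
    qs <- apply(lines, 2, percentile_interval, level = ci$level)
    lower <- qs[1, ]; upper <- qs[2, ]
  } else {
    L <- ci$intervals$lower
    U <- ci$intervals$upper
    lo_terms <- pmin(Xg %*% diag(L, length(L)), Xg %*% diag(U, length(U)))
    hi_terms <- pmax(Xg %*% diag(L, length(L)), Xg %*% diag(U, length(U)))
    lower <- rowSums(lo_terms)
    upper <- rowSums(hi_terms)
  }
  data.frame(
    age = age_grid,
    cutoff = point,
    lower = pmin(lower, point),
    upper = pmax(upper, point)
  )
}
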