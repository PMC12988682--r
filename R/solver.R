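#' Pinball (check) loss
#'
#' The asymmetric absolute loss minimized by quantile regression:
#' `rho_tau(u) = u * (tau - 1[u < 0])`, summed over residuals.  A
#' positive residual of 2 at `tau = 0.05` costs 0.10; a negative
#' residual of -2 costs 1.90.
#'
#' @param residuals Numeric vector of residuals (micrometres).
#' @param tau Quantile level, strictly between 0 and 1.
#' @return Total pinball loss (non-negative scalar; zero iff all
#'   residuals are zero).
#' @examples
#' pinball_loss(2, 0.05)   # 0.10
#' pinball_loss(-2, 0.05)  # 1.90
#' @export
pinball_loss <- function(residuals, tau) {
  check_tau(tau)
  sum(residuals * (tau - (residuals < 0)))
}

check_tau <- function(tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau <= 0 || tau >= 1) {
    stop("tau must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  invisible(tau)
}

#' Linear quantile regression on a design matrix
#'
#' Exact fit of the linear tau-th quantile by minimizing total pinball
#' loss.  The optimization is the standard linear-program formulation,
#' solved by a primal--dual interior-point method (Frisch--Newton with
#' Mehrotra predictor--corrector) on the bounded dual
#' `max y'a  s.t.  X'a = (1 - tau) X'1,  0 <= a <= 1`,
#' followed by a vertex-polish step: the optimum of this LP is attained
#' at a basic solution that interpolates `p = ncol(X)` observations, so
#' the observations with the smallest interior-point residuals are used
#' to reconstruct the exact vertex.  The returned coefficients therefore
#' attain the LP optimum to near machine precision, and `loss` is the
#' pinball loss evaluated at the returned coefficients.
#'
#' @param X Design matrix (including an intercept column if wanted).
#' @param y Response vector.
#' @param tau Quantile level in (0, 1).
#' @return A list with `coefficients`, `loss`, `residuals`,
#'   `iterations` (interior-point iterations), and `degenerate`
#'   (`TRUE` when the optimal vertex is not unique to within tolerance,
#'   i.e. several basic solutions achieve the same loss).
#' @seealso [fit_qrl()] for the data-frame interface.
#' @export
rq_solve <- function(X, y, tau) {
  check_tau(tau)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)
  if (anyNA(X) || anyNA(y)) stop("missing values in design or response",
                                 call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    stop("singular design: columns of X are linearly dependent ",
         "(e.g. a covariate is constant)", call. = FALSE)
  }

  ip <- rq_interior_point(X, y, tau, qrX)
  pol <- rq_vertex_polish(X, y, tau, ip$coefficients)

  if (!is.null(pol) && pol$loss <= ip$loss + 1e-12 * (1 + ip$loss)) {
    coef <- pol$coefficients
    loss <- pol$loss
    degenerate <- pol$degenerate
  } else {
    coef <- ip$coefficients
    loss <- ip$loss
    degenerate <- FALSE
  }
  names(coef) <- colnames(X)
  list(
    coefficients = coef,
    loss = loss,
    residuals = y - drop(X %*% coef),
    iterations = ip$iterations,
    degenerate = degenerate
  )
}

# Frisch-Newton interior point with Mehrotra predictor-corrector.
# Dual variables a in [0,1]^n with X'a fixed; b are the regression
# coefficients (multipliers of the equality constraints); z, w are the
# positive/negative parts of Xb - y, complementary to a and 1 - a.
rq_interior_point <- function(X, y, tau, qrX = qr(X),
                              maxit = 200L, beta = 0.99995) {
  n <- nrow(X)
  a <- rep(1 - tau, n)   # feasible: X'a = (1 - tau) X'1
  s <- 1 - a
  b <- qr.coef(qrX, y)
  r <- y - drop(X %*% b)
  eps <- max(1e-6, 1e-6 * stats::sd(y))
  z <- pmax(-r, 0) + eps
  w <- z + r             # maintains z - w = Xb - y, z, w > 0
  scale <- n * (1 + mean(abs(y)))
  it <- 0L
  step_bound <- function(v, dv) {
    i <- dv < 0
    if (!any(i)) 1 else min(1, beta * min(-v[i] / dv[i]))
  }
  for (it in seq_len(maxit)) {
    gap <- sum(z * a + w * s)
    if (gap < 1e-12 * scale) break
    q <- 1 / (z / a + w / s)
    r1 <- y - drop(X %*% b)
    M <- crossprod(X, q * X)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    solveM <- if (is.null(ch)) {
      function(rhs) solve(M, rhs)
    } else {
      function(rhs) backsolve(ch, forwardsolve(t(ch), rhs))
    }
    # affine predictor
    db <- solveM(crossprod(X, q * r1))
    da <- q * (r1 - drop(X %*% db))
    dz <- -z - (z / a) * da
    dw <- -w + (w / s) * da
    ap <- min(step_bound(a, da), step_bound(s, -da))
    ad <- min(step_bound(z, dz), step_bound(w, dw))
    gnew <- sum((z + ad * dz) * (a + ap * da) + (w + ad * dw) * (s - ap * da))
    mu <- (gnew / gap)^3 * gap / (2 * n)
    # corrector with second-order complementarity terms
    g1 <- (mu - a * z - da * dz) / a
    g2 <- (mu - s * w + da * dw) / s
    db <- solveM(crossprod(X, q * (g1 - g2)))
    da <- q * ((g1 - g2) - drop(X %*% db))
    dz <- g1 - (z / a) * da
    dw <- g2 + (w / s) * da
    ap <- min(step_bound(a, da), step_bound(s, -da))
    ad <- min(step_bound(z, dz), step_bound(w, dw))
    a <- a + ap * da; s <- s - ap * da
    z <- z + ad * dz; w <- w + ad * dw
    b <- b + ad * db
  }
  coef <- drop(b)
  list(coefficients = coef,
       loss = pinball_loss(y - drop(X %*% coef), tau),
       iterations = it)
}

# Reconstruct the exact optimal vertex from an interior-point solution.
# Candidate bases are p-subsets of the observations with the smallest
# absolute residuals; the best interpolating line among them is the
# exact LP optimum whenever the interior-point solution is close.
rq_vertex_polish <- function(X, y, tau, coef_ip, n_candidates = NULL) {
  n <- nrow(X); p <- ncol(X)
  r <- abs(y - drop(X %*% coef_ip))
  if (is.null(n_candidates)) n_candidates <- min(n, p + 4L)
  cand <- order(r)[seq_len(n_candidates)]
  combos <- utils::combn(cand, p)
  best <- NULL
  second <- Inf
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    Xb <- X[idx, , drop = FALSE]
    qb <- qr(Xb)
    if (qb$rank < p) next
    bk <- qr.coef(qb, y[idx])
    lk <- pinball_loss(y - drop(X %*% bk), tau)
    if (is.null(best) || lk < best$loss - 1e-12 * (1 + lk)) {
      if (!is.null(best)) second <- best$loss
      best <- list(coefficients = drop(bk), loss = lk)
    } else if (!is.null(best) && lk < second) {
      second <- lk
    }
  }
  if (is.null(best)) return(NULL)
  best$degenerate <- is.finite(second) &&
    (second - best$loss) <= 1e-9 * (1 + best$loss)
  best
}

#' Fit a quantile regression line (QRL) for one metric
#'
#' Fits the tau-th conditional quantile of a thickness metric as a
#' linear function of the metric family's covariates: age and disc area
#' for cpRNFL metrics, age alone for GCL+ metrics.  The 5th and 1st
#' percentile QRLs evaluated at an eye's covariates are the normative
#' cutoffs behind the yellow and red flags.
#'
#' @param records Cohort data frame (one row per eye) containing the
#'   metric column and the covariates required by `spec`.
#' @param spec A [metric_spec()], or a metric name.
#' @param tau Quantile level in (0, 1); typically 0.50, 0.05 or 0.01.
#' @return An object of class `qrl_fit`: list with `metric`, `tau`,
#'   `coefficients` (named: intercept, then slopes in micrometres per
#'   year and per mm^2), `loss` (achieved pinball loss), `n`,
#'   `method = "quantile"` and `degenerate`.
#' @examples
#' cohort <- generate_healthy_cohort(rdb_cohort_config("large_rdb", n = 400, seed = 1))
#' fit <- fit_qrl(cohort, "g_GCLplus", tau = 0.05)
#' fit$coefficients
#' @export
fit_qrl <- function(records, spec, tau) {
  if (is.character(spec)) spec <- metric_spec(spec)
  if (!(spec$name %in% names(records))) {
    stop("metric column '", spec$name, "' not found in records", call. = FALSE)
  }
  X <- design_matrix(records, spec)
  y <- records[[spec$name]]
  fit <- rq_solve(X, y, tau)
  structure(
    list(
      metric = spec$name,
      spec = spec,
      tau = tau,
      coefficients = fit$coefficients,
      loss = fit$loss,
      n = nrow(X),
      method = "quantile",
      degenerate = fit$degenerate
    ),
    class = "qrl_fit"
  )
}

#' @export
print.qrl_fit <- function(x, ...) {
  cat("<qrl_fit> ", x$metric, "  tau = ", format(x$tau),
      "  n = ", x$n, "\n", sep = "")
  print(round(x$coefficients, 4))
  cat("pinball loss:", format(x$loss, digits = 6),
      if (isTRUE(x$degenerate)) " (non-unique optimum)" else "", "\n")
  invisible(x)
}

#' Serialize fitted cutoff models to JSON
#'
#' @param fit A `qrl_fit`, `gaussian_model` or `cutoff_set` object.
#' @param path File to write; if `NULL`, the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_fit_json <- function(fit, path = NULL) {
  payload <- unclass(fit)
  payload$spec <- NULL
  payload$coefficients <- as.list(fit$coefficients)
  if (!is.null(fit$fits)) {
    payload$fits <- lapply(fit$fits, function(f) {
      list(tau = f$tau, coefficients = as.list(f$coefficients))
    })
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
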