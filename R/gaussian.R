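#' Fit the constant-variance Gaussian null model
#'
#' The null model against which the quantile regression lines are
#' compared: thickness is normally distributed about a linear mean with
#' a variance that does not change with age (or disc area).  The mean
#' line is the least-squares regression; the residual SD uses the
#' unbiased `n - p` denominator.  Under this model every percentile
#' cutoff line is parallel to the mean line, offset by `z_tau * sigma`.
#'
#' @param records Cohort data frame.
#' @param spec A [metric_spec()] or metric name.  The same covariate set
#'   as the quantile model for that metric is used, so that differences
#'   between the two fits isolate the distributional assumption.
#' @return Object of class `gaussian_model`: `metric`, `coefficients`
#'   (named), `sigma` (residual SD, um), `n`, `method = "gaussian"`.
#' @examples
#' coh <- generate_healthy_cohort(rdb_cohort_config("small_rdb", n = 200, seed = 3))
#' fit_gaussian_model(coh, "g_GCLplus")
#' @export
fit_gaussian_model <- function(records, spec) {
  if (is.character(spec)) spec <- metric_spec(spec)
  X <- design_matrix(records, spec)
  y <- records[[spec$name]]
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) stop("singular design", call. = FALSE)
  coef <- qr.coef(qrX, y)
  res <- y - drop(X %*% coef)
  structure(
    list(
      metric = spec$name,
      spec = spec,
      coefficients = stats::setNames(drop(coef), coef_names(spec)),
      sigma = sqrt(sum(res^2) / (n - p)),
      n = n,
      method = "gaussian"
    ),
    class = "gaussian_model"
  )
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat("<gaussian_model> ", x$metric, "  n = ", x$n, "\n", sep = "")
  print(round(x$coefficients, 4))
  cat("residual sd:", format(x$sigma, digits = 5), "um\n")
  invisible(x)
}

#' Percentile cutoff predicted by the Gaussian model
#'
#' `cutoff = mean(age, disc) + z_tau * sigma`, with `z_tau` the
#' standard-normal quantile.  At `tau = 0.5` this is the mean line;
#' cutoffs at two levels differ by `(z_a - z_b) * sigma` at every age
#' (parallel lines).
#'
#' @param model A `gaussian_model`.
#' @param tau Quantile level in (0, 1).
#' @param age Age(s) in years (vectorized).
#' @param disc_area Disc area(s) in mm^2; required iff the model's spec
#'   includes it.
#' @return Cutoff thickness(es) in um.
#' @export
gaussian_cutoff <- function(model, tau, age, disc_area = NULL) {
  stopifnot(inherits(model, "gaussian_model"))
  check_tau(tau)
  mean_line <- evaluate_linear(model$coefficients, model$spec, age, disc_area)
  mean_line + stats::qnorm(tau) * model$sigma
}

# Shared linear evaluation: intercept + slopes . covariates.
evaluate_linear <- function(coefficients, spec, age, disc_area = NULL) {
  v <- coefficients[["intercept"]] + coefficients[["age"]] * age
  if ("disc_area" %in% spec$covariates) {
    if (is.null(disc_area)) {
      stop("disc_area is required for metric '", spec$name, "'",
           call. = FALSE)
    }
    v <- v + coefficients[["disc_area"]] * disc_area
  }
  v
}

#' Divergence between QRLs and the Gaussian null prediction
#'
#' For each quantile fit, compares the fitted QRL to the Gaussian-model
#' cutoff at the same level over a grid of ages (cpRNFL metrics are
#' evaluated at a fixed reference disc area so the comparison is a
#' function of age alone).
#'
#' @param qr_fits A single `qrl_fit` or a list of them (e.g. taus 0.05
#'   and 0.01), all for the model's metric.
#' @param model The `gaussian_model` for the same metric.
#' @param age_grid Ages (years) at which to measure the vertical gap.
#' @param disc_ref Reference disc area (mm^2) for cpRNFL metrics.
#' @return Data frame with one row per fit: `tau`, `max_abs_gap` (um,
#'   over the grid), and one `slope_gap_*` column per covariate
#'   (QRL slope minus Gaussian mean-line slope).
#' @export
qrl_gaussian_divergence <- function(qr_fits, model, age_grid = seq(20, 80),
                                    disc_ref = 2.0) {
  stopifnot(inherits(model, "gaussian_model"))
  if (inherits(qr_fits, "qrl_fit")) qr_fits <- list(qr_fits)
  rows <- lapply(qr_fits, function(fit) {
    if (fit$metric != model$metric) {
      stop("metric mismatch: QRL is for '", fit$metric,
           "', Gaussian model for '", model$metric, "'", call. = FALSE)
    }
    spec <- model$spec
    da <- if ("disc_area" %in% spec$covariates) disc_ref else NULL
    qline <- evaluate_linear(fit$coefficients, spec, age_grid, da)
    gline <- gaussian_cutoff(model, fit$tau, age_grid, da)
    slopes <- fit$coefficients[spec$covariates] -
      model$coefficients[spec$covariates]
    row <- data.frame(tau = fit$tau, max_abs_gap = max(abs(qline - gline)))
    for (cv in spec$covariates) row[[paste0("slope_gap_", cv)]] <- slopes[[cv]]
    row
  })
  do.call(rbind, rows)
}
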