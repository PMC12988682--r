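#' Registry of supported thickness metrics
#'
#' The package models 24 OCT summary metrics: 17 circumpapillary RNFL
#' (cpRNFL) metrics -- the global average, the four quadrants and the
#' twelve clock hours -- and 7 ganglion cell layer plus inner plexiform
#' layer (GCL+) metrics -- the global average and six macular sectors.
#' cpRNFL metrics are modelled with age and disc area as covariates;
#' GCL+ metrics with age only, mirroring how commercial normative
#' software conditions each family.
#'
#' The `target_mean` / `target_sd` columns are the population marginals
#' (in micrometres) the synthetic-cohort generator is calibrated to.
#' For the two global metrics these are the published real-world
#' reference-database values; the regional metrics use typical values
#' for a healthy adult population on a swept-source instrument.
#'
#' @return A data frame with one row per metric and columns `metric`,
#'   `family` (`"cpRNFL"` or `"GCLplus"`), `target_mean`, `target_sd`.
#' @examples
#' nrow(metric_registry())  # 24
#' table(metric_registry()$family)
#' @export
metric_registry <- function() {
  cp <- data.frame(
    metric = c(
      "g_cpRNFL",
      paste0("cpRNFL_quadrant_", c("T", "S", "N", "I")),
      paste0("cpRNFL_clock_", 1:12)
    ),
    family = "cpRNFL",
    target_mean = c(
      103.3,
      76, 127, 84, 131,
      110, 95, 65, 75, 100, 125, 140, 115, 70, 85, 125, 135
    ),
    target_sd = c(
      10.9,
      15, 17, 14, 18,
      20, 18, 13, 15, 20, 22, 24, 22, 13, 16, 22, 24
    ),
    stringsAsFactors = FALSE
  )
  gc <- data.frame(
    metric = c("g_GCLplus", paste0("GCLplus_sector_", 1:6)),
    family = "GCLplus",
    target_mean = c(71.1, 72, 70, 69, 70, 71, 73),
    target_sd = c(5.8, 6.4, 6.2, 6.3, 6.5, 6.2, 6.6),
    stringsAsFactors = FALSE
  )
  rbind(cp, gc)
}

#' Covariate specification for one metric
#'
#' cpRNFL-family metrics are fit on age and disc area; GCL+-family
#' metrics on age alone.
#'
#' @param metric Name of a registered metric (see [metric_registry()]).
#' @return An object of class `metric_spec`: a list with `name`,
#'   `family`, and the ordered covariate vector `covariates`.
#' @examples
#' metric_spec("g_cpRNFL")$covariates   # age, disc_area
#' metric_spec("g_GCLplus")$covariates  # age
#' @export
metric_spec <- function(metric) {
  reg <- metric_registry()
  i <- match(metric, reg$metric)
  if (is.na(i)) {
    stop("unknown metric '", metric, "'; see metric_registry()", call. = FALSE)
  }
  fam <- reg$family[i]
  structure(
    list(
      name = metric,
      family = fam,
      covariates = if (fam == "cpRNFL") c("age", "disc_area") else "age"
    ),
    class = "metric_spec"
  )
}

#' @export
print.metric_spec <- function(x, ...) {
  cat("<metric_spec> ", x$name, " (", x$family, "): thickness ~ ",
      paste(x$covariates, collapse = " + "), "\n", sep = "")
  invisible(x)
}

# Canonical list key for a quantile level ("0.5", "0.05", "0.01").
tau_key <- function(tau) sprintf("%g", tau)

# Coefficient names for a spec's design: intercept then covariates.
coef_names <- function(spec) c("intercept", spec$covariates)

# Build the design matrix for a cohort data frame under a spec.
design_matrix <- function(records, spec) {
  miss <- setdiff(spec$covariates, names(records))
  if (length(miss) > 0) {
    stop("records lack required covariate(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(rep(1, nrow(records)), as.matrix(records[spec$covariates]))
  colnames(X) <- coef_names(spec)
  X
}
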