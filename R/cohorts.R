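# Truncated-normal helpers ---------------------------------------------------

# Exact moments of N(mean, sd^2) truncated to [lower, upper].
truncnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(list(mean = mean, var = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  m <- mean + sd * (pa - pb) / Z
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  v <- sd^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  list(mean = m, var = max(v, 0))
}

# Rejection sampler for the truncated normal.  The truncation ranges used
# here are wide (acceptance rates > 90%), so plain rejection is exact and
# cheap.  Deterministic given the RNG state.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean < lower || mean > upper) {
      stop("degenerate truncated normal: mean outside [lower, upper]",
           call. = FALSE)
    }
    return(rep(mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# Find (mean, sd) of a normal truncated below at `lower` whose truncated
# moments match a target mean and sd.  Used once, to calibrate the
# disease-severity distribution; deterministic closed-form objective.
solve_truncnorm_params <- function(target_mean, target_sd, lower = 0) {
  obj <- function(par) {
    m <- truncnorm_moments(par[1], exp(par[2]), lower = lower)
    (m$mean - target_mean)^2 + (sqrt(m$var) - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  list(mean = fit$par[1], sd = exp(fit$par[2]))
}

# Configuration ---------------------------------------------------------------

#' Per-metric linear mean models, calibrated to the registry marginals
#'
#' Each metric's population model is
#' `thickness = beta0 + beta_age * age + beta_disc * disc_area + eps`,
#' `eps ~ N(0, sigma(age)^2)`, with `beta_disc = 0` for GCL+ metrics.
#' Published normative studies report marginal means and SDs but not age
#' slopes, so the slopes are configurable defaults (-0.2 um/year for
#' cpRNFL metrics, -0.1 for GCL+, +2.0 um/mm^2 disc-area slope for
#' cpRNFL) and the intercept `beta0` and residual SD `sigma0` are
#' calibrated in closed form so that, under the anchor population's age
#' and disc-area distributions, the marginal mean and SD of each metric
#' equal the registry targets.  The anchor defaults to the large
#' real-world reference population (age 48.6 +/- 17.0 years, truncated
#' to 18--90).
#'
#' @param age_mean,age_sd,age_min,age_max Anchor age distribution (years).
#' @param disc_mean,disc_sd,disc_min Anchor disc-area distribution (mm^2),
#'   normal truncated below.
#' @param beta_age Named age slopes (um/year) per family.
#' @param beta_disc Named disc-area slopes (um/mm^2) per family.
#' @return Data frame: `metric`, `family`, `beta0`, `beta_age`,
#'   `beta_disc`, `sigma0`.
#' @export
default_metric_models <- function(age_mean = 48.6, age_sd = 17.0,
                                  age_min = 18, age_max = 90,
                                  disc_mean = 2.0, disc_sd = 0.4,
                                  disc_min = 0.8,
                                  beta_age = c(cpRNFL = -0.2, GCLplus = -0.1),
                                  beta_disc = c(cpRNFL = 2.0, GCLplus = 0)) {
  reg <- metric_registry()
  am <- truncnorm_moments(age_mean, age_sd, age_min, age_max)
  dm <- truncnorm_moments(disc_mean, disc_sd, disc_min, Inf)
  ba <- unname(beta_age[reg$family])
  bd <- unname(beta_disc[reg$family])
  var0 <- reg$target_sd^2 - ba^2 * am$var - bd^2 * dm$var
  sigma0 <- sqrt(pmax(var0, (0.3 * reg$target_sd)^2))
  data.frame(
    metric = reg$metric,
    family = reg$family,
    beta0 = reg$target_mean - ba * am$mean - bd * dm$mean,
    beta_age = ba,
    beta_disc = bd,
    sigma0 = sigma0,
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic healthy cohort
#'
#' @param n Number of eyes (one eye per individual).
#' @param age_mean,age_sd Age distribution (years) before truncation.
#' @param age_min,age_max Age truncation bounds (years).
#' @param disc_mean,disc_sd,disc_min Disc-area distribution (mm^2),
#'   normal truncated below at `disc_min`.
#' @param models Per-metric coefficient table as returned by
#'   [default_metric_models()]; may be restricted to a subset of metrics.
#' @param hetero_slope Fractional change of the residual SD per year of
#'   age away from 50: `sigma(age) = sigma0 * (1 + hetero_slope *
#'   (age - 50))`.  0 (the default) gives the homoscedastic population
#'   the Gaussian null model assumes.
#' @param label Cohort label stored with each record.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n, age_mean, age_sd, age_min, age_max,
                          disc_mean = 2.0, disc_sd = 0.4, disc_min = 0.8,
                          models = default_metric_models(),
                          hetero_slope = 0, label = "reference",
                          seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != round(n)) {
    stop("invalid cohort config: n must be a non-negative integer",
         call. = FALSE)
  }
  if (age_min >= age_max) {
    stop("invalid cohort config: age_min must be below age_max",
         call. = FALSE)
  }
  if (age_sd < 0 || disc_sd < 0) {
    stop("invalid cohort config: standard deviations must be non-negative",
         call. = FALSE)
  }
  if (any(models$sigma0 < 0)) {
    stop("invalid cohort config: sigma0 must be non-negative", call. = FALSE)
  }
  unknown <- setdiff(models$metric, metric_registry()$metric)
  if (length(unknown) > 0) {
    stop("invalid cohort config: unregistered metric(s) ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sd_ends <- 1 + hetero_slope * (c(age_min, age_max) - 50)
  if (any(sd_ends <= 0)) {
    stop("invalid cohort config: sigma(age) = sigma0 * (1 + hetero_slope *",
         " (age - 50)) must stay positive over [age_min, age_max]",
         call. = FALSE)
  }
  structure(
    list(n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
         age_min = age_min, age_max = age_max,
         disc_mean = disc_mean, disc_sd = disc_sd, disc_min = disc_min,
         models = models, hetero_slope = hetero_slope,
         label = label, seed = seed),
    class = "cohort_config"
  )
}

#' Configuration for glaucomatous thickness deficits
#'
#' Disease eyes are generated as healthy eyes on the disease age range,
#' then a per-eye severity is drawn from `N(loss_mean, loss_sd^2)`
#' truncated at 0 and subtracted from every metric, scaled per metric
#' family (`1` for cpRNFL metrics, `gcl_scale` for the thinner GCL+
#' metrics), and the result is clipped below at `loss_floor`.  A single
#' severity per eye makes damage correlated across metrics, emulating
#' diffuse-to-advanced structural loss; it does not model spatially
#' localized arcuate geometry.
#'
#' @param loss_mean,loss_sd Severity distribution (um of cpRNFL-scale
#'   thickness deficit) before truncation at 0.
#' @param loss_floor Minimum post-disease thickness (um); applied only
#'   where a positive deficit was subtracted.
#' @param gcl_scale Multiplier applied to the severity for GCL+ metrics.
#' @param age_min,age_max Optional override of the healthy config's age
#'   truncation bounds (years).
#' @param seed Optional integer seed for the severity draws; when `NULL`
#'   the severity draws continue the healthy generator's RNG stream.
#' @return An object of class `disease_config`.
#' @export
disease_config <- function(loss_mean, loss_sd, loss_floor = 20,
                           gcl_scale = 0.45,
                           age_min = NULL, age_max = NULL, seed = NULL) {
  if (loss_mean < 0) stop("invalid disease config: loss_mean must be >= 0",
                          call. = FALSE)
  if (loss_sd < 0) stop("invalid disease config: loss_sd must be >= 0",
                        call. = FALSE)
  if (loss_floor <= 0) stop("invalid disease config: loss_floor must be > 0",
                            call. = FALSE)
  structure(
    list(loss_mean = loss_mean, loss_sd = loss_sd, loss_floor = loss_floor,
         gcl_scale = gcl_scale, age_min = age_min, age_max = age_max,
         seed = seed),
    class = "disease_config"
  )
}

#' Preset cohort configurations for the four study cohorts
#'
#' Presets reproduce the printed design of the flagging study: a small
#' commercial-style reference database (398 eyes, age 46.2 +/- 16.3,
#' range 18--88), a large real-world reference database (4830 eyes, age
#' 48.6 +/- 17.0, range 18--90), a healthy test set (175 eyes, mean age
#' 49.3, range 22--86) and a glaucomatous (ON-G) test set (183 eyes, age
#' 68.5 +/- 7.5, range 60--92).  All four draw from one shared
#' population model ([default_metric_models()]), so differences between
#' cohorts are sampling differences -- the study's null hypothesis.
#'
#' @param type One of `"small_rdb"`, `"large_rdb"`, `"healthy_test"`,
#'   `"disease"`.
#' @param n Override the preset size (e.g. for quick experiments).
#' @param seed Integer seed.
#' @param hetero_slope Passed through to [cohort_config()].
#' @return A `cohort_config`.
#' @export
rdb_cohort_config <- function(type = c("small_rdb", "large_rdb",
                                       "healthy_test", "disease"),
                              n = NULL, seed = NULL, hetero_slope = 0) {
  type <- match.arg(type)
  p <- switch(type,
    small_rdb    = list(n = 398,  am = 46.2, asd = 16.3, lo = 18, hi = 88,
                        label = "reference_small"),
    large_rdb    = list(n = 4830, am = 48.6, asd = 17.0, lo = 18, hi = 90,
                        label = "reference_large"),
    healthy_test = list(n = 175,  am = 49.3, asd = 15.5, lo = 22, hi = 86,
                        label = "healthy_test"),
    disease      = list(n = 183,  am = 68.5, asd = 7.5,  lo = 60, hi = 92,
                        label = "disease_test")
  )
  if (is.null(n)) n <- p$n
  cohort_config(n = n, age_mean = p$am, age_sd = p$asd,
                age_min = p$lo, age_max = p$hi,
                hetero_slope = hetero_slope, label = p$label, seed = seed)
}

#' Calibrated disease severity for the glaucomatous test set
#'
#' Solves, in closed form plus a deterministic two-parameter
#' optimization, for the severity distribution under which the
#' generated ON-G-style cohort (ages 60--92) reproduces the printed
#' marginals of the glaucomatous test set: g-cpRNFL 81.0 +/- 16.5 um
#' and g-GCL+ mean 61.3 um.
#'
#' @param seed Optional seed stored in the config.
#' @return A `disease_config`.
#' @export
rdb_disease_config <- function(seed = NULL) {
  models <- default_metric_models()
  dis <- rdb_cohort_config("disease")
  am <- truncnorm_moments(dis$age_mean, dis$age_sd, dis$age_min, dis$age_max)
  dm <- truncnorm_moments(dis$disc_mean, dis$disc_sd, dis$disc_min, Inf)
  hm <- function(metric) {
    m <- models[models$metric == metric, ]
    mean_h <- m$beta0 + m$beta_age * am$mean + m$beta_disc * dm$mean
    var_h <- m$beta_age^2 * am$var + m$beta_disc^2 * dm$var + m$sigma0^2
    c(mean = mean_h, var = var_h)
  }
  cp <- hm("g_cpRNFL")
  gc <- hm("g_GCLplus")
  target_loss_mean <- cp["mean"] - 81.0
  target_loss_var <- 16.5^2 - cp["var"]
  par <- solve_truncnorm_params(unname(target_loss_mean),
                                sqrt(max(unname(target_loss_var), 1)),
                                lower = 0)
  gcl_scale <- unname((gc["mean"] - 61.3) / target_loss_mean)
  disease_config(loss_mean = par$mean, loss_sd = par$sd,
                 gcl_scale = gcl_scale, seed = seed)
}

# Generation ------------------------------------------------------------------

#' Generate a synthetic healthy cohort
#'
#' Ages and disc areas are drawn from truncated normals (exact rejection
#' sampling); each metric is `beta0 + beta_age * age + beta_disc *
#' disc_area + eps` with `eps ~ N(0, sigma(age)^2)` and `sigma(age) =
#' sigma0 * (1 + hetero_slope * (age - 50))`.  Generation is
#' deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Data frame with columns `eye_id`, `age`, `disc_area`,
#'   `cohort`, then one column per metric (um).  The config's seed and
#'   label are attached as attributes `seed` and `label`.
#' @examples
#' coh <- generate_healthy_cohort(rdb_cohort_config("small_rdb", n = 50, seed = 7))
#' summarize_cohort(coh, "g_cpRNFL")
#' @export
generate_healthy_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  models <- config$models
  age <- rtrunc_norm(n, config$age_mean, config$age_sd,
                     config$age_min, config$age_max)
  disc <- rtrunc_norm(n, config$disc_mean, config$disc_sd,
                      config$disc_min, Inf)
  out <- data.frame(
    eye_id = sprintf("%s_%05d", config$label, seq_len(n)),
    age = age,
    disc_area = disc,
    cohort = rep(config$label, n),
    stringsAsFactors = FALSE
  )
  sd_scale <- 1 + config$hetero_slope * (age - 50)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    eps <- if (m$sigma0 > 0) stats::rnorm(n, 0, 1) * (m$sigma0 * sd_scale)
           else numeric(n)
    val <- m$beta0 + m$beta_age * age + m$beta_disc * disc + eps
    out[[m$metric]] <- pmax(val, 0.1)  # thickness must stay positive
  }
  attr(out, "seed") <- config$seed
  attr(out, "label") <- config$label
  out
}

#' Generate a synthetic glaucomatous test cohort
#'
#' Healthy values are generated on the disease age range, then a
#' truncated-normal severity is subtracted from each metric (see
#' [disease_config()]).  With `loss_mean = loss_sd = 0` the output
#' equals healthy generation under the same seed.
#'
#' @param config A [cohort_config()]; its age bounds are overridden by
#'   the disease config's when those are set.
#' @param disease A [disease_config()].
#' @return Cohort data frame with cohort label `disease_test`.
#' @export
generate_disease_cohort <- function(config, disease) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(disease, "disease_config"))
  if (!is.null(disease$age_min)) config$age_min <- disease$age_min
  if (!is.null(disease$age_max)) config$age_max <- disease$age_max
  config$label <- "disease_test"
  out <- generate_healthy_cohort(config)
  n <- config$n
  if (disease$loss_sd == 0) {
    severity <- rep(disease$loss_mean, n)  # no RNG consumed
  } else {
    if (!is.null(disease$seed)) set.seed(disease$seed)
    severity <- rtrunc_norm(n, disease$loss_mean, disease$loss_sd, 0, Inf)
  }
  if (any(severity > 0)) {
    fam <- config$models$family
    scale <- ifelse(fam == "GCLplus", disease$gcl_scale, 1)
    for (i in seq_len(nrow(config$models))) {
      metric <- config$models$metric[i]
      deficit <- severity * scale[i]
      h <- out[[metric]]
      out[[metric]] <- ifelse(deficit > 0,
                              pmax(h - deficit, disease$loss_floor), h)
    }
  }
  out
}

#' Sample moments of one metric in a cohort
#'
#' @param records Cohort data frame.
#' @param metric Metric column name.
#' @return List with `n`, `mean`, `sd` (sample SD, `n - 1` denominator;
#'   `NA` when `n = 1`), `min`, `max`.
#' @export
summarize_cohort <- function(records, metric) {
  if (!metric %in% names(records)) {
    stop("metric column '", metric, "' not found", call. = FALSE)
  }
  x <- records[[metric]]
  if (length(x) == 0) stop("empty cohort: no records to summarize",
                           call. = FALSE)
  list(
    n = length(x),
    mean = mean(x),
    sd = if (length(x) > 1) stats::sd(x) else NA_real_,
    min = min(x),
    max = max(x)
  )
}
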