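#' Configuration of a full reference-database comparison study
#'
#' Describes the end-to-end workflow: generate (or accept) a small and
#' a large reference database plus healthy and disease test cohorts;
#' fit the 50th/5th/1st percentile QRLs on both databases; fit the
#' Gaussian null model; flag both test cohorts under both databases;
#' tabulate flag transitions and sensitivity/specificity/accuracy
#' changes; and run the Monte Carlo subsampling study with a membership
#' check of the small database's coefficients.
#'
#' All randomness flows from the single `seed`: per-stage seeds are
#' derived as `(seed * 7919 + stage_index) mod (2^31 - 1)`, so a
#' manifest containing `seed` suffices to re-run identically.
#'
#' @param seed Master seed (integer).
#' @param metrics Metrics to analyze (default: the two global metrics).
#' @param taus Percentile levels for the cutoff sets.
#' @param ci_method,ci_level Confidence-interval method/level for QRL
#'   coefficients.
#' @param mc_m,mc_iterations,mc_taus Monte Carlo subsampling settings.
#' @param n_small,n_large,n_healthy,n_disease Cohort sizes (defaults:
#'   the study design 398 / 4830 / 175 / 183).
#' @param hetero_slope Heteroscedasticity of the generating population
#'   (0 = the homoscedastic null).
#' @param run_mc Run the subsampling stage? (It dominates runtime.)
#' @param cohorts Optional named list
#'   (`reference_small`, `reference_large`, `healthy_test`,
#'   `disease_test`) of user-supplied cohort data frames; any supplied
#'   entry replaces the generated one.
#' @param out_dir Optional directory; when set, every stage's output is
#'   serialized there (CSV/JSON).
#' @return Object of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         metrics = c("g_cpRNFL", "g_GCLplus"),
                         taus = c(0.50, 0.05, 0.01),
                         ci_method = "rank_inversion", ci_level = 0.95,
                         mc_m = 398, mc_iterations = 1000,
                         mc_taus = c(0.05, 0.01),
                         n_small = 398, n_large = 4830,
                         n_healthy = 175, n_disease = 183,
                         hetero_slope = 0, run_mc = TRUE,
                         cohorts = NULL, out_dir = NULL) {
  bad <- setdiff(metrics, metric_registry()$metric)
  if (length(bad) > 0) {
    stop("unregistered metric(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), metrics = metrics, taus = taus,
         ci_method = ci_method, ci_level = ci_level,
         mc_m = mc_m, mc_iterations = mc_iterations, mc_taus = mc_taus,
         n_small = n_small, n_large = n_large,
         n_healthy = n_healthy, n_disease = n_disease,
         hetero_slope = hetero_slope, run_mc = isTRUE(run_mc),
         cohorts = cohorts, out_dir = out_dir),
    class = "study_config"
  )
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("study stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full reference-database comparison study
#'
#' Executes every stage of [study_config()] and returns a structured
#' report.  Deterministic given the config seed; a re-run with the same
#' config yields an identical report.
#'
#' @param config A [study_config()].
#' @return Object of class `rdb_study` with elements `cohorts`,
#'   `cutoffs` (per metric, per database), `gaussian` (divergence
#'   tables), `flags`, `transitions`, `deltas`, `discordance`,
#'   `screening`, `mc` (subsampling distributions + membership), and
#'   `manifest`.
#' @examples
#' \donttest{
#' cfg <- study_config(seed = 42, n_large = 1200, mc_iterations = 50)
#' study <- run_full_study(cfg)
#' study$discordance$g_cpRNFL$percent_discordant
#' }
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed

  cohorts <- run_stage("generate", {
    gen <- list(
      reference_small = generate_healthy_cohort(rdb_cohort_config(
        "small_rdb", n = config$n_small, seed = derive_seed(seed, 1),
        hetero_slope = config$hetero_slope)),
      reference_large = generate_healthy_cohort(rdb_cohort_config(
        "large_rdb", n = config$n_large, seed = derive_seed(seed, 2),
        hetero_slope = config$hetero_slope)),
      healthy_test = generate_healthy_cohort(rdb_cohort_config(
        "healthy_test", n = config$n_healthy, seed = derive_seed(seed, 3),
        hetero_slope = config$hetero_slope)),
      disease_test = generate_disease_cohort(
        rdb_cohort_config("disease", n = config$n_disease,
                          seed = derive_seed(seed, 4),
                          hetero_slope = config$hetero_slope),
        rdb_disease_config())
    )
    for (nm in names(config$cohorts)) gen[[nm]] <- config$cohorts[[nm]]
    gen
  })

  cutoffs <- run_stage("fit_qrl", {
    lapply(stats::setNames(config$metrics, config$metrics), function(m) {
      list(
        small = cutoff_set(cohorts$reference_small, m, "quantile",
                           taus = config$taus, rdb = "small"),
        large = cutoff_set(cohorts$reference_large, m, "quantile",
                           taus = config$taus, rdb = "large")
      )
    })
  })

  gaussian <- run_stage("gaussian_null", {
    lapply(stats::setNames(config$metrics, config$metrics), function(m) {
      lapply(cutoffs[[m]], function(cs) {
        src <- if (cs$rdb == "small") cohorts$reference_small
               else cohorts$reference_large
        gm <- fit_gaussian_model(src, m)
        tail_fits <- Filter(function(f) f$tau < 0.5, cs$fits)
        list(model = gm,
             divergence = qrl_gaussian_divergence(tail_fits, gm))
      })
    })
  })

  flags <- run_stage("flag", {
    lapply(stats::setNames(config$metrics, config$metrics), function(m) {
      list(
        healthy = list(
          small = flag_cohort(cohorts$healthy_test, cutoffs[[m]]$small,
                              on_crossing = "clamp"),
          large = flag_cohort(cohorts$healthy_test, cutoffs[[m]]$large,
                              on_crossing = "clamp")
        ),
        disease = list(
          small = flag_cohort(cohorts$disease_test, cutoffs[[m]]$small,
                              on_crossing = "clamp"),
          large = flag_cohort(cohorts$disease_test, cutoffs[[m]]$large,
                              on_crossing = "clamp")
        )
      )
    })
  })

  truth <- rbind(
    data.frame(eye_id = cohorts$healthy_test$eye_id, truth = "healthy",
               stringsAsFactors = FALSE),
    data.frame(eye_id = cohorts$disease_test$eye_id, truth = "disease",
               stringsAsFactors = FALSE)
  )

  transitions <- run_stage("transitions", {
    lapply(stats::setNames(config$metrics, config$metrics), function(m) {
      list(
        healthy = transition_table(flags[[m]]$healthy$small,
                                   flags[[m]]$healthy$large,
                                   cohort = "healthy_test"),
        disease = transition_table(flags[[m]]$disease$small,
                                   flags[[m]]$disease$large,
                                   cohort = "disease_test")
      )
    })
  })

  deltas <- run_stage("deltas", {
    lapply(stats::setNames(config$metrics, config$metrics), function(m) {
      list(
        level_5 = delta_confusion(transitions[[m]]$healthy,
                                  transitions[[m]]$disease, 0.05),
        level_1 = delta_confusion(transitions[[m]]$healthy,
                                  transitions[[m]]$disease, 0.01)
      )
    })
  })

  discordance <- run_stage("discordance", {
    lapply(stats::setNames(config$metrics, config$metrics), function(m) {
      fa <- rbind(as.data.frame(flags[[m]]$healthy$small),
                  as.data.frame(flags[[m]]$disease$small))
      fb <- rbind(as.data.frame(flags[[m]]$healthy$large),
                  as.data.frame(flags[[m]]$disease$large))
      accuracy_of_flagging(fa, fb, truth)
    })
  })

  screening <- run_stage("screening", {
    lapply(stats::setNames(config$metrics, config$metrics), function(m) {
      screening_projection(
        1000, 0.03,
        transition_summary(transitions[[m]]$disease)$fraction_changed)
    })
  })

  mc <- if (config$run_mc) run_stage("monte_carlo", {
    lapply(stats::setNames(config$metrics, config$metrics), function(m) {
      k <- match(m, config$metrics)
      dist <- run_subsample_study(
        cohorts$reference_large, m,
        mc_config(m = config$mc_m, iterations = config$mc_iterations,
                  taus = config$mc_taus, seed = derive_seed(seed, 10 + k)),
        level = config$ci_level)
      list(distribution = dist,
           membership = membership_check(cutoffs[[m]]$small, dist))
    })
  }) else NULL

  study <- structure(
    list(
      cohorts = cohorts, cutoffs = cutoffs, gaussian = gaussian,
      flags = flags, transitions = transitions, deltas = deltas,
      discordance = discordance, screening = screening, mc = mc,
      manifest = list(
        package = "qrlnorm",
        version = as.character(utils::packageVersion("qrlnorm")),
        seed = seed,
        stage_seeds = c(reference_small = derive_seed(seed, 1),
                        reference_large = derive_seed(seed, 2),
                        healthy_test = derive_seed(seed, 3),
                        disease_test = derive_seed(seed, 4)),
        sizes = c(small = config$n_small, large = config$n_large,
                  healthy = config$n_healthy, disease = config$n_disease),
        metrics = config$metrics
      )
    ),
    class = "rdb_study"
  )
  if (!is.null(config$out_dir)) serialize_study(study, config$out_dir)
  study
}

#' @export
print.rdb_study <- function(x, ...) {
  m <- x$manifest
  cat("<rdb_study> seed ", m$seed, ": RDBs n = ", m$sizes[["small"]],
      " vs ", m$sizes[["large"]], "; test eyes ",
      m$sizes[["healthy"]], " healthy + ", m$sizes[["disease"]],
      " disease\n", sep = "")
  for (metric in m$metrics) {
    d <- x$discordance[[metric]]
    cat(sprintf("  %-12s flag discordance: disease %.1f%%, healthy %.1f%%\n",
                metric, d$disease$percent, d$healthy$percent))
    if (!is.null(x$mc)) {
      cnt <- attr(x$mc[[metric]]$membership, "counts")
      cat(sprintf("  %-12s small-RDB coefficients inside MC CIs: %d/%d\n",
                  "", cnt[["inside"]], cnt[["total"]]))
    }
  }
  invisible(x)
}

serialize_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$cohorts)) {
    write_cohort_csv(study$cohorts[[nm]],
                     file.path(out_dir, paste0("cohort_", nm, ".csv")))
  }
  for (m in names(study$cutoffs)) {
    for (side in names(study$cutoffs[[m]])) {
      write_fit_json(study$cutoffs[[m]][[side]],
                     file.path(out_dir,
                               sprintf("cutoffs_%s_%s.json", m, side)))
    }
    for (grp in names(study$flags[[m]])) {
      for (side in names(study$flags[[m]][[grp]])) {
        utils::write.csv(as.data.frame(study$flags[[m]][[grp]][[side]]),
                         file.path(out_dir,
                                   sprintf("flags_%s_%s_%s.csv", m, grp, side)),
                         row.names = FALSE)
      }
    }
    if (!is.null(study$mc)) {
      utils::write.csv(study$mc[[m]]$distribution$estimates,
                       file.path(out_dir, sprintf("mc_%s.csv", m)),
                       row.names = FALSE)
    }
  }
  report <- list(
    manifest = study$manifest,
    transitions = lapply(study$transitions, function(tt)
      lapply(tt, transition_summary)),
    deltas = lapply(study$deltas, function(d) lapply(d, unclass)),
    discordance = study$discordance,
    screening = study$screening
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

# Cohort CSV I/O --------------------------------------------------------------

#' Read a cohort from CSV
#'
#' Expects the schema `eye_id,age,disc_area,cohort,<metric...>`.
#' Unknown metric columns are dropped with a warning; non-numeric
#' values in numeric columns are reported with their line number
#' (line 1 is the header).
#'
#' @param path CSV file path.
#' @return Cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("eye_id", "age", "disc_area", "cohort")
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("cohort CSV lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  metric_cols <- setdiff(names(raw), required)
  unknown <- setdiff(metric_cols, metric_registry()$metric)
  if (length(unknown) > 0) {
    warning("ignoring unknown metric column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    metric_cols <- setdiff(metric_cols, unknown)
  }
  numeric_cols <- c("age", "disc_area", metric_cols)
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !(raw[[cl]] %in% c("NA", "")))
    if (length(bad) > 0) {
      stop("non-numeric value in column '", cl, "' at line ",
           bad[1] + 1L, ": '", raw[[cl]][bad[1]], "'", call. = FALSE)
    }
    raw[[cl]] <- v
  }
  raw[, c(required, metric_cols), drop = FALSE]
}

#' Write a cohort to CSV
#'
#' Numeric columns are written with 6 significant digits, so a
#' read-back round trip reproduces the records to that precision.
#'
#' @param records Cohort data frame.
#' @param path Output path.
#' @export
write_cohort_csv <- function(records, path) {
  out <- as.data.frame(records)
  for (cl in names(out)) {
    if (is.numeric(out[[cl]])) out[[cl]] <- signif(out[[cl]], 6)
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
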