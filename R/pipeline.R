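#' Configure an end-to-end pipeline run
#'
#' Bundles every stage choice: the synthetic-generator config (or a CSV
#' path with the same column dictionary), unit map, imputation settings,
#' exposure metrics, model blocks, and the sensitivity toggles
#' (no-imputation complete-case run, landmark exclusion window, alternative
#' exposure columns).
#'
#' @param n_participants Cohort size when generating synthetically.
#' @param seed Master seed; every stage seed is derived from it.
#' @param input Either `"synthetic"` (default) or a CSV path.
#' @param generator Overrides for [cohort_config()] (list).
#' @param metrics Exposures to analyze: any of `"kdm"`, `"phenoage"`, or
#'   `"custom:<column>"` for a generic alternative exposure (e.g. telomere
#'   length).
#' @param blocks Model blocks to run, a subset of `"logistic"`, `"cox"`,
#'   `"dose_response"`, `"multistate"`, `"life_expectancy"`.
#' @param impute Run the three-strategy multiple imputation for covariates
#'   (`FALSE` = complete-case sensitivity run).
#' @param m Number of imputations (default 20).
#' @param landmark_years Exclude participants with events within this many
#'   years of baseline (0 = off; 5 in the sensitivity design).
#' @param le_ages Conditioning ages for the life-expectancy table.
#' @param ci_draws Parametric-simulation draws for LE/YLL CIs.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_participants = 20000, seed = 1,
                            input = "synthetic", generator = list(),
                            metrics = c("kdm", "phenoage"),
                            blocks = c("logistic", "cox", "dose_response",
                                       "multistate", "life_expectancy"),
                            impute = TRUE, m = 20, landmark_years = 0,
                            le_ages = 45:99, ci_draws = 200,
                            out_dir = NULL) {
  known <- c("logistic", "cox", "dose_response", "multistate",
             "life_expectancy")
  blocks <- match.arg(blocks, known, several.ok = TRUE)
  if (length(blocks) == 0) {
    abort("at least one model block must be enabled",
          class = "agepath_config_error")
  }
  std <- metrics %in% c("kdm", "phenoage")
  if (!all(std | startsWith(metrics, "custom:"))) {
    abort("metrics must be 'kdm', 'phenoage' or 'custom:<column>'")
  }
  if (!identical(input, "synthetic") && !file.exists(input)) {
    abort(sprintf("input file not found: %s", input),
          class = "agepath_config_error")
  }
  cfg <- list(n_participants = n_participants, seed = as.integer(seed),
              input = input, generator = generator, metrics = metrics,
              blocks = blocks, impute = impute, m = m,
              landmark_years = landmark_years, le_ages = le_ages,
              ci_draws = ci_draws, out_dir = out_dir)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

default_imputation_strategies <- function(table) {
  strat <- c(income = "ordered_logistic", education = "ordered_logistic",
             bmi_category = "ordered_logistic", smoking = "ordered_logistic",
             alcohol = "ordered_logistic", ethnicity = "ordered_logistic",
             townsend = "multivariate_normal_bounded",
             physical_activity = "mean_substitution",
             diet_score = "mean_substitution",
             no2 = "mean_substitution", nox = "mean_substitution",
             pm25 = "mean_substitution", pm10 = "mean_substitution")
  strat[names(strat) %in% names(table)]
}

metric_columns <- function(metric, data) {
  if (metric == "kdm") {
    list(label = "kdm", sd_col = "kdm_ba_accel_sd",
         quart_col = "kdm_ba_quartile", accel_col = "kdm_ba_accel")
  } else if (metric == "phenoage") {
    list(label = "phenoage", sd_col = "phenoage_accel_sd",
         quart_col = "phenoage_quartile", accel_col = "phenoage_accel")
  } else {
    col <- sub("^custom:", "", metric)
    if (!col %in% names(data)) {
      abort(sprintf("custom exposure column '%s' not found", col))
    }
    list(label = col, sd_col = paste0(col, "_sd"),
         quart_col = paste0(col, "_quartile"), accel_col = col)
  }
}

first_k_onset <- function(cohort, k) {
  on <- cbind(cohort$physical_onset_age, cohort$psychological_onset_age,
              cohort$cognitive_onset_age)
  apply(on, 1, function(x) {
    x <- sort(x[!is.na(x)])
    if (length(x) >= k) x[k] else NA_real_
  })
}

incident_outcomes <- function(cohort) {
  end_age <- pmin(cohort$death_age, cohort$censor_age, na.rm = TRUE)
  first_on <- first_k_onset(cohort, 1)
  second_on <- first_k_onset(cohort, 2)
  mk <- function(onset) {
    event <- !is.na(onset) & onset > cohort$chronological_age &
      onset <= end_age
    time <- ifelse(event, onset, end_age) - cohort$chronological_age
    list(event = as.integer(event), time = time)
  }
  single <- mk(first_on)
  multi <- mk(second_on)
  death <- list(event = as.integer(!is.na(cohort$death_age) &
                                     cohort$death_age <= cohort$censor_age),
                time = end_age - cohort$chronological_age)
  cohort$single_event <- single$event
  cohort$single_time <- single$time
  cohort$multi_event <- multi$event
  cohort$multi_time <- multi$time
  cohort$death_event <- death$event
  cohort$death_time <- death$time
  cohort
}

# run one model block element, converting a statistical failure (e.g.
# separation in a sparse stratum) into a recorded skip instead of aborting
# the whole run
try_block <- function(label, expr) {
  tryCatch(expr, error = function(e) {
    warn(sprintf("skipping %s: %s", label, conditionMessage(e)))
    NULL
  })
}

pooled_or_single <- function(datasets, fitter, ...) {
  if (length(datasets) == 1) {
    f <- fitter(datasets[[1]], ...)
    tt <- f$tidy
    est_col <- intersect(c("or", "hr"), names(tt))
    tibble::tibble(term = tt$term, point = tt$estimate,
                   within_var = tt$se^2, between_var = 0,
                   total_var = tt$se^2, df = Inf,
                   ci_low = tt$ci_low, ci_high = tt$ci_high,
                   ratio = tt[[est_col]],
                   ratio_low = exp(tt$ci_low), ratio_high = exp(tt$ci_high))
  } else {
    fit_pooled(datasets, fitter, ...)
  }
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, harmonizes units, scores both
#' biological ages, applies the missing-score and 5-SD exclusions, imputes
#' covariates, classifies multimorbidity states, and runs the enabled model
#' blocks: cross-sectional logistic ORs, longitudinal Cox HRs in the
#' baseline disorder-free subset (incident single disorder, incident
#' dual/triple comorbidity, mortality; mortality also within each baseline
#' state), spline dose-response curves, the interval-censored multistate
#' model, and the life-expectancy / years-of-life-lost table.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `cohort` (scored analysis set),
#'   `exclusions` accounting table, per-block results, and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  seed <- config$seed

  # --- input ------------------------------------------------------------
  if (identical(config$input, "synthetic")) {
    gen <- do.call(cohort_config,
                   c(list(n_participants = config$n_participants,
                          seed = seed), config$generator))
    cohort <- generate_cohort(gen)
  } else {
    cohort <- tibble::as_tibble(utils::read.csv(config$input))
  }
  n_input <- nrow(cohort)

  # --- harmonize + score ------------------------------------------------
  marker_cols <- intersect(union(kdm_biomarkers(), phenoage_biomarkers()),
                           names(cohort))
  cohort <- harmonize_units(cohort, identity_unit_map(marker_cols),
                            columns = marker_cols)
  kdm_params <- fit_kdm(cohort)
  scored <- compute_kdm(cohort, kdm_params)
  scored <- compute_phenoage(scored)
  miss_score <- is.na(scored$kdm_ba) | is.na(scored$phenoage)
  scored <- scored[!miss_score, ]
  extreme <- flag_extreme(scored$kdm_ba) | flag_extreme(scored$phenoage)
  scored <- scored[!extreme, ]
  for (metric in c("kdm_ba", "phenoage")) {
    scored <- compute_acceleration(scored, metric)
    scored[[paste0(metric, "_quartile")]] <-
      assign_quartiles(scored[[paste0(metric, "_accel")]])
  }
  for (mt in config$metrics[startsWith(config$metrics, "custom:")]) {
    col <- sub("^custom:", "", mt)
    scored[[paste0(col, "_sd")]] <- as.numeric(scale(scored[[col]]))
    scored[[paste0(col, "_quartile")]] <- assign_quartiles(scored[[col]])
  }
  scored$baseline_state <- baseline_state(scored)
  scored <- incident_outcomes(scored)
  scored$sex_female <- as.numeric(scored$sex == "female")

  exclusions <- tibble::tibble(
    step = c("input", "missing_score", "extreme_score", "analysis_set"),
    excluded = c(0L, sum(miss_score), sum(extreme), 0L),
    retained = c(n_input, n_input - sum(miss_score), nrow(scored),
                 nrow(scored)))

  # --- imputation -------------------------------------------------------
  strategies <- default_imputation_strategies(scored)
  has_missing <- vapply(names(strategies),
                        function(nm) anyNA(scored[[nm]]), logical(1))
  if (config$impute && any(has_missing)) {
    spec <- imputation_spec(
      m = config$m, strategies = strategies[has_missing],
      bounds = list(townsend = c(-10, 15)),
      predictors = c("chronological_age", "sex"),
      seed = seed + 1L)
    datasets <- impute_cohort(scored, spec)
  } else if (!config$impute) {
    cc <- complete.cases(scored[, intersect(default_covariates(),
                                            names(scored))])
    datasets <- list(scored[cc, ])
    exclusions <- dplyr::bind_rows(
      exclusions,
      tibble::tibble(step = "complete_case", excluded = sum(!cc),
                     retained = sum(cc)))
  } else {
    datasets <- list(scored)
  }

  # --- timelines / panel ------------------------------------------------
  timelines <- build_timelines(scored)
  if (config$landmark_years > 0) {
    timelines <- landmark_exclude(timelines, config$landmark_years)
    keep <- unique(timelines$id)
    datasets <- lapply(datasets, function(d) d[d$id %in% keep, ])
    scored_lm <- scored[scored$id %in% keep, ]
    exclusions <- dplyr::bind_rows(
      exclusions,
      tibble::tibble(step = "landmark", excluded = attr(timelines, "n_excluded"),
                     retained = length(keep)))
    scored <- scored_lm
  }
  panel <- make_panel(timelines)
  exclusions <- dplyr::bind_rows(
    exclusions,
    tibble::tibble(step = "none_to_death",
                   excluded = attr(panel, "exclusions")$n,
                   retained = length(unique(panel$id))))

  results <- list()
  covs <- intersect(default_covariates(), names(scored))

  # --- cross-sectional logistic ----------------------------------------
  if ("logistic" %in% config$blocks) {
    rows <- list()
    for (mt in config$metrics) {
      mc <- metric_columns(mt, scored)
      for (onm in c("single", "dual", "triple")) {
        out_state <- match(onm, .state_levels)
        subsets <- lapply(datasets, function(d) {
          d <- d[d$baseline_state %in% c(1L, out_state), ]
          d$.case <- as.integer(d$baseline_state == out_state)
          d
        })
        for (coding in c("per_sd", "quartile")) {
          expo <- if (coding == "per_sd") mc$sd_col else mc$quart_col
          pooled <- try_block(
            paste("logistic", mc$label, onm, coding),
            pooled_or_single(subsets, fit_logistic,
                             outcome = ".case", exposure = expo,
                             covariates = covs,
                             quartiles = coding == "quartile"))
          if (is.null(pooled)) next
          rows[[length(rows) + 1]] <-
            dplyr::mutate(pooled, metric = mc$label, outcome = onm,
                          coding = coding, .before = 1)
        }
      }
    }
    results$logistic <- dplyr::bind_rows(rows)
  }

  # --- longitudinal Cox -------------------------------------------------
  free_sets <- lapply(datasets, function(d) d[d$baseline_state == 1L, ])
  if ("cox" %in% config$blocks) {
    rows <- list()
    for (mt in config$metrics) {
      mc <- metric_columns(mt, scored)
      specs <- list(
        incident_single = c("single_time", "single_event"),
        incident_multimorbidity = c("multi_time", "multi_event"),
        mortality = c("death_time", "death_event"))
      for (onm in names(specs)) {
        sp <- specs[[onm]]
        for (coding in c("per_sd", "quartile")) {
          expo <- if (coding == "per_sd") mc$sd_col else mc$quart_col
          pooled <- try_block(
            paste("cox", mc$label, onm, coding),
            pooled_or_single(free_sets, fit_cox,
                             time = sp[1], event = sp[2],
                             exposure = expo, covariates = covs,
                             quartiles = coding == "quartile"))
          if (is.null(pooled)) next
          rows[[length(rows) + 1]] <-
            dplyr::mutate(pooled, metric = mc$label, outcome = onm,
                          coding = coding, baseline_group = "none",
                          .before = 1)
        }
      }
      # overall mortality across the whole cohort (the headline mortality
      # contrast), both codings
      for (coding in c("per_sd", "quartile")) {
        expo <- if (coding == "per_sd") mc$sd_col else mc$quart_col
        pooled <- try_block(
          paste("cox overall mortality", mc$label, coding),
          pooled_or_single(datasets, fit_cox,
                           time = "death_time", event = "death_event",
                           exposure = expo, covariates = covs,
                           quartiles = coding == "quartile"))
        if (is.null(pooled)) next
        rows[[length(rows) + 1]] <-
          dplyr::mutate(pooled, metric = mc$label, outcome = "mortality",
                        coding = coding, baseline_group = "all",
                        .before = 1)
      }
      # mortality within each baseline state (quartile coding)
      for (st in 2L:4L) {
        subsets <- lapply(datasets, function(d) d[d$baseline_state == st, ])
        if (nrow(subsets[[1]]) < 300 ||
            sum(subsets[[1]]$death_event) < 30) next
        pooled <- try_block(
          paste("cox mortality", mc$label, .state_levels[st]),
          pooled_or_single(subsets, fit_cox,
                           time = "death_time", event = "death_event",
                           exposure = mc$quart_col,
                           covariates = covs, quartiles = TRUE))
        if (is.null(pooled)) next
        rows[[length(rows) + 1]] <-
          dplyr::mutate(pooled, metric = mc$label, outcome = "mortality",
                        coding = "quartile",
                        baseline_group = .state_levels[st], .before = 1)
      }
    }
    results$cox <- dplyr::bind_rows(rows)
  }

  # --- dose-response ----------------------------------------------------
  if ("dose_response" %in% config$blocks) {
    curves <- list()
    for (mt in config$metrics) {
      mc <- metric_columns(mt, scored)
      for (onm in c("incident_single", "incident_multimorbidity")) {
        sp <- if (onm == "incident_single") {
          c("single_time", "single_event")
        } else c("multi_time", "multi_event")
        knots <- rcs_knots(free_sets[[1]][[mc$sd_col]], 4)
        fits <- try_block(
          paste("dose-response", mc$label, onm),
          lapply(free_sets, function(d)
            fit_dose_response(d, time = sp[1], event = sp[2],
                              exposure = mc$sd_col, covariates = covs,
                              knots = knots, reference = 0)))
        if (is.null(fits)) next
        if (length(fits) == 1) {
          cv <- fits[[1]]$curve
        } else {
          grid <- fits[[1]]$curve$x
          loghr <- sapply(fits, function(f) f$curve$loghr)
          sev <- sapply(fits, function(f) f$curve$se^2)
          pooled <- lapply(seq_along(grid), function(i)
            pool_rubin(loghr[i, ], sev[i, ]))
          pooled <- dplyr::bind_rows(pooled)
          cv <- tibble::tibble(x = grid, loghr = pooled$point,
                               se = sqrt(pooled$total_var),
                               hr = exp(pooled$point),
                               ci_low = exp(pooled$ci_low),
                               ci_high = exp(pooled$ci_high))
        }
        curves[[length(curves) + 1]] <-
          dplyr::mutate(cv, metric = mc$label, outcome = onm, .before = 1)
      }
    }
    results$dose_response <- dplyr::bind_rows(curves)
  }

  # --- multistate -------------------------------------------------------
  if ("multistate" %in% config$blocks) {
    scored$age_decade <- (scored$chronological_age - 60) / 10
    fits <- list()
    for (mt in config$metrics) {
      mc <- metric_columns(mt, scored)
      cd <- scored[, c("id", "sex_female", "age_decade", mc$sd_col)]
      names(cd)[4] <- "accel_sd"
      fits[[mc$label]] <- fit_multistate(
        panel, cd, covariates = c("sex_female", "age_decade", "accel_sd"))
    }
    results$multistate <- fits
  }

  # --- life expectancy --------------------------------------------------
  if ("life_expectancy" %in% config$blocks) {
    surv <- scored
    surv$entry_age <- surv$chronological_age
    surv$exit_age <- pmin(surv$death_age, surv$censor_age, na.rm = TRUE)
    surv$death <- as.integer(!is.na(surv$death_age) &
                               surv$death_age <= surv$censor_age)
    surv <- surv[surv$exit_age > surv$entry_age, ]
    for (st in c("single", "dual", "triple")) {
      surv[[paste0("state_", st)]] <-
        as.numeric(surv$baseline_state == match(st, .state_levels))
    }
    sex_mean <- mean(surv$sex_female)
    rp <- fit_royston_parmar(
      surv, entry = "entry_age", exit = "exit_age", event = "death",
      covariates = c("state_single", "state_dual", "state_triple",
                     "sex_female"), df = 4)
    zs <- list(
      none = c(state_single = 0, state_dual = 0, state_triple = 0,
               sex_female = sex_mean),
      single = c(state_single = 1, state_dual = 0, state_triple = 0,
                 sex_female = sex_mean),
      dual = c(state_single = 0, state_dual = 1, state_triple = 0,
               sex_female = sex_mean),
      triple = c(state_single = 0, state_dual = 0, state_triple = 1,
                 sex_female = sex_mean))
    results$life_expectancy <- le_table(
      rp, zs, referent = "none", ages = config$le_ages,
      B = config$ci_draws, seed = seed + 2L)
    results$rp_fit <- rp

    # LE loss from accelerated aging (Q4 vs Q1) per metric
    acc_rows <- list()
    for (mt in config$metrics) {
      mc <- metric_columns(mt, scored)
      sub <- surv[surv[[mc$quart_col]] %in% c("Q1", "Q4"), ]
      sub$q4 <- as.numeric(sub[[mc$quart_col]] == "Q4")
      rp_q <- fit_royston_parmar(
        sub, entry = "entry_age", exit = "exit_age", event = "death",
        covariates = c("state_single", "state_dual", "state_triple",
                       "sex_female", "q4"), df = 4)
      for (st in c("none", "single", "dual", "triple")) {
        zb <- c(state_single = as.numeric(st == "single"),
                state_dual = as.numeric(st == "dual"),
                state_triple = as.numeric(st == "triple"),
                sex_female = sex_mean)
        y <- years_of_life_lost(rp_q, z_group = c(zb, q4 = 1),
                                z_ref = c(zb, q4 = 0), age_a = 45,
                                B = config$ci_draws, seed = seed + 3L)
        acc_rows[[length(acc_rows) + 1]] <-
          dplyr::mutate(y, metric = mc$label, baseline_group = st,
                        .before = 1)
      }
    }
    results$accel_yll <- dplyr::bind_rows(acc_rows)
  }

  provenance <- list(
    seed = seed, n_input = n_input,
    package_version = as.character(utils::packageVersion("agepath")),
    imputations = if (config$impute) length(datasets) else 0L,
    landmark_years = config$landmark_years,
    complete_case = !config$impute,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- list(cohort = scored, exclusions = exclusions, results = results,
              provenance = provenance, config = config)
  class(out) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$exclusions, file.path(dir, "exclusions.csv"),
            row.names = FALSE)
  for (nm in c("logistic", "cox", "dose_response")) {
    if (!is.null(result$results[[nm]])) {
      write.csv(result$results[[nm]], file.path(dir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
  }
  if (!is.null(result$results$multistate)) {
    ms <- purrr::imap(result$results$multistate,
                      function(f, nm) dplyr::mutate(tidy(f), metric = nm,
                                                    .before = 1))
    write.csv(dplyr::bind_rows(ms), file.path(dir, "multistate.csv"),
              row.names = FALSE)
  }
  if (!is.null(result$results$life_expectancy)) {
    write.csv(result$results$life_expectancy,
              file.path(dir, "life_expectancy.csv"), row.names = FALSE)
  }
  jsonlite::write_json(result$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("agepath pipeline run (seed", x$provenance$seed, ")\n")
  cat("exclusion accounting:\n")
  print(x$exclusions)
  cat("blocks run:", paste(names(x$results), collapse = ", "), "\n")
  invisible(x)
}
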