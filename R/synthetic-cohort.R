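#' Load or build a synthetic-cohort generator configuration
#'
#' The generator draws a cohort whose statistical structure matches what the
#' downstream pipeline assumes: age- and sex-dependent biomarker means with
#' Gaussian noise, a single latent frailty shared between biomarkers and
#' disease progression, proportional-intensity progression through
#' none/single/dual/triple multimorbidity states, Gompertz age-dependent
#' mortality from the diseased states, and per-column missingness.
#'
#' The default calibration lives in a versioned YAML file shipped with the
#' package (`system.file("extdata", "default_generator.yaml", package =
#' "agepath")`).  Its transition intensities are tuned so that the baseline
#' state mix is roughly 18% no condition, 55% single, 23% dual and 3% triple
#' at the default age distribution, and overall mortality over the default
#' 13.6-year follow-up is roughly 8%.
#'
#' @param ... Named overrides of top-level config entries (e.g.
#'   `n_participants = 500`, `seed = 42`, `frailty_sd = 0`).
#' @param file Path to a YAML config; defaults to the packaged calibration.
#' @return A validated config list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_participants = 50, seed = 1)
#' cfg$followup_years
cohort_config <- function(..., file = NULL) {
  file <- file %||% system.file("extdata", "default_generator.yaml",
                                package = "agepath")
  cfg <- yaml::read_yaml(file)
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  validate_cohort_config(cfg)
}

allowed_transitions <- function() {
  tibble::tibble(
    edge = c("none_single", "single_dual", "dual_triple",
             "single_death", "dual_death", "triple_death"),
    from = c(1L, 2L, 3L, 2L, 3L, 4L),
    to   = c(2L, 3L, 4L, 5L, 5L, 5L)
  )
}

validate_cohort_config <- function(cfg) {
  stopifnot_cfg(is.numeric(cfg$n_participants) && cfg$n_participants >= 1,
                "n_participants", "must be a positive count")
  stopifnot_cfg(is.numeric(cfg$seed), "seed", "must be numeric")
  stopifnot_cfg(length(cfg$age_range) == 2 && cfg$age_range[1] < cfg$age_range[2],
                "age_range", "must be (low, high) with low < high")
  stopifnot_cfg(cfg$sex_ratio >= 0 && cfg$sex_ratio <= 1,
                "sex_ratio", "must be a proportion in [0, 1]")
  stopifnot_cfg(cfg$followup_years > 0, "followup_years", "must be > 0")
  stopifnot_cfg(cfg$frailty_sd >= 0, "frailty_sd", "must be >= 0")
  for (nm in names(cfg$biomarker_models)) {
    bm <- cfg$biomarker_models[[nm]]
    stopifnot_cfg(is.numeric(bm$residual_sd) && bm$residual_sd > 0,
                  paste0("biomarker_models$", nm, "$residual_sd"),
                  "must be > 0")
  }
  edges <- allowed_transitions()$edge
  have <- names(cfg$transition_log_intensities)
  stopifnot_cfg(setequal(have, edges), "transition_log_intensities",
                paste("must be defined exactly for:", paste(edges, collapse = ", ")))
  stopifnot_cfg(all(edges %in% names(cfg$transition_frailty_loghr)),
                "transition_frailty_loghr",
                "must cover every allowed transition")
  for (nm in names(cfg$missingness_rates)) {
    r <- cfg$missingness_rates[[nm]]
    stopifnot_cfg(is.numeric(r) && r >= 0 && r <= 1,
                  paste0("missingness_rates$", nm), "must be in [0, 1]")
  }
  structure(cfg, class = c("cohort_config", "list"))
}

# per-participant intensity set: constant disorder-progression rates and
# Gompertz death rates evaluated at a given age
participant_rates <- function(cfg, frailty) {
  tr <- allowed_transitions()
  base <- unlist(cfg$transition_log_intensities)[tr$edge]
  loghr <- unlist(cfg$transition_frailty_loghr)[tr$edge]
  logq <- base + loghr * frailty
  gomp <- cfg$gompertz_mortality
  list(
    edges = tr,
    logq = logq,
    is_death = tr$to == 5L,
    gomp_intercept = gomp$rate_intercept,
    gomp_slope = gomp$age_slope,
    gomp_ref = gomp$reference_age %||% 60
  )
}

edge_rate_at_age <- function(rates, e, age, allow_death) {
  lq <- rates$logq[e]
  if (rates$is_death[e]) {
    if (!allow_death) return(0)
    lq <- lq + rates$gomp_intercept +
      rates$gomp_slope * (age - rates$gomp_ref)
  }
  exp(lq)
}

#' Simulate one participant's disease history
#'
#' Simulates the continuous-time progression none -> single -> dual -> triple
#' with state-specific death exits, by competing exponential clocks refreshed
#' at each jump.  The Gompertz age dependence of the death intensities is
#' handled by a piecewise-constant approximation on a 1-year age grid; the
#' disorder-progression intensities are constant in age.  Death intensities
#' are switched on only from `death_from_age` onward (the cohort is enrolled
#' alive at baseline).
#'
#' @param baseline_age Age (years) at cohort baseline.
#' @param sex `"female"` or `"male"` (carried through; the default intensity
#'   calibration is sex-neutral, sex acts via the fitted models instead).
#' @param frailty Latent frailty draw (dimensionless, finite); multiplies
#'   each transition intensity by `exp(loghr * frailty)`.
#' @param config A `cohort_config`.
#' @param from_age Age at which progression starts (default
#'   `config$progression_start_age`); the participant starts disease-free.
#' @param to_age End of simulation (default baseline + follow-up).
#' @param death_from_age Age from which death intensities apply (default
#'   `baseline_age`).
#' @return A tibble with columns `age`, `state` (integer code), and `domain`
#'   (the disorder domain acquired at that jump, `NA` for death).  Empty when
#'   no event occurs.
#' @export
simulate_disease_history <- function(baseline_age, sex, frailty, config,
                                     from_age = NULL, to_age = NULL,
                                     death_from_age = baseline_age) {
  stopifnot(is.finite(frailty))
  cfg <- config
  from_age <- from_age %||% cfg$progression_start_age %||% 25
  to_age <- to_age %||% (baseline_age + cfg$followup_years)
  rates <- participant_rates(cfg, frailty)

  state <- 1L
  age <- from_age
  present <- character(0)
  ev_age <- numeric(0); ev_state <- integer(0); ev_domain <- character(0)

  while (state != 5L && age < to_age) {
    exits <- which(rates$edges$from == state)
    if (length(exits) == 0) break
    allow_death <- age >= death_from_age
    # piecewise-constant segment: with death off the rates are constant in
    # age, so the segment runs to the death switch-on (or horizon); with
    # death on, to the next integer age (1-year Gompertz grid)
    seg_end <- if (allow_death) min(floor(age) + 1, to_age)
               else min(death_from_age, to_age)
    q <- vapply(exits, function(e) edge_rate_at_age(rates, e, age, allow_death),
                numeric(1))
    total <- sum(q)
    if (total < 1e-300) { age <- seg_end; next }  # denormal rates: no event
    wait <- rexp(1, total)
    if (!is.finite(wait) || age + wait >= seg_end) { age <- seg_end; next }
    age <- age + wait
    e <- exits[sample.int(length(exits), 1, prob = q)]
    state <- rates$edges$to[e]
    dom <- NA_character_
    if (state != 5L) {
      free <- setdiff(.domains, present)
      dom <- free[sample.int(length(free), 1)]
      present <- c(present, dom)
    }
    ev_age <- c(ev_age, age); ev_state <- c(ev_state, state)
    ev_domain <- c(ev_domain, dom)
  }
  tibble::tibble(age = ev_age, state = ev_state, domain = ev_domain)
}

draw_baseline_ages <- function(n, cfg) {
  m <- cfg$age_mean %||% mean(cfg$age_range)
  s <- cfg$age_sd %||% (diff(range(cfg$age_range)) / 4)
  lo <- cfg$age_range[1]; hi <- cfg$age_range[2]
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, m, s)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

draw_covariates <- function(n, cfg) {
  cv <- cfg$covariate_models
  samp_cat <- function(spec) {
    p <- unlist(spec$probs)
    factor(sample(spec$levels[seq_along(p)], n, replace = TRUE, prob = p),
           levels = spec$levels, ordered = isTRUE(spec$ordered))
  }
  tibble::tibble(
    ethnicity = samp_cat(cv$ethnicity),
    education = samp_cat(cv$education),
    income = samp_cat(cv$income),
    smoking = samp_cat(cv$smoking),
    alcohol = samp_cat(cv$alcohol),
    bmi_category = samp_cat(cv$bmi_category),
    townsend = rnorm(n, cv$townsend$mean, cv$townsend$sd),
    physical_activity = rgamma(n, shape = cv$physical_activity$shape,
                               scale = cv$physical_activity$scale),
    diet_score = rbinom(n, 5, cv$diet_score$prob),
    no2 = rnorm(n, cv$no2$mean, cv$no2$sd),
    nox = rnorm(n, cv$nox$mean, cv$nox$sd),
    pm25 = rnorm(n, cv$pm25$mean, cv$pm25$sd),
    pm10 = rnorm(n, cv$pm10$mean, cv$pm10$sd)
  )
}

draw_biomarkers <- function(age, sex_female, frailty, cfg) {
  out <- list()
  for (nm in names(cfg$biomarker_models)) {
    bm <- cfg$biomarker_models[[nm]]
    mu <- bm$intercept + bm$age_slope * age + bm$sex_offset * sex_female +
      (bm$frailty_loading %||% 0) * frailty * bm$residual_sd
    x <- mu + rnorm(length(age), 0, bm$residual_sd)
    if (isTRUE(bm$log_scale)) x <- exp(x)
    out[[nm]] <- x
  }
  tibble::as_tibble(out)
}

#' Generate a seeded synthetic cohort
#'
#' Draws `config$n_participants` participants: baseline age, sex, a latent
#' frailty shared between biomarkers and disease progression, the biomarker
#' panel measured at baseline, baseline covariates, per-domain first-onset
#' ages (which may pre-date baseline, giving prevalent disease), death age
#' and censoring age.  All randomness flows from `config$seed`; two calls
#' with equal configs return identical tables.
#'
#' Disorder progression is simulated from `progression_start_age` (disease
#' free) so that the baseline multimorbidity mix emerges from the same
#' intensities that drive follow-up; death intensities act from baseline
#' onward (enrolment conditions on being alive).
#'
#' @param config A `cohort_config`.
#' @param apply_missingness Mask covariate cells at the configured
#'   per-column rates (default `TRUE`; set `FALSE` for fully observed data).
#' @return A tibble with one row per participant.  The latent `frailty`
#'   column is included for diagnostics; real cohorts do not have it and the
#'   pipeline never uses it.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_participants = 20, seed = 1))
#' dim(coh)
generate_cohort <- function(config, apply_missingness = TRUE) {
  cfg <- if (inherits(config, "cohort_config")) config else
    validate_cohort_config(config)
  n <- as.integer(cfg$n_participants)
  set.seed(as.integer(cfg$seed))

  age <- draw_baseline_ages(n, cfg)
  sex <- ifelse(runif(n) < cfg$sex_ratio, "female", "male")
  frailty <- rnorm(n, 0, cfg$frailty_sd)

  bio <- draw_biomarkers(age, as.numeric(sex == "female"), frailty, cfg)
  cov <- draw_covariates(n, cfg)

  onset <- matrix(NA_real_, n, 3, dimnames = list(NULL, .domains))
  death_age <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ev <- simulate_disease_history(age[i], sex[i], frailty[i], cfg)
    if (nrow(ev)) {
      for (j in seq_len(nrow(ev))) {
        if (ev$state[j] == 5L) death_age[i] <- ev$age[j]
        else onset[i, ev$domain[j]] <- ev$age[j]
      }
    }
  }
  censor_age <- age + cfg$followup_years

  coh <- tibble::tibble(
    id = seq_len(n),
    chronological_age = age,
    sex = sex,
    frailty = frailty
  ) |>
    dplyr::bind_cols(bio, cov) |>
    dplyr::mutate(
      physical_onset_age = onset[, "physical"],
      psychological_onset_age = onset[, "psychological"],
      cognitive_onset_age = onset[, "cognitive"],
      death_age = death_age,
      censor_age = censor_age
    )

  if (apply_missingness && length(cfg$missingness_rates) > 0) {
    coh <- inject_missingness(coh, cfg$missingness_rates,
                              seed = as.integer(cfg$seed) + 1L,
                              mechanism = cfg$missingness_mechanism %||% "mcar")
  }
  attr(coh, "config") <- cfg
  coh
}

.protected_cols <- c("id", "chronological_age", "sex", "frailty",
                     "physical_onset_age", "psychological_onset_age",
                     "cognitive_onset_age", "death_age", "censor_age")

#' Mask cells at given per-column rates
#'
#' Missing-completely-at-random by default; with `mechanism = "mar_by_age"`
#' the per-row masking probability is proportional to the participant's age
#' rank (older participants more likely missing) while preserving the
#' requested marginal rate.  Outcome, date, id, sex and age columns are
#' protected and cannot be masked.
#'
#' @param table A cohort tibble.
#' @param rates Named list/vector of per-column missingness proportions.
#' @param seed Integer seed.
#' @param mechanism `"mcar"` or `"mar_by_age"`.
#' @return The table with the selected cells set to `NA`.
#' @export
inject_missingness <- function(table, rates, seed, mechanism = "mcar") {
  rates <- unlist(rates)
  bad <- intersect(names(rates), .protected_cols)
  if (length(bad) > 0) {
    abort(paste0("missingness requested on protected column(s): ",
                 paste(bad, collapse = ", ")),
          class = "agepath_protected_column")
  }
  missing_cols <- setdiff(names(rates), names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("missingness rate given for unknown column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(rates < 0 | rates > 1)) abort("missingness rates must be in [0, 1]")
  n <- nrow(table)
  set.seed(as.integer(seed))
  for (nm in names(rates)) {
    r <- rates[[nm]]
    if (r <= 0) next
    if (identical(mechanism, "mar_by_age")) {
      w <- rank(table$chronological_age, ties.method = "average") / n
      p <- pmin(1, 2 * r * w)        # E[p] ~ r, increasing in age
      mask <- runif(n) < p
    } else {
      mask <- runif(n) < r
    }
    table[[nm]][mask] <- NA
  }
  table
}
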