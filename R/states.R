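#' Classify a multimorbidity state from disorder-domain flags
#'
#' The state is determined solely by how many of the three domains
#' (physical, psychological, cognitive) are present: 0 -> none, 1 -> single,
#' 2 -> dual, 3 -> triple.  Which particular domains are held does not
#' change the level.
#'
#' @param domains Character vector, a subset of [disorder_domains()].
#' @return Integer state code (see [health_states()]).
#' @export
#' @examples
#' classify_state(c("physical", "cognitive"))  # dual
classify_state <- function(domains) {
  domains <- unique(domains)
  bad <- setdiff(domains, .domains)
  if (length(bad) > 0) {
    abort(paste0("unknown disorder domain(s): ", paste(bad, collapse = ", ")))
  }
  as.integer(length(domains) + 1L)
}

#' Build a participant's health-state timeline
#'
#' The baseline state collects every domain whose first onset is at or
#' before baseline age.  Each later distinct onset age adds one entry; two
#' or three domains recorded at exactly the same age are split into
#' consecutive single-level jumps separated by a one-day epsilon (the
#' continuous-time model has no multi-level jumps), ordered
#' physical -> psychological -> cognitive.  Death is appended when the death
#' age is at or before the censoring age.  Onsets after death are an error.
#'
#' @param onsets Named numeric vector of first-onset ages (years); use `NA`
#'   or omit for a domain never present.  Names from [disorder_domains()].
#' @param baseline_age,censor_age Baseline and censoring ages (years).
#' @param death_age Death age or `NA`.
#' @param id Participant id carried into the output.
#' @return Tibble: `id`, `age`, `state` (code), `n_domains`, plus attributes
#'   `death_age`/`censor_age`.  First row is the baseline state at
#'   `baseline_age`.
#' @export
build_timeline <- function(onsets, baseline_age, censor_age,
                           death_age = NA_real_, id = NA_integer_) {
  if (baseline_age < 0 || censor_age < baseline_age) {
    abort("need 0 <= baseline_age <= censor_age")
  }
  onsets <- onsets[!is.na(onsets)]
  if (any(onsets < 0)) abort("negative onset age")
  if (!is.na(death_age) && length(onsets) > 0 && any(onsets > death_age)) {
    abort("disorder onset recorded after death", class = "agepath_timeline_error")
  }
  end_age <- if (!is.na(death_age)) min(death_age, censor_age) else censor_age
  onsets <- onsets[onsets <= end_age]

  base_domains <- names(onsets)[onsets <= baseline_age]
  age <- baseline_age
  state <- classify_state(base_domains)
  ages <- age; states <- state; nd <- length(base_domains)

  later <- onsets[onsets > baseline_age]
  eps <- 1 / 365.25
  if (length(later) > 0) {
    # deterministic tie-break at equal ages: physical -> psychological ->
    # cognitive, separated by a one-day epsilon
    later <- later[order(later, match(names(later), .domains))]
    last_age <- ages[length(ages)]
    for (j in seq_along(later)) {
      a <- later[[j]]
      if (a <= last_age) a <- last_age + eps
      count <- nd[length(nd)] + 1L
      nd <- c(nd, count)
      states <- c(states, count + 1L)
      ages <- c(ages, a)
      last_age <- a
    }
  }
  if (!is.na(death_age) && death_age <= censor_age) {
    d_age <- death_age
    if (d_age <= ages[length(ages)]) d_age <- ages[length(ages)] + eps
    ages <- c(ages, d_age)
    states <- c(states, 5L)
    nd <- c(nd, nd[length(nd)])
  }
  out <- tibble::tibble(id = id, age = ages, state = as.integer(states),
                        n_domains = as.integer(nd))
  attr(out, "death_age") <- death_age
  attr(out, "censor_age") <- censor_age
  out
}

#' Build timelines for a whole cohort
#'
#' @param cohort Cohort table with `id`, `chronological_age`,
#'   `*_onset_age` columns, `death_age` and `censor_age`.
#' @return Long tibble of timeline entries (one row per id x state entry)
#'   with per-id `death_age` and `censor_age` columns.
#' @export
build_timelines <- function(cohort) {
  need <- c("id", "chronological_age", paste0(.domains, "_onset_age"),
            "death_age", "censor_age")
  absent <- setdiff(need, names(cohort))
  if (length(absent) > 0) {
    abort(paste0("missing column(s): ", paste(absent, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    on <- setNames(as.numeric(cohort[i, paste0(.domains, "_onset_age")]),
                   .domains)
    tl <- build_timeline(on, cohort$chronological_age[i],
                         cohort$censor_age[i], cohort$death_age[i],
                         id = cohort$id[i])
    tl$death_age <- cohort$death_age[i]
    tl$censor_age <- cohort$censor_age[i]
    tl
  })
  dplyr::bind_rows(rows)
}

#' Convert timelines to panel observations
#'
#' Under the `"event-dates"` scheme each participant contributes an
#' observation at baseline, at each disorder-onset age, and at the end of
#' observation (death, marked exactly observed, or censoring).  Participants
#' whose only transition is no-condition -> death are excluded (that edge is
#' not in the model graph) and counted in the `"exclusions"` attribute.
#'
#' @param timelines Output of [build_timelines()].
#' @param scheme Observation scheme; only `"event-dates"` is implemented.
#' @return Tibble: `id`, `time` (years since baseline), `age`, `state`,
#'   `exact_death` (logical); attribute `exclusions` is a one-row tibble
#'   with the none-to-death exclusion count.
#' @export
make_panel <- function(timelines, scheme = "event-dates") {
  if (!identical(scheme, "event-dates")) {
    abort("only the 'event-dates' observation scheme is implemented")
  }
  if (nrow(timelines) == 0) {
    out <- tibble::tibble(id = integer(), time = numeric(), age = numeric(),
                          state = integer(), exact_death = logical())
    attr(out, "exclusions") <-
      tibble::tibble(reason = "none_to_death", n = 0L)
    return(out)
  }
  excluded <- 0L
  panels <- timelines |>
    dplyr::group_by(.data$id) |>
    dplyr::group_split()
  rows <- lapply(panels, function(tl) {
    tl <- dplyr::arrange(tl, .data$age)
    states <- tl$state
    # direct none -> death with no intermediate state: drop participant
    if (any(states == 5L) && all(states %in% c(1L, 5L))) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    baseline <- tl$age[1]
    died <- any(states == 5L)
    obs_age <- tl$age
    obs_state <- states
    if (!died) {
      cens <- tl$censor_age[1]
      if (cens > obs_age[length(obs_age)]) {
        obs_age <- c(obs_age, cens)
        obs_state <- c(obs_state, obs_state[length(obs_state)])
      }
    }
    tibble::tibble(id = tl$id[1], time = obs_age - baseline, age = obs_age,
                   state = as.integer(obs_state),
                   exact_death = obs_state == 5L)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "exclusions") <- tibble::tibble(reason = "none_to_death",
                                            n = excluded)
  out
}

#' Landmark exclusion of early events
#'
#' Removes participants with any disorder onset or death within
#' `window_years` after baseline, a sensitivity design against reverse
#' causation.  Survivors' records are unchanged.
#'
#' @param timelines Output of [build_timelines()].
#' @param window_years Exclusion window (default 5; 0 returns the input).
#' @return Filtered timelines; attribute `n_excluded` gives the count.
#' @export
landmark_exclude <- function(timelines, window_years = 5) {
  if (window_years < 0) abort("window_years must be >= 0")
  if (window_years == 0 || nrow(timelines) == 0) {
    attr(timelines, "n_excluded") <- 0L
    return(timelines)
  }
  early <- timelines |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      baseline = min(.data$age),
      early_event = any(.data$age > .data$baseline[1] &
                          .data$age <= .data$baseline[1] + window_years),
      .groups = "drop")
  drop_ids <- early$id[early$early_event]
  out <- dplyr::filter(timelines, !.data$id %in% drop_ids)
  attr(out, "n_excluded") <- length(drop_ids)
  out
}

#' Baseline multimorbidity state for each participant
#'
#' @param cohort Cohort table (see [build_timelines()] for required columns).
#' @return Integer vector of baseline state codes (1-4).
#' @export
baseline_state <- function(cohort) {
  counts <- rep(0L, nrow(cohort))
  for (d in .domains) {
    on <- cohort[[paste0(d, "_onset_age")]]
    counts <- counts + as.integer(!is.na(on) & on <= cohort$chronological_age)
  }
  counts + 1L
}
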