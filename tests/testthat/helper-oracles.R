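# Independent oracles used across the test suite.  These deliberately avoid
# the package's own code paths: direct arithmetic, closed forms, and an
# inverse-CDF event-time sampler for the continuous-time Markov chain.

# Direct evaluation of the Klemera-Doubal weighted-mean formula for one
# participant, plain arithmetic.
kdm_oracle <- function(x, q, k, s, ca, s_ba) {
  num <- sum((x - q) * k / s^2) + ca / s_ba^2
  den <- sum((k / s)^2) + 1 / s_ba^2
  num / den
}

# Step-by-step phenotypic age: xb -> 120-month mortality risk -> age.
phenoage_oracle <- function(xb, gamma = 0.0076927, horizon = 120,
                            c1 = 141.50225, c2 = -0.00553, c3 = 0.090165) {
  risk <- 1 - exp(-exp(xb) * (exp(horizon * gamma) - 1) / gamma)
  c1 + log(c2 * log(1 - risk)) / c3
}

# Closed-form OLS residuals via the normal equations.
ols_residuals_oracle <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  drop(y - X %*% beta)
}

# Harrell restricted-cubic-spline truncated-power formula, written out
# directly (normalized by the squared boundary-knot span).
rcs_oracle <- function(x, knots) {
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]
  pl <- function(u) ifelse(u > 0, u^3, 0)
  cols <- sapply(seq_len(k - 2), function(j) {
    (pl(x - knots[j]) - pl(x - tk1) * (tk - knots[j]) / (tk - tk1) +
       pl(x - tk) * (tk1 - knots[j]) / (tk - tk1)) / (tk - knots[1])^2
  })
  cbind(x, cols)
}

# Event-time sampler for the illness-death chain by inverse-CDF on the
# piecewise-constant (1-year grid) total exit hazard.  Independent of the
# package's competing-clock simulator.
#   rates: function(state, age) -> named numeric of exit rates
#          (names = destination state codes)
gillespie_path <- function(from_age, to_age, state, rates) {
  path <- list()
  age <- from_age
  while (state != 5L && age < to_age) {
    target <- stats::rexp(1)       # cumulative hazard to next event
    acc <- 0
    a <- age
    repeat {
      seg_end <- min(floor(a) + 1, to_age)
      r <- rates(state, a)
      tot <- sum(r)
      if (acc + tot * (seg_end - a) >= target && tot > 0) {
        a <- a + (target - acc) / tot
        dest <- as.integer(sample(names(r), 1, prob = r))
        state <- dest
        path[[length(path) + 1]] <- c(age = a, state = dest)
        break
      }
      acc <- acc + tot * (seg_end - a)
      a <- seg_end
      if (a >= to_age) { state <- -1L; break }  # censored
    }
    if (state == -1L) break
    age <- a
    if (state == 5L) break
  }
  if (length(path) == 0) {
    return(data.frame(age = numeric(0), state = integer(0)))
  }
  as.data.frame(do.call(rbind, path))
}

# Exit-rate function matching the default generator's definition.
generator_rates_fn <- function(cfg, frailty, death_from_age) {
  lq <- unlist(cfg$transition_log_intensities)
  fh <- unlist(cfg$transition_frailty_loghr)
  gm <- cfg$gompertz_mortality
  function(state, age) {
    out <- c()
    if (state == 1L) {
      out["2"] <- exp(lq["none_single"] + fh["none_single"] * frailty)
    } else if (state == 2L) {
      out["3"] <- exp(lq["single_dual"] + fh["single_dual"] * frailty)
      if (age >= death_from_age) {
        out["5"] <- exp(lq["single_death"] + fh["single_death"] * frailty +
                          gm$rate_intercept +
                          gm$age_slope * (age - gm$reference_age))
      }
    } else if (state == 3L) {
      out["4"] <- exp(lq["dual_triple"] + fh["dual_triple"] * frailty)
      if (age >= death_from_age) {
        out["5"] <- exp(lq["dual_death"] + fh["dual_death"] * frailty +
                          gm$rate_intercept +
                          gm$age_slope * (age - gm$reference_age))
      }
    } else if (state == 4L) {
      if (age >= death_from_age) {
        out["5"] <- exp(lq["triple_death"] + fh["triple_death"] * frailty +
                          gm$rate_intercept +
                          gm$age_slope * (age - gm$reference_age))
      }
    }
    if (is.null(out)) out <- c("5" = 0)
    out
  }
}

# Simulate interval-censored panel data from a known intensity model at
# fixed visit times (plus exactly observed deaths), for recovery tests.
simulate_panel <- function(model, X, visit_times, seed = 1) {
  set.seed(seed)
  st <- model$structure
  nsub <- nrow(X)
  rows <- list()
  for (i in seq_len(nsub)) {
    z <- X[i, , drop = TRUE]
    lq <- model$log_q0 + if (ncol(model$beta)) drop(model$beta %*%
                                                      as.numeric(z)) else 0
    qe <- exp(lq)
    state <- 1L
    t <- 0
    horizon <- max(visit_times)
    jumps <- list()
    while (state != 5L) {
      exits <- which(st$from == state)
      if (length(exits) == 0) break
      tot <- sum(qe[exits])
      if (tot <= 0) break
      t <- t + stats::rexp(1, tot)
      if (t > horizon) break
      state <- st$to[exits[sample.int(length(exits), 1,
                                      prob = qe[exits])]]
      jumps[[length(jumps) + 1]] <- c(t, state)
    }
    jm <- if (length(jumps)) do.call(rbind, jumps) else
      matrix(numeric(0), 0, 2)
    death_t <- if (nrow(jm) && jm[nrow(jm), 2] == 5) jm[nrow(jm), 1] else NA
    obs_t <- visit_times
    if (!is.na(death_t)) obs_t <- c(obs_t[obs_t < death_t], death_t)
    state_at <- function(tt) {
      s <- 1L
      if (nrow(jm)) for (j in seq_len(nrow(jm)))
        if (jm[j, 1] <= tt) s <- as.integer(jm[j, 2])
      s
    }
    rows[[i]] <- data.frame(
      id = i, time = obs_t,
      state = vapply(obs_t, state_at, integer(1)),
      exact_death = !is.na(death_t) & obs_t == death_t)
  }
  out <- dplyr::bind_rows(rows)
  tibble::as_tibble(out)
}

# Small complete test cohort without going through the generator defaults.
tiny_cohort <- function(n = 400, seed = 42) {
  cfg <- cohort_config(n_participants = n, seed = seed)
  generate_cohort(cfg, apply_missingness = FALSE)
}
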