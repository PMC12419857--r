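toy_model <- function(lq = c(none_single = -2.5, single_dual = -3,
                             dual_triple = -3.5, single_death = -4,
                             dual_death = -3.8, triple_death = -3.2),
                      beta = NULL, covariates = colnames(beta)) {
  intensity_model(lq, beta, covariates)
}

test_that("transition probabilities satisfy the CTMC identities", {
  m <- toy_model()
  # dt = 0 is the identity
  expect_equal(transition_probability(m, dt = 0), diag(5),
               ignore_attr = TRUE)
  P <- transition_probability(m, dt = 4)
  expect_true(all(P >= 0))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  # death row is absorbing
  expect_equal(unname(P[5, ]), c(0, 0, 0, 0, 1))
  # Chapman-Kolmogorov on random generators
  set.seed(61)
  for (r in 1:20) {
    lq <- setNames(runif(6, -5, -0.5), names(m$log_q0))
    mr <- toy_model(lq)
    s <- runif(1, 0.1, 5); t <- runif(1, 0.1, 5)
    Pst <- transition_probability(mr, dt = s + t)
    expect_lt(max(abs(Pst - transition_probability(mr, dt = s) %*%
                        transition_probability(mr, dt = t))), 1e-9)
  }
})

test_that("the uniformization exponential agrees with a dense-series oracle", {
  skip_if_not_installed("expm")
  set.seed(62)
  for (r in 1:20) {
    m <- toy_model(setNames(runif(6, -5, 0.5), names(toy_model()$log_q0)))
    Q <- generator_matrix(m)
    dt <- runif(1, 0.01, 40)
    P1 <- unname(transition_probability(m, dt = dt))
    P2 <- unname(as.matrix(expm::expm(Q * dt)))
    expect_lt(max(abs(P1 - P2)), 1e-9)
  }
})

test_that("the two-state closed form holds to 1e-10", {
  q <- 0.23
  lq <- c(none_single = -30, single_dual = -30, dual_triple = -30,
          single_death = log(q), dual_death = -30, triple_death = -30)
  m <- toy_model(lq)
  for (t in c(0.1, 0.5, 1, 2, 5, 10, 25)) {
    P <- transition_probability(m, dt = t)
    expect_lt(abs(P[2, 5] - (1 - exp(-q * t))), 1e-10)
    expect_lt(abs(P[2, 2] - exp(-q * t)), 1e-10)
  }
})

test_that("panel log-likelihood reproduces hand-computed contributions", {
  # frozen generator: a participant observed twice in the same state with
  # all intensities (effectively) zero has stay probability one
  lq0 <- setNames(rep(-30, 6), names(toy_model()$log_q0))
  m0 <- toy_model(lq0)
  panel0 <- tibble::tibble(id = 1, time = c(0, 1), state = c(2L, 2L),
                           exact_death = FALSE)
  expect_equal(panel_loglik(m0, panel0), 0, tolerance = 1e-10)

  # exactly observed single -> death at T: density exp(-qT) * q
  q <- 0.12; T <- 3.7
  lq <- lq0; lq["single_death"] <- log(q)
  m1 <- toy_model(lq)
  panel1 <- tibble::tibble(id = 1, time = c(0, T), state = c(2L, 5L),
                           exact_death = c(FALSE, TRUE))
  expect_equal(panel_loglik(m1, panel1), log(exp(-q * T) * q),
               tolerance = 1e-9)

  # an observed backward move is infeasible: -Inf with the participant named
  panel2 <- tibble::tibble(id = 7, time = c(0, 2), state = c(3L, 2L),
                           exact_death = FALSE)
  ll <- panel_loglik(toy_model(), panel2)
  expect_identical(as.numeric(ll), -Inf)
  expect_equal(attr(ll, "infeasible_ids"), 7)
})

test_that("interval splitting leaves the likelihood invariant", {
  m <- toy_model()
  # observing (2, t=0) and (2, t=4) must equal marginalizing over the state
  # at t = 1.5: handled internally by the semigroup property
  p_direct <- transition_probability(m, dt = 4)[2, 3]
  P1 <- transition_probability(m, dt = 1.5)
  P2 <- transition_probability(m, dt = 2.5)
  p_split <- sum(P1[2, ] * P2[, 3])
  expect_lt(abs(p_direct - p_split), 1e-10)
})

test_that("the analytic likelihood gradient matches finite differences", {
  skip_if_not_installed("numDeriv")
  set.seed(63)
  beta <- matrix(c(0.3, -0.2, 0.1, 0.4, 0.25, -0.1), ncol = 1,
                 dimnames = list(NULL, "z"))
  model <- toy_model(beta = beta)
  X <- matrix(rnorm(40), ncol = 1, dimnames = list(NULL, "z"))
  pan <- simulate_panel(model, as.data.frame(X), visit_times = c(0, 2, 5, 9),
                        seed = 3)
  cd <- tibble::tibble(id = seq_len(nrow(X)), z = X[, 1])
  st <- transition_structure()
  pp <- agepath:::prepare_panel(pan, cd, "z")
  par <- c(model$log_q0, as.vector(t(model$beta)))
  got <- agepath:::cpp_panel_loglik_grad(par, st$from, st$to, 5L, pp$state,
                                         pp$time, pp$exact, pp$offsets, pp$X)
  fn <- function(p) agepath:::cpp_panel_loglik(p, st$from, st$to, 5L,
                                               pp$state, pp$time, pp$exact,
                                               pp$offsets, pp$X)
  expect_equal(got$loglik, fn(par))
  num <- numDeriv::grad(fn, par)
  expect_lt(max(abs(got$gradient - num)), 1e-6 * max(1, max(abs(num))))
})

test_that("panel MLE recovers the generating intensity model", {
  set.seed(64)
  n <- 1500
  beta <- matrix(c(0.4, 0.3, 0.2, 0.5, 0.35, 0.25), ncol = 1,
                 dimnames = list(NULL, "z"))
  lq <- c(none_single = -2.2, single_dual = -2.8, dual_triple = -3.0,
          single_death = -3.5, dual_death = -3.2, triple_death = -2.8)
  truth <- toy_model(lq, beta)
  X <- data.frame(z = rnorm(n))
  pan <- simulate_panel(truth, X, visit_times = c(0, 3, 6, 10), seed = 65)
  cd <- tibble::tibble(id = seq_len(n), z = X$z)
  fit <- fit_multistate(pan, cd, covariates = "z")
  td <- tidy(fit)
  base <- td[td$type == "intensity", ]
  expect_lt(max(abs(base$estimate - lq) / base$se), 3)
  eff <- td[td$type == "loghr", ]
  expect_lt(max(abs(eff$estimate - beta[, 1]) / eff$se), 3)
})

test_that("near-continuous observation recovers occurrence/exposure rates", {
  set.seed(66)
  n <- 3000
  lq <- c(none_single = -2.0, single_dual = -2.5, dual_triple = -2.6,
          single_death = -3.0, dual_death = -2.7, triple_death = -2.4)
  truth <- toy_model(lq)
  X <- data.frame(z = numeric(n))[, 0, drop = FALSE]
  # event-date observation with a small pre-jump epsilon: the sojourn state
  # is seen until just before each jump, so the path is fully observed
  eps <- 1e-4
  st <- transition_structure()
  rows <- list()
  for (i in seq_len(n)) {
    qe <- exp(lq)
    state <- 1L; t <- 0
    obs <- tibble::tibble(id = i, time = 0, state = 1L, exact_death = FALSE)
    while (state != 5L && t < 12) {
      exits <- which(st$from == state)
      tot <- sum(qe[exits])
      prev_state <- state
      t <- t + rexp(1, tot)
      if (t >= 12) break
      state <- st$to[exits[sample.int(length(exits), 1, prob = qe[exits])]]
      new_states <- c(prev_state, as.integer(state))
      new_exact <- c(FALSE, state == 5L)
      obs <- dplyr::bind_rows(obs, tibble::tibble(
        id = i, time = c(t - eps, t), state = new_states,
        exact_death = new_exact))
    }
    if (state != 5L) {
      obs <- dplyr::bind_rows(obs, tibble::tibble(
        id = i, time = 12, state = state, exact_death = FALSE))
    }
    rows[[i]] <- obs
  }
  pan <- dplyr::bind_rows(rows)
  # drop the none -> death impossibility: no such edge simulated
  fit <- fit_multistate(pan, covariates = character(0))
  # occurrence/exposure estimator
  pp <- agepath:::prepare_panel(pan, NULL, character(0))
  cr <- agepath:::crude_rates(pp, st)
  counts <- cr$count
  pt <- numeric(6)
  for (i in seq_len(length(pp$offsets) - 1)) {
    for (j in (pp$offsets[i] + 1):(pp$offsets[i + 1] - 1)) {
      s0 <- pp$state[j]
      dt <- pp$time[j + 1] - pp$time[j]
      pt[st$from == s0] <- pt[st$from == s0] + dt
    }
  }
  oe <- counts / pt
  expect_lt(max(abs(exp(fit$par[1:6]) - oe) / oe), 0.01)
})

test_that("doubling intervals and halving intensities rescales the fit", {
  set.seed(67)
  n <- 1200
  lq <- c(none_single = -1.8, single_dual = -2.3, dual_triple = -2.5,
          single_death = -2.9, dual_death = -2.6, triple_death = -2.3)
  m_fast <- toy_model(lq)
  m_slow <- toy_model(lq - log(2))
  X <- data.frame(z = numeric(n))[, 0, drop = FALSE]
  pan_fast <- simulate_panel(m_fast, X, visit_times = c(0, 2, 4, 7), seed = 68)
  pan_slow <- simulate_panel(m_slow, X, visit_times = 2 * c(0, 2, 4, 7),
                             seed = 68)
  f_fast <- fit_multistate(pan_fast, covariates = character(0))
  f_slow <- fit_multistate(pan_slow, covariates = character(0))
  d <- (f_slow$par[1:6] + log(2)) - f_fast$par[1:6]
  se <- sqrt(diag(f_fast$vcov)[1:6] + diag(f_slow$vcov)[1:6])
  expect_lt(max(abs(d) / se), 3)
})

test_that("unobserved transitions are reported as unidentifiable", {
  pan <- tibble::tibble(id = rep(1:20, each = 2),
                        time = rep(c(0, 5), 20),
                        state = rep(c(1L, 2L), 20),
                        exact_death = FALSE)
  expect_error(fit_multistate(pan, covariates = character(0)),
               "unidentifiable")
})
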