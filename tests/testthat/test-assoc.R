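test_that("covariate-free logistic fit reproduces the closed-form 2x2 OR", {
  dat <- tibble::tibble(
    y = c(rep(1, 40), rep(0, 60), rep(1, 20), rep(0, 80)),
    x = c(rep(1, 100), rep(0, 100)))
  fit <- fit_logistic(dat, outcome = "y", exposure = "x",
                      covariates = character(0))
  or <- fit$tidy$or[fit$tidy$term == "x"]
  expect_lt(abs(or - (40 * 80) / (60 * 20)), 1e-6)
})

test_that("logistic estimates are calibrated under null and alternative", {
  set.seed(41)
  n <- 10000
  x <- rnorm(n)
  # null: exposure independent of outcome
  y0 <- rbinom(n, 1, 0.3)
  f0 <- fit_logistic(tibble::tibble(y = y0, x = x), "y", "x",
                     covariates = character(0))
  t0 <- f0$tidy[f0$tidy$term == "x", ]
  expect_lt(abs(t0$estimate), 3 * t0$se)
  # alternative: true log OR 0.5
  y1 <- rbinom(n, 1, plogis(-1 + 0.5 * x))
  f1 <- fit_logistic(tibble::tibble(y = y1, x = x), "y", "x",
                     covariates = character(0))
  t1 <- f1$tidy[f1$tidy$term == "x", ]
  expect_lt(abs(t1$estimate - 0.5), 3 * t1$se)
})

test_that("quartile coding uses Q1 as referent and reports a trend p", {
  set.seed(43)
  n <- 4000
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * x))
  fit <- fit_logistic(tibble::tibble(y = y, x = x), "y", "x",
                      covariates = character(0), quartiles = TRUE)
  terms <- fit$tidy$term
  expect_false(any(terms == ".quartileQ1"))
  expect_true(all(c(".quartileQ2", ".quartileQ3", ".quartileQ4") %in% terms))
  expect_lt(fit$p_trend, 0.001)
  q4 <- fit$tidy[fit$tidy$term == ".quartileQ4", ]
  expect_gt(q4$or, 1)
})

test_that("degenerate logistic designs fail loudly", {
  dat <- tibble::tibble(y = rep(1, 50), x = rnorm(50))
  expect_error(fit_logistic(dat, "y", "x", covariates = character(0)),
               "both classes")
  dat2 <- tibble::tibble(y = rbinom(100, 1, 0.5), x = rnorm(100))
  dat2$x2 <- dat2$x * 2
  expect_error(fit_logistic(dat2, "y", "x", covariates = "x2"),
               "rank deficient|collinear")
  # perfectly separated exposure
  dat3 <- tibble::tibble(y = c(rep(0, 50), rep(1, 50)),
                         x = c(rnorm(50, -8), rnorm(50, 8)))
  expect_error(suppressWarnings(
    fit_logistic(dat3, "y", "x", covariates = character(0))),
    "separation")
})

test_that("Cox fits recover exponential rate ratios with Efron ties", {
  set.seed(47)
  n <- 2000
  lam <- 0.1
  grp <- rep(c(0, 1), each = n)
  tt <- c(rexp(n, lam), rexp(n, 2 * lam))
  dat <- tibble::tibble(time = tt, event = 1, x = grp)
  fit <- fit_cox(dat, "time", "event", "x", covariates = character(0))
  tx <- fit$tidy[fit$tidy$term == "x", ]
  expect_lt(abs(tx$estimate - log(2)), 3 * tx$se)

  # null exposure on exponential data
  set.seed(48)
  dat0 <- tibble::tibble(time = rexp(5000, 0.1), event = 1, x = rnorm(5000))
  f0 <- fit_cox(dat0, "time", "event", "x", covariates = character(0))
  t0 <- f0$tidy[f0$tidy$term == "x", ]
  expect_lt(abs(t0$estimate), 3 * t0$se)
})

test_that("a tiny Cox fit matches brute-force partial-likelihood search", {
  dat <- tibble::tibble(time = c(1, 2.2, 3.1, 4.7, 5.3, 6.9),
                        event = c(1, 1, 0, 1, 1, 1),
                        x = c(0.5, -1.2, 0.8, 1.9, -0.3, 0.1))
  fit <- fit_cox(dat, "time", "event", "x", covariates = character(0))
  b_hat <- fit$tidy$estimate[fit$tidy$term == "x"]
  # no ties: Cox partial likelihood by direct enumeration over a fine grid
  plik <- function(b) {
    ll <- 0
    for (i in which(dat$event == 1)) {
      risk <- dat$time >= dat$time[i]
      ll <- ll + b * dat$x[i] - log(sum(exp(b * dat$x[risk])))
    }
    ll
  }
  grid <- seq(b_hat - 0.5, b_hat + 0.5, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, plik, numeric(1)))]
  expect_lt(abs(b_hat - b_grid), 1e-3)
  expect_lt(abs(plik(b_hat) - max(vapply(grid, plik, numeric(1)))), 1e-6)
  expect_error(fit_cox(dplyr::mutate(dat, event = 0), "time", "event", "x",
                       covariates = character(0)), "no events")
})

test_that("the restricted cubic spline basis matches the truncated-power form", {
  knots <- c(-1.2, 0.1, 0.9, 2.4)
  x <- seq(-3, 4, length.out = 500)
  B <- rcs_basis(x, knots)
  expect_equal(ncol(B), 3)
  O <- rcs_oracle(x, knots)
  expect_lt(max(abs(B - O)), 1e-12)
  # below the first knot only the linear term is alive
  left <- x < knots[1]
  expect_true(all(abs(B[left, -1]) == 0))
  # linear beyond the boundary knots: second differences vanish in both tails
  for (tail_idx in list(which(x < knots[1]), which(x > knots[4]))) {
    for (j in seq_len(ncol(B))) {
      d2 <- diff(diff(B[tail_idx, j]))
      expect_lt(max(abs(d2)), 1e-8)
    }
  }
  expect_error(rcs_basis(x, c(1, 1, 2)), "increasing")
})

test_that("spline basis is C2: no curvature jumps at the knots", {
  knots <- c(0, 1, 2.5, 4)
  h <- 1e-4
  x <- seq(-1, 5, by = h)
  B <- rcs_basis(x, knots)
  for (j in seq_len(ncol(B))) {
    d2 <- diff(B[, j], differences = 2) / h^2
    # a jump in the second derivative would appear as a spike of order 1/h
    expect_lt(max(abs(diff(d2))), 1e-2)
  }
})

test_that("dose-response curves recover a log-linear hazard and pin the referent", {
  set.seed(53)
  n <- 8000
  x <- rnorm(n)
  beta <- 0.35
  tt <- rexp(n, 0.05 * exp(beta * x))
  cens <- runif(n, 5, 40)
  dat <- tibble::tibble(time = pmin(tt, cens), event = as.integer(tt <= cens),
                        x = x)
  dr <- fit_dose_response(dat, "time", "event", "x",
                          covariates = character(0), reference = 0)
  cv <- dr$curve
  at_ref <- cv[which.min(abs(cv$x)), ]
  # curve within its own pointwise band of the truth on [-2, 2]
  inner <- cv[cv$x > -2 & cv$x < 2, ]
  truth <- exp(beta * inner$x)
  cover <- mean(truth >= inner$ci_low & truth <= inner$ci_high)
  expect_gt(cover, 0.90)
  # exact reference normalization
  drx <- fit_dose_response(dat, "time", "event", "x",
                           covariates = character(0), reference = 0,
                           grid = c(-1, 0, 1))
  expect_equal(drx$curve$hr[drx$curve$x == 0], 1)
  expect_equal(drx$curve$se[drx$curve$x == 0], 0)
})

test_that("dose-response is equivariant under affine exposure rescaling", {
  set.seed(54)
  n <- 3000
  x <- rnorm(n, 0, 2)
  tt <- rexp(n, 0.05 * exp(0.2 * x))
  dat <- tibble::tibble(time = tt, event = 1, x = x, x_sd = x / 2)
  knots <- rcs_knots(x, 4)
  d1 <- fit_dose_response(dat, "time", "event", "x",
                          covariates = character(0), knots = knots,
                          reference = 0, grid = c(-2, -1, 1, 2))
  d2 <- fit_dose_response(dat, "time", "event", "x_sd",
                          covariates = character(0), knots = knots / 2,
                          reference = 0, grid = c(-1, -0.5, 0.5, 1))
  expect_lt(max(abs(d1$curve$loghr - d2$curve$loghr)), 1e-8)
  # out-of-range grid points are dropped with a warning
  expect_warning(
    fit_dose_response(dat, "time", "event", "x", covariates = character(0),
                      reference = 0, grid = c(0, 1, 99)),
    "outside")
})

test_that("model fits pool across imputations via Rubin's rules", {
  set.seed(59)
  n <- 1500
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 + 0.5 * x))
  mk <- function() tibble::tibble(y = y, x = x + rnorm(n, 0, 0.05))
  imp <- list(mk(), mk(), mk())
  pooled <- fit_pooled(imp, fit_logistic, outcome = "y", exposure = "x",
                       covariates = character(0))
  row <- pooled[pooled$term == "x", ]
  expect_gt(row$between_var, 0)
  expect_equal(row$total_var,
               row$within_var + (1 + 1 / 3) * row$between_var)
  expect_lt(abs(row$point - 0.5), 4 * sqrt(row$total_var))
})
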