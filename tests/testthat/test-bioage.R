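make_kdm_params <- function(q, k, s, s_ba, sexes = c("female", "male"),
                            biomarkers = paste0("bm", seq_along(q))) {
  coefs <- dplyr::bind_rows(lapply(sexes, function(sx) {
    tibble::tibble(sex = sx, biomarker = biomarkers, q = q, k = k, s = s,
                   flagged = FALSE)
  }))
  structure(list(coefficients = coefs,
                 s_ba = setNames(rep(s_ba, length(sexes)), sexes),
                 age_range = c(30, 80), biomarkers = biomarkers,
                 age_col = "chronological_age", sex_col = "sex"),
            class = "kdm_parameters")
}

test_that("KDM training recovers known regression parameters", {
  set.seed(5)
  n <- 6000
  age <- runif(n, 40, 70)
  sex <- sample(c("female", "male"), n, TRUE)
  truth <- list(q = c(100, 4), k = c(0.8, -0.03), s = c(9, 0.5))
  dat <- tibble::tibble(
    chronological_age = age, sex = sex,
    bm1 = truth$q[1] + truth$k[1] * age + rnorm(n, 0, truth$s[1]),
    bm2 = truth$q[2] + truth$k[2] * age + rnorm(n, 0, truth$s[2]))
  fit <- fit_kdm(dat, biomarkers = c("bm1", "bm2"))
  for (sx in c("female", "male")) {
    cf <- fit$coefficients[fit$coefficients$sex == sx, ]
    nsx <- sum(sex == sx)
    for (j in 1:2) {
      se_k <- truth$s[j] / (sd(age) * sqrt(nsx))
      expect_lt(abs(cf$k[j] - truth$k[j]), 3 * se_k)
      expect_lt(abs(cf$s[j] - truth$s[j]), 3 * truth$s[j] / sqrt(2 * nsx) + 0.02)
    }
  }
})

test_that("noiseless biomarkers are recovered exactly and flagged degenerate", {
  age <- seq(40, 70, length.out = 300)
  dat <- tibble::tibble(chronological_age = rep(age, 2),
                        sex = rep(c("female", "male"), each = 300),
                        bm1 = 10 + 0.5 * rep(age, 2))
  expect_warning(fit <- fit_kdm(dat, biomarkers = "bm1", min_n = 100),
                 "degenerate")
  cf <- fit$coefficients
  expect_lt(max(abs(cf$q - 10)), 1e-8)
  expect_lt(max(abs(cf$k - 0.5)), 1e-8)
  expect_true(all(cf$flagged))
})

test_that("uninformative biomarkers yield a near-zero age weight with warning", {
  set.seed(8)
  n <- 2000
  dat <- tibble::tibble(chronological_age = runif(n, 40, 70),
                        sex = sample(c("female", "male"), n, TRUE),
                        bm1 = rnorm(n), bm2 = rnorm(n))
  expect_warning(fit <- fit_kdm(dat, biomarkers = c("bm1", "bm2")), "s_BA")
  expect_lt(max(fit$s_ba), 1)
})

test_that("KDM score matches the direct weighted-mean formula", {
  set.seed(11)
  for (rep in 1:200) {
    p <- 9
    q <- runif(p, 1, 100); k <- runif(p, -1, 1) * 2
    k[abs(k) < 0.05] <- 0.1
    s <- runif(p, 0.5, 10); s_ba <- runif(1, 3, 15)
    ca <- runif(1, 35, 75)
    x <- q + k * ca + rnorm(p, 0, s)
    params <- make_kdm_params(q, k, s, s_ba)
    dat <- tibble::as_tibble(as.list(setNames(x, paste0("bm", 1:p))))
    dat$chronological_age <- ca; dat$sex <- "female"
    got <- compute_kdm(dat, params)$kdm_ba
    want <- kdm_oracle(x, q, k, s, ca, s_ba)
    expect_lt(abs(got - want) / max(1, abs(want)), 1e-10)
  }
})

test_that("a participant on every regression line scores chronological age", {
  params <- make_kdm_params(q = 20, k = 0.7, s = 3, s_ba = 8,
                            biomarkers = "bm1")
  dat <- tibble::tibble(bm1 = 20 + 0.7 * 50, chronological_age = 50,
                        sex = "male")
  expect_equal(compute_kdm(dat, params)$kdm_ba, 50)
})

test_that("a huge chronological-age variance limit inverts the biomarker", {
  q <- 15; k <- 0.6; s <- 2; ca <- 57; x <- 48
  params <- make_kdm_params(q, k, s, s_ba = 1e9, biomarkers = "bm1")
  dat <- tibble::tibble(bm1 = x, chronological_age = ca, sex = "female")
  got <- compute_kdm(dat, params)$kdm_ba
  expect_lt(abs(got - (x - q) / k), 1e-4)
})

test_that("missing biomarkers withhold the KDM score with a reason", {
  params <- make_kdm_params(c(10, 20), c(0.5, 0.8), c(2, 3), 8)
  dat <- tibble::tibble(bm1 = c(40, NA), bm2 = c(60, 61),
                        chronological_age = c(55, 60),
                        sex = c("female", "female"))
  out <- compute_kdm(dat, params)
  expect_false(is.na(out$kdm_ba[1]))
  expect_true(is.na(out$kdm_ba[2]))
  expect_match(out$kdm_reason[2], "bm1")
  dat$bm1[2] <- Inf
  expect_error(compute_kdm(dat, params), "non-finite")
})

test_that("the phenotypic-age identity point returns the printed constant", {
  coeffs <- phenoage_coefficients()
  # xb at which the outer log argument equals one
  c_gomp <- (exp(coeffs$horizon_months * coeffs$gamma) - 1) / coeffs$gamma
  xb_star <- log((1 / -coeffs$outer_scale) / c_gomp)
  got <- agepath:::phenoage_from_xb(xb_star, coeffs)
  expect_equal(got, 141.50225, tolerance = 1e-12)
})

test_that("phenotypic age matches the step-by-step oracle on random panels", {
  coeffs <- phenoage_coefficients()
  w <- coeffs$weights
  set.seed(23)
  for (rep in 1:200) {
    dat <- tibble::tibble(
      chronological_age = runif(1, 35, 75),
      albumin = runif(1, 35, 52), creatinine = runif(1, 45, 120),
      glucose = runif(1, 3.5, 9), crp = exp(rnorm(1, -2, 1)),
      lymph_pct = runif(1, 10, 45), mcv = runif(1, 75, 100),
      rdw = runif(1, 11.5, 16.5), alp = runif(1, 40, 140),
      wbc = runif(1, 3.5, 11))
    got <- compute_phenoage(dat, coeffs)$phenoage
    xb <- w$weight[w$marker == "intercept"]
    for (mk in setdiff(w$marker, "intercept")) {
      v <- dat[[mk]]
      if (w$transform[w$marker == mk] == "log") v <- log(v)
      xb <- xb + w$weight[w$marker == mk] * v
    }
    want <- phenoage_oracle(xb)
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("phenotypic age is monotone in xb and guards the lower boundary", {
  coeffs <- phenoage_coefficients()
  xbs <- seq(-12, 0, length.out = 40)
  pa <- agepath:::phenoage_from_xb(xbs, coeffs)
  expect_true(all(diff(pa) > 0))
  expect_error(agepath:::phenoage_from_xb(-Inf, coeffs), "risk")
})

test_that("missing phenotypic-age markers withhold with a reason", {
  coeffs <- phenoage_coefficients()
  dat <- tibble::tibble(
    chronological_age = 60, albumin = NA_real_, creatinine = 80,
    glucose = 5, crp = 1, lymph_pct = 30, mcv = 85, rdw = 13,
    alp = 80, wbc = 6.5)
  out <- compute_phenoage(dat, coeffs)
  expect_true(is.na(out$phenoage))
  expect_match(out$phenoage_reason, "albumin")
  dat$crp <- -1; dat$albumin <- 45
  expect_error(compute_phenoage(dat, coeffs), "positive")
})

test_that("acceleration residuals behave like intercepted OLS residuals", {
  # biological age equal to chronological age: all residuals zero
  ca <- c(40, 50, 55, 62, 70)
  r0 <- acceleration_residuals(ca, ca)
  expect_equal(r0$residual, rep(0, 5))
  # a constant shift is absorbed by the intercept
  r1 <- acceleration_residuals(ca + 7, ca)
  expect_equal(r1$residual, rep(0, 5))
  # hand dataset matches the normal equations to 1e-12
  ba <- c(44, 47, 60, 59, 75)
  r2 <- acceleration_residuals(ba, ca)
  expect_lt(max(abs(r2$residual - ols_residuals_oracle(ba, ca))), 1e-12)
  # residuals are orthogonal to chronological age
  expect_lt(abs(cor(r2$residual, ca)), 1e-10)
  expect_equal(r2$accelerated, r2$residual > 0)
  expect_error(acceleration_residuals(ba, rep(50, 5)), "constant")
})

test_that("quartile assignment uses lower-closed empirical cutpoints", {
  expect_equal(as.character(assign_quartiles(1:8)),
               c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
  expect_warning(qq <- assign_quartiles(rep(3, 10)), "degenerate")
  expect_true(all(qq == "Q1"))
  expect_error(assign_quartiles(c(1, 2, 3)), "at least 4")
  set.seed(31)
  x <- runif(10000)
  tab <- table(assign_quartiles(x))
  se <- 3 * sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(tab - 2500) < se))
})

test_that("KDM scoring is invariant to biomarker unit rescaling after refit", {
  set.seed(17)
  n <- 3000
  age <- runif(n, 40, 70)
  sex <- sample(c("female", "male"), n, TRUE)
  dat <- tibble::tibble(
    chronological_age = age, sex = sex,
    bm1 = 30 + 0.6 * age + rnorm(n, 0, 5),
    bm2 = 200 - 1.1 * age + rnorm(n, 0, 20))
  f1 <- fit_kdm(dat, biomarkers = c("bm1", "bm2"))
  s1 <- compute_kdm(dat, f1)$kdm_ba
  dat2 <- dat
  dat2$bm1 <- dat$bm1 * 38.67      # arbitrary unit change
  dat2$bm2 <- dat$bm2 / 18
  f2 <- fit_kdm(dat2, biomarkers = c("bm1", "bm2"))
  s2 <- compute_kdm(dat2, f2)$kdm_ba
  expect_lt(max(abs(s1 - s2)), 1e-8)
})

test_that("extreme scores beyond 5 SD are flagged for exclusion", {
  x <- c(rnorm(500), 40)
  fl <- flag_extreme(x)
  expect_true(fl[501])
  expect_lt(mean(fl[1:500]), 0.01)
})
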