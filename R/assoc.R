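#' Default covariate adjustment set
#'
#' The adjustment list used throughout the association models: age, sex,
#' ethnicity, BMI category, smoking, alcohol, diet score, physical
#' activity, Townsend deprivation, household income, and the four air
#' pollutants.
#'
#' @return Character vector of column names.
#' @export
default_covariates <- function() {
  c("chronological_age", "sex", "ethnicity", "bmi_category", "smoking",
    "alcohol", "diet_score", "physical_activity", "townsend", "income",
    "no2", "nox", "pm25", "pm10")
}

term_table <- function(fit, conf_level = 0.95) {
  sm <- summary(fit)$coefficients
  est <- sm[, 1]
  # glm labels the column "Std. Error"; coxph uses "se(coef)" (its second
  # column is exp(coef), so positional indexing would be wrong)
  se_col <- intersect(c("Std. Error", "se(coef)"), colnames(sm))[1]
  se <- sm[, se_col]
  q <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * pnorm(-abs(est / se))
  tibble::tibble(term = rownames(sm), estimate = est, se = se,
                 ci_low = est - q * se, ci_high = est + q * se, p = p)
}

check_full_rank <- function(mm) {
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "agepath_rank_error")
  }
}

exposure_terms <- function(data, exposure, quartiles) {
  if (!quartiles) return(list(data = data, terms = exposure))
  qcol <- data[[exposure]]
  if (!is.factor(qcol)) qcol <- assign_quartiles(qcol)
  data$.quartile <- stats::relevel(factor(qcol, ordered = FALSE), ref = "Q1")
  data$.qtrend <- as.integer(factor(qcol, levels = paste0("Q", 1:4)))
  list(data = data, terms = ".quartile")
}

#' Cross-sectional logistic model for a multimorbidity outcome
#'
#' Maximum-likelihood logistic regression of a binary outcome on an
#' acceleration exposure, either continuous (per SD) or as quartile
#' indicators with Q1 as referent.  Quartile fits also report a p-for-trend
#' from a separate fit replacing the indicators with the ordinal quartile
#' score 1-4.
#'
#' @param data Analysis table.
#' @param outcome Binary outcome column (0/1 or logical).
#' @param exposure Exposure column (continuous, or quartile factor /
#'   numeric to be quartiled when `quartiles = TRUE`).
#' @param covariates Adjustment columns (default [default_covariates()]).
#' @param quartiles Code the exposure as quartile indicators.
#' @param conf_level Confidence level.
#' @return Object of class `assoc_fit` with elements `tidy` (term table
#'   with ORs), `n`, `events`, `vcov`, `p_trend` (quartile fits),
#'   `exposure_coding`.
#' @export
fit_logistic <- function(data, outcome, exposure,
                         covariates = default_covariates(),
                         quartiles = FALSE, conf_level = 0.95) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (length(unique(na.omit(y))) < 2) {
    abort("outcome must have both classes", class = "agepath_model_error")
  }
  ex <- exposure_terms(data, exposure, quartiles)
  dat <- droplevels(ex$data)
  dat$.y <- y
  fml <- reformulate(c(ex$terms, covariates), response = ".y")
  mm <- stats::model.matrix(fml, data = dat)
  check_full_rank(mm)
  fit <- glm(fml, data = dat, family = binomial())
  cf <- coef(fit)
  expo_terms <- grepl("^\\.quartile", names(cf)) |
    startsWith(names(cf), exposure)
  if (!fit$converged || any(abs(cf[expo_terms]) > 15, na.rm = TRUE)) {
    abort(paste("logistic fit suggests separation (diverging coefficient);",
                "consider coarser exposure coding or penalization"),
          class = "agepath_separation_error")
  }
  if (any(abs(cf[!expo_terms]) > 15, na.rm = TRUE)) {
    warn("an adjustment covariate coefficient diverges; its estimate is unreliable")
  }
  tt <- term_table(fit, conf_level) |>
    dplyr::mutate(or = exp(.data$estimate),
                  or_low = exp(.data$ci_low), or_high = exp(.data$ci_high))
  p_trend <- NA_real_
  if (quartiles) {
    fml_t <- reformulate(c(".qtrend", covariates), response = ".y")
    fit_t <- glm(fml_t, data = dat, family = binomial())
    sm <- summary(fit_t)$coefficients
    p_trend <- sm[".qtrend", 4]
  }
  out <- list(tidy = tt, n = nrow(stats::model.frame(fit)),
              events = sum(stats::model.frame(fit)$.y), vcov = vcov(fit),
              p_trend = p_trend, model = "logistic",
              exposure_coding = if (quartiles) "quartile" else "per_sd",
              exposure = exposure, glm_fit = fit)
  class(out) <- "assoc_fit"
  out
}

#' Cox proportional hazards model for incident outcomes and mortality
#'
#' Partial-likelihood maximization with Efron tie handling via
#' \code{survival::coxph}, with the same exposure codings as
#' [fit_logistic()].  Fits can be run within baseline-state strata by
#' subsetting `data` beforehand.
#'
#' @param data Analysis table.
#' @param time,event Follow-up time (> 0) and event indicator columns.
#' @param exposure,covariates,quartiles,conf_level See [fit_logistic()].
#' @return An `assoc_fit` with hazard ratios.
#' @export
fit_cox <- function(data, time, event, exposure,
                    covariates = default_covariates(),
                    quartiles = FALSE, conf_level = 0.95) {
  if (any(data[[time]] <= 0, na.rm = TRUE)) {
    abort("follow-up times must be > 0")
  }
  if (sum(data[[event]], na.rm = TRUE) < 1) {
    abort("no events; cannot fit a Cox model",
          class = "agepath_model_error")
  }
  ex <- exposure_terms(data, exposure, quartiles)
  dat <- droplevels(ex$data)
  dat$.time <- dat[[time]]; dat$.event <- as.integer(dat[[event]])
  fml <- reformulate(c(ex$terms, covariates),
                     response = "survival::Surv(.time, .event)")
  mm <- stats::model.matrix(reformulate(c(ex$terms, covariates)), data = dat)
  check_full_rank(mm)
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  cf <- coef(fit)
  expo_terms <- grepl("^\\.quartile", names(cf)) |
    startsWith(names(cf), exposure)
  if (any(abs(cf[expo_terms]) > 15, na.rm = TRUE)) {
    abort("Cox fit suggests a diverging exposure coefficient",
          class = "agepath_separation_error")
  }
  if (any(abs(cf[!expo_terms]) > 15, na.rm = TRUE)) {
    warn("an adjustment covariate coefficient diverges; its estimate is unreliable")
  }
  tt <- term_table(fit, conf_level) |>
    dplyr::mutate(hr = exp(.data$estimate),
                  hr_low = exp(.data$ci_low), hr_high = exp(.data$ci_high))
  p_trend <- NA_real_
  if (quartiles) {
    fml_t <- reformulate(c(".qtrend", covariates),
                         response = "survival::Surv(.time, .event)")
    fit_t <- survival::coxph(fml_t, data = dat, ties = "efron")
    sm <- summary(fit_t)$coefficients
    p_trend <- sm[".qtrend", 5]
  }
  out <- list(tidy = tt, n = fit$n, events = fit$nevent, vcov = vcov(fit),
              p_trend = p_trend, model = "cox",
              exposure_coding = if (quartiles) "quartile" else "per_sd",
              exposure = exposure, cox_fit = fit)
  class(out) <- "assoc_fit"
  out
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s exposure): n = %d, events = %d\n", x$model,
              x$exposure_coding, x$n, x$events))
  print(x$tidy, n = Inf)
  if (!is.na(x$p_trend)) cat("p for trend:", format.pval(x$p_trend), "\n")
  invisible(x)
}

#' @export
tidy.assoc_fit <- function(x, ...) x$tidy

#' @export
glance.assoc_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n = x$n, events = x$events,
                 exposure_coding = x$exposure_coding, p_trend = x$p_trend)
}

#' Fit a model on each imputed dataset and pool by Rubin's rules
#'
#' Runs `fitter` on every completed dataset and pools each term's log-scale
#' estimate via [pool_rubin()], so pooled ORs/HRs are exponentials of the
#' pooled log estimates.
#'
#' @param imputed An `imputed_cohort` list from [impute_cohort()], or any
#'   list of data frames.
#' @param fitter A function `function(data, ...)` returning an `assoc_fit`
#'   (e.g. [fit_logistic()], [fit_cox()]).
#' @param ... Passed to `fitter`.
#' @return Tibble with one row per term: pooled `estimate`, Rubin variance
#'   components, `ratio` (= exp(estimate)), CI bounds on the ratio scale.
#' @export
fit_pooled <- function(imputed, fitter, ...) {
  fits <- lapply(imputed, function(d) fitter(d, ...))
  terms <- fits[[1]]$tidy$term
  rows <- lapply(terms, function(tm) {
    est <- vapply(fits, function(f) f$tidy$estimate[f$tidy$term == tm],
                  numeric(1))
    va <- vapply(fits, function(f) f$tidy$se[f$tidy$term == tm]^2, numeric(1))
    pooled <- pool_rubin(est, va)
    tibble::tibble(term = tm, pooled,
                   ratio = exp(pooled$point),
                   ratio_low = exp(pooled$ci_low),
                   ratio_high = exp(pooled$ci_high))
  })
  dplyr::bind_rows(rows)
}

#' Restricted cubic spline basis (Harrell form)
#'
#' Columns: the linear term, then `k - 2` combinations of truncated cubics
#' that are linear beyond the boundary knots, each normalized by
#' `(t_k - t_1)^2`.  The basis is continuous with continuous first and
#' second derivatives at the knots.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing knot vector, length >= 3.
#' @return Matrix with `length(knots) - 1` columns.
#' @export
#' @examples
#' rcs_basis(seq(0, 10, 0.5), knots = c(2, 5, 8))
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) abort("need at least 3 knots")
  if (any(diff(knots) <= 0)) abort("knots must be strictly increasing")
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm2 <- (tk - t1)^2
  cub <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (cub(x - tj) -
       cub(x - tk1) * (tk - tj) / (tk - tk1) +
       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / norm2
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- c("linear", paste0("nl", seq_len(k - 2)))
  out
}

#' Conventional RCS knot placement
#'
#' Quantile-based default placement: 10/50/90 percentiles for 3 knots,
#' 5/35/65/95 for 4, 5/27.5/50/72.5/95 for 5.
#'
#' @param x Exposure values.
#' @param k Number of knots (3-5).
#' @return Numeric knot vector.
#' @export
rcs_knots <- function(x, k = 4) {
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  abort("k must be 3, 4 or 5"))
  quantile(x, probs, na.rm = TRUE, names = FALSE)
}

#' Dose-response curve from a spline Cox fit
#'
#' Fits a Cox model with the exposure entering through a restricted cubic
#' spline, then evaluates `HR(x) = exp(eta(x) - eta(ref))` over a grid,
#' with pointwise delta-method CIs from the spline-coefficient covariance.
#' `HR(ref) = 1` exactly.
#'
#' @param data Analysis table.
#' @param time,event Survival columns (as in [fit_cox()]).
#' @param exposure Continuous exposure column.
#' @param covariates Adjustment columns.
#' @param knots Knot vector (default [rcs_knots()] with 4 knots).
#' @param reference Reference exposure value (default 0, the
#'   accelerated/non-accelerated boundary); must lie in the observed range.
#' @param grid Evaluation grid (default 101 points over the observed
#'   range); points outside the observed range are dropped with a warning.
#' @param conf_level Confidence level.
#' @return Object of class `dose_response`: `curve` tibble (`x`, `loghr`,
#'   `se`, `hr`, `ci_low`, `ci_high`), `knots`, `reference`, and the
#'   underlying `coxph` fit.
#' @export
fit_dose_response <- function(data, time, event, exposure,
                              covariates = default_covariates(),
                              knots = NULL, reference = 0, grid = NULL,
                              conf_level = 0.95) {
  x <- data[[exposure]]
  knots <- knots %||% rcs_knots(x, 4)
  rng <- range(x, na.rm = TRUE)
  if (reference < rng[1] || reference > rng[2]) {
    abort("reference value outside the observed exposure range")
  }
  if (is.null(grid)) grid <- seq(rng[1], rng[2], length.out = 101)
  outside <- grid < rng[1] | grid > rng[2]
  if (any(outside)) {
    warn(sprintf("%d grid point(s) outside the observed range dropped",
                 sum(outside)))
    grid <- grid[!outside]
  }
  B <- rcs_basis(x, knots)
  bn <- paste0(".rcs", seq_len(ncol(B)))
  dat <- droplevels(data)
  dat[bn] <- as.data.frame(B)
  dat$.time <- dat[[time]]; dat$.event <- as.integer(dat[[event]])
  fml <- reformulate(c(bn, covariates),
                     response = "survival::Surv(.time, .event)")
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  Bg <- rcs_basis(grid, knots)
  Br <- rcs_basis(reference, knots)
  D <- sweep(Bg, 2, drop(Br))          # basis differences vs reference
  beta <- coef(fit)[bn]
  V <- vcov(fit)[bn, bn]
  loghr <- drop(D %*% beta)
  se <- sqrt(pmax(rowSums((D %*% V) * D), 0))
  q <- qnorm(1 - (1 - conf_level) / 2)
  curve <- tibble::tibble(x = grid, loghr = loghr, se = se,
                          hr = exp(loghr),
                          ci_low = exp(loghr - q * se),
                          ci_high = exp(loghr + q * se))
  out <- list(curve = curve, knots = knots, reference = reference,
              exposure = exposure, cox_fit = fit)
  class(out) <- "dose_response"
  out
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Dose-response curve for", x$exposure, "with knots at",
      paste(sprintf("%.3g", x$knots), collapse = ", "), "\n")
  print(x$curve)
  invisible(x)
}

#' @export
tidy.dose_response <- function(x, ...) x$curve
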