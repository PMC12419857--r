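#' Biomarker sets for the two biological-age scores
#'
#' `kdm_biomarkers()` lists the nine markers entering the Klemera-Doubal
#' score (cardiovascular, pulmonary, metabolic, inflammatory, hepatic and
#' renal function); `phenoage_biomarkers()` the nine markers (plus
#' chronological age) entering the phenotypic-age score.
#'
#' @return Character vector of column names.
#' @export
kdm_biomarkers <- function() {
  c("sbp", "fev1", "cholesterol", "hba1c", "urea", "crp", "alp",
    "albumin", "creatinine")
}

#' @rdname kdm_biomarkers
#' @export
phenoage_biomarkers <- function() {
  c("albumin", "creatinine", "glucose", "crp", "lymph_pct", "mcv",
    "rdw", "alp", "wbc")
}

#' Train Klemera-Doubal parameters on a reference cohort
#'
#' For each sex stratum and biomarker, fits the simple regression
#' `biomarker ~ q + k * age` and records the intercept `q`, slope `k` and
#' residual root mean square error `s`.  (Note the convention: `q` is the
#' intercept and `k` the age slope, the standard Klemera-Doubal
#' parameterization.)  The chronological-age weight `s_BA` is the square
#' root of the variance in chronological age explained by the full biomarker
#' set, `sqrt(R^2 * Var(age))`, from a multiple regression of age on all
#' biomarkers within the stratum; an override can be supplied at scoring
#' time for users who prefer the fuller Klemera-Doubal variance correction.
#'
#' Biomarkers whose residual scale is numerically zero or whose
#' slope-to-noise ratio `|k|/s` falls below `ratio_floor` are flagged: a
#' vanishing `|k|/s` removes the marker's weight from the score, and a
#' vanishing `s` makes its weight explode.
#'
#' @param data Training table with chronological age, sex and the biomarker
#'   columns (complete cases are used per stratum).
#' @param biomarkers Biomarker columns (default [kdm_biomarkers()]).
#' @param age_col,sex_col Column names for age and sex.
#' @param min_n Minimum complete rows per sex stratum.
#' @param ratio_floor Floor on `|k|/s` below which a marker is flagged.
#' @param s_floor Floor on `s` below which a marker is flagged degenerate.
#' @return An object of class `kdm_parameters`: a list with `coefficients`
#'   (tibble: sex, biomarker, q, k, s, flagged), `s_ba` (named per sex) and
#'   `age_range`.
#' @export
fit_kdm <- function(data, biomarkers = kdm_biomarkers(),
                    age_col = "chronological_age", sex_col = "sex",
                    min_n = 100, ratio_floor = 1e-4, s_floor = 1e-8) {
  missing_cols <- setdiff(c(biomarkers, age_col, sex_col), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  sexes <- sort(unique(data[[sex_col]]))
  coefs <- list(); s_ba <- setNames(numeric(length(sexes)), sexes)
  for (sx in sexes) {
    sub <- data[data[[sex_col]] == sx, c(age_col, biomarkers)]
    sub <- sub[complete.cases(sub), ]
    if (nrow(sub) < min_n) {
      abort(sprintf("only %d complete rows for sex '%s' (min_n = %d)",
                    nrow(sub), sx, min_n), class = "agepath_training_error")
    }
    age <- sub[[age_col]]
    if (sd(age) == 0) abort("chronological age has zero variance")
    rows <- lapply(biomarkers, function(bm) {
      x <- sub[[bm]]
      if (sd(x) == 0) {
        abort(sprintf("biomarker %s has zero variance in sex '%s'", bm, sx),
              class = "agepath_training_error")
      }
      f <- lm(x ~ age)
      s <- sqrt(sum(residuals(f)^2) / f$df.residual)
      k <- unname(coef(f)[2])
      tibble::tibble(sex = sx, biomarker = bm,
                     q = unname(coef(f)[1]), k = k, s = s,
                     flagged = s < s_floor ||
                       abs(k) / max(s, s_floor) < ratio_floor)
    })
    coefs[[sx]] <- dplyr::bind_rows(rows)
    fit_age <- lm(reformulate(biomarkers, response = age_col), data = sub)
    r2 <- summary(fit_age)$r.squared
    s_ba[sx] <- sqrt(r2 * stats::var(age))
    if (s_ba[sx] < 0.5) {
      warn(sprintf(
        "s_BA = %.3g years for sex '%s': biomarkers explain almost no age variance; chronological age will dominate the score",
        s_ba[sx], sx))
    }
  }
  coefs <- dplyr::bind_rows(coefs)
  if (any(coefs$flagged)) {
    warn(paste0("degenerate KDM biomarker(s) flagged: ",
                paste(unique(coefs$biomarker[coefs$flagged]), collapse = ", ")))
  }
  structure(list(coefficients = coefs, s_ba = s_ba,
                 age_range = range(data[[age_col]], na.rm = TRUE),
                 biomarkers = biomarkers,
                 age_col = age_col, sex_col = sex_col),
            class = "kdm_parameters")
}

#' @export
print.kdm_parameters <- function(x, ...) {
  cat("Klemera-Doubal parameters:", length(x$biomarkers), "biomarkers,",
      "s_BA =", paste(sprintf("%s %.2f", names(x$s_ba), x$s_ba),
                      collapse = ", "), "years\n")
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Compute Klemera-Doubal biological age
#'
#' The score is the inverse-variance-weighted combination of each
#' biomarker's implied age and chronological age:
#' \deqn{KDM = \frac{\sum_i (x_i - q_i) k_i / s_i^2 + CA / s_{BA}^2}
#'                  {\sum_i (k_i / s_i)^2 + 1 / s_{BA}^2}}
#' A participant whose biomarkers all sit exactly on their age-regression
#' lines scores exactly their chronological age.  Participants missing any
#' biomarker are not scored (no within-score imputation); the reason is
#' recorded in `kdm_reason`.
#'
#' @param data Cohort table with biomarkers, age and sex.
#' @param params A [fit_kdm()] object.
#' @param s_ba_override Optional numeric overriding the trained `s_BA`
#'   (same value for all sexes).
#' @return `data` with columns `kdm_ba` (years; `NA` when withheld) and
#'   `kdm_reason` (`NA` when scored).
#' @export
compute_kdm <- function(data, params, s_ba_override = NULL) {
  stopifnot(inherits(params, "kdm_parameters"))
  bms <- params$biomarkers
  age <- data[[params$age_col]]
  sex <- data[[params$sex_col]]
  bad_finite <- vapply(bms, function(bm) any(is.infinite(data[[bm]])),
                       logical(1))
  if (any(bad_finite)) {
    abort(paste0("non-finite biomarker values in: ",
                 paste(bms[bad_finite], collapse = ", ")))
  }
  kdm <- rep(NA_real_, nrow(data))
  reason <- rep(NA_character_, nrow(data))
  for (sx in unique(sex)) {
    cf <- params$coefficients[params$coefficients$sex == sx, ]
    if (nrow(cf) == 0) {
      reason[sex == sx] <- paste0("no parameters for sex '", sx, "'")
      next
    }
    sba <- s_ba_override %||% params$s_ba[[sx]]
    idx <- which(sex == sx)
    xs <- as.matrix(data[idx, cf$biomarker])
    miss <- is.na(xs)
    num <- sweep(xs, 2, cf$q, "-") %*% (cf$k / cf$s^2) + age[idx] / sba^2
    den <- sum((cf$k / cf$s)^2) + 1 / sba^2
    val <- drop(num) / den
    has_miss <- rowSums(miss) > 0
    val[has_miss] <- NA_real_
    kdm[idx] <- val
    reason[idx[has_miss]] <- vapply(which(has_miss), function(i) {
      paste0("missing biomarker: ",
             paste(cf$biomarker[miss[i, ]], collapse = ", "))
    }, character(1))
  }
  data$kdm_ba <- kdm
  data$kdm_reason <- reason
  data
}

#' Packaged phenotypic-age coefficients
#'
#' Reads the versioned coefficient file shipped with the package (or a user
#' file in the same CSV layout: marker, transform, unit, weight) and
#' attaches the Gompertz constants of the phenotypic-age definition: the
#' per-month mortality-hazard slope `gamma`, the 120-month prediction
#' horizon, and the outer constants mapping 10-year mortality risk to an
#' age in years.
#'
#' @param file CSV path; default the packaged file.
#' @param gamma,horizon_months,outer_const,outer_scale,outer_slope Gompertz
#'   constants; defaults are the published values (gamma = 0.0076927,
#'   horizon 120 months, 141.50225, -0.00553, 0.090165).
#' @return A list of class `phenoage_coefficients`.
#' @export
phenoage_coefficients <- function(file = NULL, gamma = 0.0076927,
                                  horizon_months = 120,
                                  outer_const = 141.50225,
                                  outer_scale = -0.00553,
                                  outer_slope = 0.090165) {
  file <- file %||% system.file("extdata", "phenoage_coefficients.csv",
                                package = "agepath")
  tab <- utils::read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("marker", "transform", "weight") %in% names(tab)),
            gamma > 0, horizon_months > 0)
  need <- c("intercept", "chronological_age", phenoage_biomarkers())
  absent <- setdiff(need, tab$marker)
  if (length(absent) > 0) {
    abort(paste0("coefficient file lacks weights for: ",
                 paste(absent, collapse = ", ")))
  }
  structure(list(weights = tibble::as_tibble(tab), gamma = gamma,
                 horizon_months = horizon_months, outer_const = outer_const,
                 outer_scale = outer_scale, outer_slope = outer_slope),
            class = "phenoage_coefficients")
}

phenoage_from_xb <- function(xb, coeffs) {
  # u = -ln(1 - risk) = exp(xb) * (exp(120 gamma) - 1) / gamma.  The outer
  # log argument is -outer_scale * u; evaluating through u keeps it exact
  # even where the 120-month risk itself rounds to 1 in double precision
  # (risk = -expm1(-u) is returned for reference, not used in the age).
  u <- exp(xb) * (exp(coeffs$horizon_months * coeffs$gamma) - 1) /
    coeffs$gamma
  bad <- !is.na(u) & (u <= 0 | !is.finite(u))
  if (any(bad)) {
    abort(sprintf(
      "mortality risk numerically 0 or 1 for %d row(s) (extreme xb, e.g. %.3g); cannot map to an age",
      sum(bad), xb[which(bad)[1]]), class = "agepath_phenoage_error")
  }
  coeffs$outer_const + log(-coeffs$outer_scale * u) / coeffs$outer_slope
}

#' Compute phenotypic age
#'
#' Builds the linear predictor `xb` from the weighted (log-transformed where
#' specified) markers plus chronological age, converts it to a 120-month
#' mortality risk under the Gompertz form
#' `risk = 1 - exp(-exp(xb) * (exp(120 * gamma) - 1) / gamma)`, and maps the
#' risk to the age at which the reference population reaches it:
#' `141.50225 + ln(-0.00553 * ln(1 - risk)) / 0.090165`.  Markers must be in
#' the coefficients' training units (see [harmonize_units()]).  Rows missing
#' any marker are withheld with a reason; a risk that is numerically 0 or 1
#' is an error, not a silent infinity.
#'
#' @param data Cohort table.
#' @param coeffs A [phenoage_coefficients()] object.
#' @param age_col Chronological-age column.
#' @return `data` with `phenoage` (years) and `phenoage_reason` columns.
#' @export
compute_phenoage <- function(data, coeffs = phenoage_coefficients(),
                             age_col = "chronological_age") {
  stopifnot(inherits(coeffs, "phenoage_coefficients"))
  w <- coeffs$weights
  markers <- setdiff(w$marker, "intercept")
  cols <- ifelse(markers == "chronological_age", age_col, markers)
  absent <- setdiff(cols, names(data))
  if (length(absent) > 0) {
    abort(paste0("missing marker column(s): ", paste(absent, collapse = ", ")))
  }
  xb <- rep(w$weight[w$marker == "intercept"], nrow(data))
  miss <- matrix(FALSE, nrow(data), length(markers),
                 dimnames = list(NULL, markers))
  for (j in seq_along(markers)) {
    x <- data[[cols[j]]]
    tr <- w$transform[w$marker == markers[j]]
    if (identical(tr, "log")) {
      if (any(x <= 0, na.rm = TRUE)) {
        abort(sprintf("marker %s must be positive for log transform",
                      markers[j]))
      }
      x <- log(x)
    }
    miss[, j] <- is.na(x)
    xb <- xb + w$weight[w$marker == markers[j]] * ifelse(is.na(x), 0, x)
  }
  has_miss <- rowSums(miss) > 0
  xb[has_miss] <- NA_real_
  pa <- rep(NA_real_, nrow(data))
  if (any(!has_miss)) pa[!has_miss] <- phenoage_from_xb(xb[!has_miss], coeffs)
  data$phenoage <- pa
  data$phenoage_reason <- ifelse(
    has_miss,
    apply(miss, 1, function(m) if (any(m))
      paste0("missing marker: ", paste(markers[m], collapse = ", "))
      else NA_character_),
    NA_character_)
  data
}

#' Aging-acceleration residuals
#'
#' Acceleration is the residual from an ordinary least-squares regression of
#' biological age on chronological age (with intercept): positive residuals
#' mark participants biologically older than peers of the same chronological
#' age.  Residuals sum to zero and are uncorrelated with chronological age
#' by construction.  Also returned is the SD-standardized residual used as
#' the per-SD exposure in the association models.
#'
#' @param biological_age,chronological_age Numeric vectors (equal length,
#'   `NA`s allowed in `biological_age`; those rows get `NA` residuals).
#' @return Tibble: `residual` (years), `accel_sd` (SD units), `accelerated`
#'   (residual > 0).
#' @export
#' @examples
#' acceleration_residuals(c(50, 60, 72), c(50, 60, 70))
acceleration_residuals <- function(biological_age, chronological_age) {
  if (length(biological_age) != length(chronological_age)) {
    abort("biological and chronological age vectors differ in length")
  }
  ok <- !is.na(biological_age) & !is.na(chronological_age)
  if (sum(ok) < 3) abort("need at least 3 complete pairs")
  if (sd(chronological_age[ok]) == 0) {
    abort("chronological age is constant; residuals undefined",
          class = "agepath_acceleration_error")
  }
  res <- rep(NA_real_, length(biological_age))
  f <- lm(biological_age[ok] ~ chronological_age[ok])
  res[ok] <- residuals(f)
  s <- sd(res[ok])
  tibble::tibble(residual = res,
                 accel_sd = if (s > 0) res / s else res,
                 accelerated = res > 0)
}

#' Add acceleration columns for one biological-age metric
#'
#' @param data Table containing the biological-age and chronological-age
#'   columns.
#' @param ba_col Biological-age column name (e.g. `"kdm_ba"`).
#' @param age_col Chronological-age column.
#' @param prefix Prefix for the new columns (default `ba_col`).
#' @param stratify_by_sex Fit the residual regression within sex strata
#'   (default `FALSE`, pooled).
#' @param sex_col Sex column (used when stratifying).
#' @return `data` plus `<prefix>_accel`, `<prefix>_accel_sd`,
#'   `<prefix>_accelerated`.
#' @export
compute_acceleration <- function(data, ba_col, age_col = "chronological_age",
                                 prefix = ba_col, stratify_by_sex = FALSE,
                                 sex_col = "sex") {
  if (stratify_by_sex) {
    res <- rep(NA_real_, nrow(data)); asd <- res; acc <- rep(NA, nrow(data))
    for (sx in unique(data[[sex_col]])) {
      idx <- which(data[[sex_col]] == sx)
      r <- acceleration_residuals(data[[ba_col]][idx], data[[age_col]][idx])
      res[idx] <- r$residual; asd[idx] <- r$accel_sd; acc[idx] <- r$accelerated
    }
  } else {
    r <- acceleration_residuals(data[[ba_col]], data[[age_col]])
    res <- r$residual; asd <- r$accel_sd; acc <- r$accelerated
  }
  data[[paste0(prefix, "_accel")]] <- res
  data[[paste0(prefix, "_accel_sd")]] <- asd
  data[[paste0(prefix, "_accelerated")]] <- acc
  data
}

#' Assign empirical quartiles
#'
#' Cutpoints at the 25/50/75 empirical percentiles; values tied with a
#' cutpoint fall in the lower quartile.  Q1 is the referent in downstream
#' models.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @return Factor with levels Q1-Q4 (`NA` preserved).
#' @export
#' @examples
#' assign_quartiles(1:8)
assign_quartiles <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 4) abort("need at least 4 finite values for quartiles")
  qs <- quantile(values[ok], c(0.25, 0.5, 0.75), names = FALSE)
  if (qs[1] == qs[3]) {
    warn("degenerate quartiles: cutpoints coincide; all values in Q1")
  }
  lab <- rep(NA_character_, length(values))
  lev <- 1L + (values[ok] > qs[1]) + (values[ok] > qs[2]) + (values[ok] > qs[3])
  lab[ok] <- paste0("Q", lev)
  factor(lab, levels = paste0("Q", 1:4))
}

#' Flag extreme biological-age scores
#'
#' Scores more than `k` standard deviations from the cohort mean are flagged
#' for exclusion before any modeling.
#'
#' @param values Numeric vector.
#' @param k SD multiple (default 5).
#' @return Logical vector (`TRUE` = extreme; `NA` stays `NA`).
#' @export
flag_extreme <- function(values, k = 5) {
  m <- mean(values, na.rm = TRUE); s <- sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) return(rep(FALSE, length(values)) & !is.na(values))
  abs(values - m) > k * s
}

#' Score a cohort on both biological-age metrics
#'
#' Convenience wrapper: trains KDM parameters on the cohort itself
#' (sex-stratified), computes both scores, pooled acceleration residuals,
#' accelerated flags, quartiles, and 5-SD extreme-score flags.
#'
#' @param data Harmonized cohort table.
#' @param kdm_params Optional pre-trained [fit_kdm()] object (default:
#'   train on `data`).
#' @param coeffs [phenoage_coefficients()] to use.
#' @param extreme_sd SD multiple for the extreme-score flag.
#' @return `data` with `kdm_ba`, `phenoage`, per-metric `_accel`,
#'   `_accel_sd`, `_accelerated`, `_quartile` and `_extreme` columns.
#' @export
score_cohort <- function(data, kdm_params = NULL,
                         coeffs = phenoage_coefficients(), extreme_sd = 5) {
  kdm_params <- kdm_params %||% fit_kdm(data)
  data <- compute_kdm(data, kdm_params)
  data <- compute_phenoage(data, coeffs)
  for (metric in c("kdm_ba", "phenoage")) {
    data <- compute_acceleration(data, metric)
    data[[paste0(metric, "_quartile")]] <-
      assign_quartiles(data[[paste0(metric, "_accel")]])
    data[[paste0(metric, "_extreme")]] <- flag_extreme(data[[metric]],
                                                       k = extreme_sd)
  }
  data
}
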