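#' Build a unit map for biomarker harmonization
#'
#' Each entry is an affine transform `y = scale * x + shift`, optionally
#' followed by a natural log, taking a cohort-native column into the units
#' the scoring coefficients were trained in.
#'
#' @param ... Named entries, each a list with elements `scale` (default 1),
#'   `shift` (default 0) and `log` (default `FALSE`).
#' @param columns For [identity_unit_map()], the biomarker columns to cover.
#' @return A named list of class `unit_map`.
#' @export
#' @examples
#' um <- unit_map(albumin = list(scale = 10))  # g/dL -> g/L
unit_map <- function(...) {
  entries <- list(...)
  entries <- lapply(entries, function(e) {
    list(scale = e$scale %||% 1, shift = e$shift %||% 0,
         log = isTRUE(e$log))
  })
  structure(entries, class = c("unit_map", "list"))
}

#' @rdname unit_map
#' @export
identity_unit_map <- function(columns) {
  do.call(unit_map, setNames(lapply(columns, function(x) list()), columns))
}

#' Harmonize biomarker units
#'
#' Applies the affine (+ optional log) transform of `map` to every biomarker
#' column, producing values in the training units of downstream scoring
#' coefficients.  Every column in `columns` must be covered by the map; the
#' applied transforms are recorded in the `"unit_provenance"` attribute so
#' the operation is invertible via [invert_units()].
#'
#' @param table A cohort data frame.
#' @param map A [unit_map()].
#' @param columns Biomarker columns that must be harmonized (default: every
#'   column named in the map).
#' @return The table with transformed columns.
#' @export
harmonize_units <- function(table, map, columns = names(map)) {
  uncovered <- setdiff(columns, names(map))
  if (length(uncovered) > 0) {
    abort(paste0("unit map does not cover biomarker column(s): ",
                 paste(uncovered, collapse = ", ")),
          class = "agepath_unit_error")
  }
  absent <- setdiff(columns, names(table))
  if (length(absent) > 0) {
    abort(paste0("biomarker column(s) absent from table: ",
                 paste(absent, collapse = ", ")), class = "agepath_unit_error")
  }
  for (nm in columns) {
    e <- map[[nm]]
    x <- e$scale * table[[nm]] + e$shift
    if (e$log) x <- log(x)
    table[[nm]] <- x
  }
  attr(table, "unit_provenance") <- map[columns]
  table
}

#' @rdname harmonize_units
#' @export
invert_units <- function(table, map = attr(table, "unit_provenance")) {
  if (is.null(map)) abort("no unit provenance found; pass `map` explicitly")
  for (nm in names(map)) {
    e <- map[[nm]]
    x <- table[[nm]]
    if (e$log) x <- exp(x)
    table[[nm]] <- (x - e$shift) / e$scale
  }
  attr(table, "unit_provenance") <- NULL
  table
}

#' Specify a multiple-imputation run
#'
#' Three strategies are supported, one per column: `"ordered_logistic"`
#' (proportional-odds fit on observed data, categories drawn from predicted
#' probabilities), `"multivariate_normal_bounded"` (regression-based
#' conditional normal draws with posterior parameter draws, rejected at the
#' plausibility bounds and clamped after a capped number of retries) and
#' `"mean_substitution"` (deterministic, identical across imputations).
#'
#' @param m Number of completed datasets (default 20).
#' @param strategies Named character vector/list: column -> strategy.
#' @param bounds Named list of `c(low, high)` plausibility bounds for
#'   bounded-normal columns.
#' @param predictors Columns used as predictors in the model-based
#'   strategies (default: age, sex and the Townsend index); missing
#'   predictor cells are filled with the column mean for prediction only.
#' @param seed Integer seed.
#' @return A list of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 20,
                            strategies,
                            bounds = list(),
                            predictors = c("chronological_age", "sex"),
                            seed = 1L) {
  if (m < 2) abort("m must be >= 2", class = "agepath_imputation_error")
  strategies <- unlist(strategies)
  ok <- c("ordered_logistic", "multivariate_normal_bounded", "mean_substitution")
  if (!all(strategies %in% ok)) {
    abort(paste0("unknown strategy: ",
                 paste(setdiff(strategies, ok), collapse = ", ")))
  }
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || b[1] >= b[2]) {
      abort(sprintf("bounds for %s must be (low, high) with low < high", nm))
    }
  }
  structure(list(m = as.integer(m), strategies = strategies,
                 bounds = bounds, predictors = predictors,
                 seed = as.integer(seed)),
            class = c("imputation_spec", "list"))
}

predictor_matrix <- function(table, predictors) {
  cols <- lapply(predictors, function(nm) {
    x <- table[[nm]]
    if (is.numeric(x)) {
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      matrix(x, ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(x)
      lev <- levels(f)
      f[is.na(f)] <- lev[which.max(tabulate(f))]
      mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(nm, lev[-1])
      mm
    }
  })
  do.call(cbind, cols)
}

impute_mean <- function(x) {
  x[is.na(x)] <- mean(x, na.rm = TRUE)
  x
}

# posterior-style draw of (sigma, beta) then conditional normal draws,
# rejection sampling at the bounds with clamping after `max_retry` rounds
impute_bounded_normal <- function(x, X, bounds, max_retry = 100) {
  obs <- !is.na(x)
  fit <- stats::lm.fit(cbind(1, X[obs, , drop = FALSE]), x[obs])
  dfres <- sum(obs) - length(fit$coefficients)
  if (dfres < 2) abort("too few observed rows for bounded-normal imputation")
  s2 <- sum(fit$residuals^2) / dfres
  sigma2 <- s2 * dfres / rchisq(1, dfres)
  XtX <- crossprod(cbind(1, X[obs, , drop = FALSE]))
  beta <- fit$coefficients +
    drop(t(chol(sigma2 * solve(XtX))) %*% rnorm(length(fit$coefficients)))
  mu <- drop(cbind(1, X) %*% beta)
  miss <- which(!obs)
  draw <- rnorm(length(miss), mu[miss], sqrt(sigma2))
  if (!is.null(bounds)) {
    lo <- bounds[1]; hi <- bounds[2]
    for (r in seq_len(max_retry)) {
      bad <- draw < lo | draw > hi
      if (!any(bad)) break
      draw[bad] <- rnorm(sum(bad), mu[miss][bad], sqrt(sigma2))
    }
    draw <- pmin(pmax(draw, lo), hi)
  }
  x[miss] <- draw
  x
}

impute_ordered_logistic <- function(x, X) {
  obs <- !is.na(x)
  f <- factor(x, ordered = TRUE)
  if (nlevels(droplevels(f[obs])) < 2) {
    abort("ordered-logistic imputation needs >= 2 observed levels")
  }
  dat <- data.frame(.y = droplevels(f[obs]), X[obs, , drop = FALSE])
  miss <- which(!obs)
  newd <- data.frame(X[miss, , drop = FALSE])
  if (nlevels(dat$.y) == 2) {
    # two observed levels: proportional odds reduces to plain logistic
    lev2 <- levels(dat$.y)
    fit <- glm(.y ~ ., data = dat, family = binomial())
    p2 <- predict(fit, newdata = newd, type = "response")
    drawn <- lev2[1 + rbinom(length(miss), 1, p2)]
  } else {
    fit <- MASS::polr(.y ~ ., data = dat, Hess = FALSE)
    pr <- predict(fit, newdata = newd, type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
    lev <- colnames(pr)
    drawn <- apply(pr, 1, function(p) sample(lev, 1, prob = p))
  }
  x[miss] <- drawn
  x
}

#' Multiply impute missing covariates
#'
#' Produces `spec$m` completed copies of the table, one strategy per column.
#' Observed cells are never altered; mean-substitution columns are identical
#' across imputations while the stochastic strategies vary.
#'
#' @param table A cohort data frame.
#' @param spec An [imputation_spec()].
#' @return A list of `m` completed tibbles, class `imputed_cohort`, with the
#'   spec attached as an attribute.
#' @export
impute_cohort <- function(table, spec) {
  stopifnot(inherits(spec, "imputation_spec"))
  for (nm in names(spec$strategies)) {
    if (!nm %in% names(table)) abort(sprintf("column %s not in table", nm))
    if (all(is.na(table[[nm]]))) {
      abort(sprintf("column %s has no observed values", nm),
            class = "agepath_imputation_error")
    }
    b <- spec$bounds[[nm]]
    if (!is.null(b)) {
      x <- table[[nm]]
      if (!any(x >= b[1] & x <= b[2], na.rm = TRUE)) {
        abort(sprintf("bounds for %s exclude all observed mass", nm),
              class = "agepath_imputation_error")
      }
    }
  }
  preds <- setdiff(spec$predictors, names(spec$strategies))
  X <- predictor_matrix(table, preds)
  set.seed(spec$seed)
  out <- vector("list", spec$m)
  for (i in seq_len(spec$m)) {
    tbl <- table
    for (nm in names(spec$strategies)) {
      strat <- spec$strategies[[nm]]
      x <- tbl[[nm]]
      if (!anyNA(x)) next
      tbl[[nm]] <- switch(
        strat,
        mean_substitution = impute_mean(x),
        multivariate_normal_bounded =
          impute_bounded_normal(x, X, spec$bounds[[nm]]),
        ordered_logistic = {
          was_factor <- is.factor(x)
          filled <- impute_ordered_logistic(x, X)
          if (was_factor) factor(filled, levels = levels(x),
                                 ordered = is.ordered(x)) else filled
        }
      )
    }
    out[[i]] <- tbl
  }
  structure(out, class = c("imputed_cohort", "list"), spec = spec)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Point estimate is the mean across imputations; within-imputation variance
#' the mean of the variances; between-imputation variance the sample
#' variance of the estimates; total variance
#' `within + (1 + 1/m) * between`.  Degrees of freedom use the small-sample
#' formula `(m - 1) * (1 + within / ((1 + 1/m) * between))^2`; when the
#' between variance is zero the reference distribution is normal
#' (`df = Inf`).  Ratio measures (ORs, HRs) must be pooled on the log scale
#' by the caller.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Numeric vector of per-imputation squared standard errors.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `point`, `within_var`, `between_var`, `total_var`,
#'   `df`, `ci_low`, `ci_high`.
#' @export
#' @examples
#' pool_rubin(c(1, 2, 3), c(1, 1, 1))
pool_rubin <- function(estimates, variances, conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) abort("need at least 2 imputations to pool",
                   class = "agepath_pooling_error")
  if (length(variances) != m) abort("estimates and variances differ in length")
  if (!all(is.finite(estimates)) || !all(is.finite(variances)) ||
      any(variances < 0)) {
    abort("estimates must be finite and variances finite and >= 0")
  }
  point <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  if (between > 0) {
    df <- (m - 1) * (1 + within / ((1 + 1 / m) * between))^2
    q <- qt(1 - (1 - conf_level) / 2, df)
  } else {
    df <- Inf
    q <- qnorm(1 - (1 - conf_level) / 2)
  }
  tibble::tibble(point = point, within_var = within, between_var = between,
                 total_var = total, df = df,
                 ci_low = point - q * sqrt(total),
                 ci_high = point + q * sqrt(total))
}
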