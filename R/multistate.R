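#' Transition structure of the progressive illness-death model
#'
#' Allowed transitions: none -> single -> dual -> triple for disorder
#' accumulation, and a death exit from each diseased state.  There is no
#' direct none -> death edge (such observations are excluded when building
#' the panel), death is absorbing, and the generator is upper triangular
#' under the state order none, single, dual, triple, death.
#'
#' @return Tibble with columns `edge`, `from`, `to`, `label`.
#' @export
#' @examples
#' transition_structure()
transition_structure <- function() {
  tr <- allowed_transitions()
  tr$label <- paste(.state_levels[tr$from], "->", .state_levels[tr$to])
  tr
}

#' Construct a proportional-intensity model
#'
#' Off-diagonal intensities on the allowed edges are
#' `q_rs(z) = exp(log_q0_rs + beta_rs . z)`; rows of the generator sum to
#' zero.
#'
#' @param log_q0 Named numeric vector of baseline log intensities (per
#'   year), names matching `structure$edge`.
#' @param beta Optional matrix of per-transition covariate log hazard
#'   ratios (rows = edges, columns = covariates); defaults to none.
#' @param covariates Covariate names (columns of `beta`).
#' @param structure Transition structure (default [transition_structure()]).
#' @param vcov Optional parameter covariance (from a fit).
#' @return Object of class `intensity_model`.
#' @export
intensity_model <- function(log_q0, beta = NULL, covariates = colnames(beta),
                            structure = transition_structure(), vcov = NULL) {
  if (!setequal(names(log_q0), structure$edge)) {
    abort("log_q0 must be named by the allowed transition edges")
  }
  log_q0 <- log_q0[structure$edge]
  if (!all(is.finite(log_q0))) abort("non-finite baseline log intensity")
  if (is.null(beta)) {
    beta <- matrix(0, nrow(structure), 0,
                   dimnames = list(structure$edge, NULL))
  }
  if (is.null(dim(beta)) || nrow(beta) != nrow(structure)) {
    abort("beta must have one row per allowed transition")
  }
  rownames(beta) <- structure$edge
  colnames(beta) <- covariates
  obj <- list(log_q0 = log_q0, beta = beta,
              covariates = covariates %||% character(0),
              structure = structure, vcov = vcov)
  class(obj) <- "intensity_model"
  obj
}

#' Generator matrix at a covariate value
#'
#' @param model An [intensity_model()].
#' @param z Named covariate vector (may be empty).
#' @return The 5x5 generator `Q(z)` (rows sum to zero).
#' @export
generator_matrix <- function(model, z = NULL) {
  st <- model$structure
  S <- 5L
  C <- ncol(model$beta)
  zz <- numeric(C)
  if (C > 0) {
    if (is.null(z)) abort("model has covariates; supply z")
    zz <- as.numeric(z[colnames(model$beta)])
    if (anyNA(zz)) abort("z lacks some model covariates")
  }
  lq <- model$log_q0 + if (C > 0) drop(model$beta %*% zz) else 0
  if (!all(is.finite(lq))) abort("non-finite intensity")
  Q <- matrix(0, S, S, dimnames = list(.state_levels, .state_levels))
  for (e in seq_len(nrow(st))) {
    q <- exp(lq[e])
    Q[st$from[e], st$to[e]] <- Q[st$from[e], st$to[e]] + q
    Q[st$from[e], st$from[e]] <- Q[st$from[e], st$from[e]] - q
  }
  Q
}

#' Interval transition probabilities
#'
#' `P(dt | z) = exp(dt * Q(z))`, computed by uniformization (Poisson-
#' weighted series in the substochastic matrix `I + Q/q_max`, truncation
#' error below 1e-13, interval halving for large `q_max * dt`).  Rows sum
#' to one within 1e-10 and tiny negative entries are clamped to zero.
#'
#' @param model An [intensity_model()].
#' @param z Named covariate vector.
#' @param dt Interval length in years (>= 0).
#' @return 5x5 stochastic matrix.
#' @export
transition_probability <- function(model, z = NULL, dt) {
  if (dt < 0) abort("dt must be >= 0")
  Q <- generator_matrix(model, z)
  P <- cpp_ctmc_expm(unname(Q), dt)
  dimnames(P) <- dimnames(Q)
  P
}

# panel data marshalling shared by panel_loglik and fit_multistate
prepare_panel <- function(panel, covariate_data, covariates) {
  need <- c("id", "time", "state", "exact_death")
  absent <- setdiff(need, names(panel))
  if (length(absent) > 0) {
    abort(paste0("panel lacks column(s): ", paste(absent, collapse = ", ")))
  }
  panel <- dplyr::arrange(panel, .data$id, .data$time)
  ids <- unique(panel$id)
  counts <- table(factor(panel$id, levels = ids))
  keep <- names(counts)[counts >= 2]
  panel <- panel[panel$id %in% keep, ]
  ids <- unique(panel$id)
  offsets <- c(0L, cumsum(as.integer(table(factor(panel$id, levels = ids)))))
  X <- matrix(0, length(ids), length(covariates),
              dimnames = list(NULL, covariates))
  if (length(covariates) > 0) {
    if (is.null(covariate_data)) abort("covariates named but no covariate_data")
    cd <- covariate_data[match(ids, covariate_data$id), , drop = FALSE]
    for (j in seq_along(covariates)) {
      x <- cd[[covariates[j]]]
      if (is.null(x)) abort(sprintf("covariate %s not in covariate_data",
                                    covariates[j]))
      if (anyNA(x)) abort(sprintf("covariate %s has missing values",
                                  covariates[j]))
      X[, j] <- as.numeric(x)
    }
  }
  list(ids = ids, state = as.integer(panel$state), time = panel$time,
       exact = as.integer(panel$exact_death), offsets = offsets, X = X,
       panel = panel)
}

#' Panel log-likelihood of an intensity model
#'
#' Sums, over consecutive observation pairs within participant,
#' `log P(dt)[s_prev, s_next]`; an exactly observed death at time `T`
#' contributes `log sum_s P(T - t_prev)[s_prev, s] * q_{s,death}(z)` over
#' transient states with a death edge.  Observed pairs that are impossible
#' under the transition graph give `-Inf`, with the offending participants
#' named in the `"infeasible_ids"` attribute.
#'
#' @param model An [intensity_model()].
#' @param panel Panel tibble from [make_panel()] (`id`, `time`, `state`,
#'   `exact_death`).
#' @param covariate_data One row per id with the model covariates.
#' @return Log-likelihood (scalar).
#' @export
panel_loglik <- function(model, panel, covariate_data = NULL) {
  pp <- prepare_panel(panel, covariate_data, colnames(model$beta))
  par <- c(model$log_q0, as.vector(t(model$beta)))
  st <- model$structure
  ll <- cpp_panel_loglik(par, st$from, st$to, 5L, pp$state, pp$time,
                         pp$exact, pp$offsets, pp$X)
  if (!is.finite(ll)) {
    by_int <- cpp_panel_loglik_by_interval(par, st$from, st$to, 5L, pp$state,
                                           pp$time, pp$exact, pp$offsets,
                                           pp$X)
    bad <- unique(pp$panel$id[!is.na(by_int) & by_int == -Inf])
    attr(ll, "infeasible_ids") <- bad
  }
  ll
}

crude_rates <- function(pp, structure) {
  E <- nrow(structure)
  count <- setNames(numeric(E), structure$edge)
  persontime <- numeric(5)
  n <- length(pp$state)
  for (i in seq_len(length(pp$offsets) - 1)) {
    for (j in (pp$offsets[i] + 1):(pp$offsets[i + 1] - 1)) {
      s0 <- pp$state[j]; s1 <- pp$state[j + 1]
      dt <- pp$time[j + 1] - pp$time[j]
      persontime[s0] <- persontime[s0] + dt
      if (s1 != s0) {
        if (s1 == 5L) {
          # attribute a death to the closest death edge on the implied path
          from <- max(s0, 2L)
          e <- which(structure$from == from & structure$to == 5L)
          count[e] <- count[e] + 1
        } else {
          # multi-level jumps credit every edge on the implied path
          for (s in s0:(s1 - 1)) {
            e <- which(structure$from == s & structure$to == s + 1L)
            count[e] <- count[e] + 1
          }
        }
      }
    }
  }
  list(count = count,
       rate = pmax(count, 0.5) / pmax(persontime[structure$from], 1e-8))
}

#' Fit the multistate model by maximum likelihood
#'
#' Quasi-Newton (BFGS) maximization of the interval-censored panel
#' log-likelihood over the baseline log intensities and per-transition
#' covariate log hazard ratios.  Standard errors come from the inverse of
#' the finite-difference observed information at the optimum.  The fit is
#' initialized at crude occurrence/exposure rates with zero covariate
#' effects, so it is deterministic given the data.
#'
#' @param panel Panel tibble from [make_panel()].
#' @param covariate_data One row per id holding the covariates (e.g. sex
#'   indicator, baseline age, acceleration in SD units).
#' @param covariates Character vector of covariate column names (applied to
#'   every transition).
#' @param structure Transition structure (default [transition_structure()]).
#' @param init Optional [intensity_model()] to initialize from.
#' @param control Passed to [stats::optim()] (defaults: BFGS, maxit 500,
#'   reltol 1e-10).
#' @return Object of class `multistate_fit`: the fitted `intensity_model`
#'   plus `loglik`, `vcov`, `convergence`, observed transition counts and
#'   the tidy coefficient table.
#' @export
fit_multistate <- function(panel, covariate_data = NULL,
                           covariates = character(0),
                           structure = transition_structure(), init = NULL,
                           control = list()) {
  pp <- prepare_panel(panel, covariate_data, covariates)
  E <- nrow(structure); C <- length(covariates)
  cr <- crude_rates(pp, structure)
  if (any(cr$count == 0)) {
    abort(paste0("transition(s) never observed, baseline unidentifiable: ",
                 paste(structure$edge[cr$count == 0], collapse = ", ")),
          class = "agepath_multistate_error")
  }
  par0 <- c(log(cr$rate), rep(0, E * C))
  if (!is.null(init)) {
    par0 <- c(init$log_q0[structure$edge], as.vector(t(init$beta)))
  }
  # likelihood and analytic gradient come from the same C++ pass; memoize so
  # optim's separate fn/gr calls at the same point cost one evaluation
  cache <- new.env(parent = emptyenv())
  evalp <- function(p) {
    if (!identical(cache$par, p)) {
      cache$val <- cpp_panel_loglik_grad(p, structure$from, structure$to, 5L,
                                         pp$state, pp$time, pp$exact,
                                         pp$offsets, pp$X)
      cache$par <- p
    }
    cache$val
  }
  negll <- function(p) {
    v <- evalp(p)$loglik
    if (!is.finite(v)) 1e10 else -v
  }
  neggr <- function(p) {
    v <- evalp(p)
    if (!is.finite(v$loglik)) numeric(length(p)) else -v$gradient
  }
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-12), control)
  opt <- optim(par0, negll, neggr, method = "BFGS", control = ctl)
  gnorm <- max(abs(neggr(opt$par)))
  if (opt$convergence != 0) {
    abort(sprintf("multistate fit did not converge (code %d, max |grad| %.3g)",
                  opt$convergence, gnorm), class = "agepath_multistate_error")
  }
  # observed information by central differences of the analytic gradient
  np <- length(opt$par)
  H <- matrix(0, np, np)
  h <- pmax(1e-5, 1e-5 * abs(opt$par))
  for (i in seq_len(np)) {
    e <- numeric(np); e[i] <- h[i]
    H[i, ] <- (neggr(opt$par + e) - neggr(opt$par - e)) / (2 * h[i])
  }
  H <- (H + t(H)) / 2
  vc <- tryCatch(solve(H), error = function(e) {
    warn("observed information is singular; using pseudo-inverse")
    MASS::ginv(H)
  })
  par <- opt$par
  log_q0 <- setNames(par[seq_len(E)], structure$edge)
  beta <- matrix(par[-seq_len(E)], E, C, byrow = TRUE,
                 dimnames = list(structure$edge, covariates))
  model <- intensity_model(log_q0, if (C > 0) beta else NULL, covariates,
                           structure, vcov = vc)
  out <- list(model = model, loglik = -opt$value, vcov = vc,
              convergence = opt$convergence, counts = cr$count,
              n = length(pp$ids), par = par, structure = structure,
              covariates = covariates)
  class(out) <- "multistate_fit"
  out
}

# central-difference gradient (only used for convergence diagnostics)
numDeriv_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

#' @export
print.multistate_fit <- function(x, ...) {
  cat("Multistate illness-death fit:", x$n, "participants, loglik",
      sprintf("%.2f", x$loglik), "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a multistate fit
#'
#' One row per parameter: baseline log intensities (`type = "intensity"`,
#' `estimate` on the log scale) and covariate effects (`type = "loghr"`)
#' with hazard ratios and delta-free Wald CIs on the log scale.
#'
#' @param x A `multistate_fit`.
#' @param conf_level Confidence level.
#' @param ... Unused.
#' @return Tibble: `transition`, `term`, `type`, `estimate`, `se`,
#'   `hr`, `ci_low`, `ci_high` (HR scale for covariate terms).
#' @export
tidy.multistate_fit <- function(x, conf_level = 0.95, ...) {
  st <- x$structure
  E <- nrow(st); C <- length(x$covariates)
  se <- sqrt(pmax(diag(x$vcov), 0))
  q <- qnorm(1 - (1 - conf_level) / 2)
  est_b <- x$par[seq_len(E)]; se_b <- se[seq_len(E)]
  base <- tibble::tibble(
    transition = st$label, term = "(baseline)", type = "intensity",
    estimate = est_b, se = se_b,
    hr = NA_real_,
    ci_low = exp(est_b - q * se_b),
    ci_high = exp(est_b + q * se_b))
  if (C == 0) return(base)
  idx <- E + seq_len(E * C)
  est_i <- x$par[idx]; se_i <- se[idx]
  eff <- tibble::tibble(
    transition = rep(st$label, each = C),
    term = rep(x$covariates, times = E), type = "loghr",
    estimate = est_i, se = se_i,
    hr = exp(est_i),
    ci_low = exp(est_i - q * se_i),
    ci_high = exp(est_i + q * se_i))
  dplyr::bind_rows(base, eff)
}

#' @rdname tidy.multistate_fit
#' @param x A `multistate_fit`.
#' @export
glance.multistate_fit <- function(x, ...) {
  tibble::tibble(n = x$n, logLik = x$loglik,
                 n_parameters = length(x$par),
                 AIC = 2 * length(x$par) - 2 * x$loglik,
                 convergence = x$convergence)
}
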