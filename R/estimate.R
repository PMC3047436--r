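#' Estimation configuration
#'
#' Bundles the tunables of the two-step estimation: parameter bounds, the
#' time-interval weight exponent, the initial-condition search window, the
#' per-species normalization mode and the optimizer/solver tolerances.
#'
#' @param lower,upper Parameter bounds (scalars, recycled; lower must be
#'   nonnegative). No fitted constant in the reference set exceeds 13, so the
#'   default upper bound of 100 is unrestrictive.
#' @param weight_exponent Exponent on the preceding time-interval length used
#'   to weight each time point's residual (default 1/4).
#' @param ic_window_sem Half-width of the initial-condition window in SEM
#'   units around the measured t = 0 value (default 2).
#' @param ic_window_frac Fractional fallback half-width when the t = 0 SEM is
#'   zero (default 0.2).
#' @param maxiter,ftol,ptol Levenberg-Marquardt controls for one refinement
#'   round.
#' @param epsfcn Assumed relative accuracy of the residuals, which sets the
#'   forward-difference Jacobian step to about sqrt(epsfcn). Must not be
#'   smaller than the ODE solver accuracy, or the Jacobian degenerates to
#'   solver noise.
#' @param restarts Maximum number of LM rounds; the optimizer is restarted
#'   from the previous solution (resetting its trust region) until the
#'   objective stops improving. Restarting works around stalls at active
#'   nonnegativity bounds.
#' @param sim_rtol,sim_atol ODE tolerances used inside the objective.
#' @param conditions Conditions fitted jointly.
#' @param normalize_rows Scale each step-1 regression row by the species'
#'   maximum measured concentration (recommended: concentrations span
#'   0.01-700 pmol/ug-DNA).
#' @param gene_delay Protein-synthesis delay (hours).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = 0, upper = 100, weight_exponent = 0.25,
                       ic_window_sem = 2, ic_window_frac = 0.2,
                       maxiter = 80, ftol = 1e-13, ptol = 1e-13,
                       epsfcn = 1e-6, restarts = 5,
                       sim_rtol = 1e-6, sim_atol = 1e-10,
                       conditions = c("control", "treatment"),
                       normalize_rows = TRUE, gene_delay = 3) {
  stopifnot(lower >= 0, upper > lower, weight_exponent >= 0)
  structure(list(lower = lower, upper = upper,
                 weight_exponent = weight_exponent,
                 ic_window_sem = ic_window_sem,
                 ic_window_frac = ic_window_frac,
                 maxiter = maxiter, ftol = ftol, ptol = ptol,
                 epsfcn = epsfcn, restarts = restarts,
                 sim_rtol = sim_rtol, sim_atol = sim_atol,
                 conditions = conditions, normalize_rows = normalize_rows,
                 gene_delay = gene_delay),
            class = "fit_config")
}

#' Backward-difference derivative estimates
#'
#' Discretizes a time-course as (x_k - x_{k-1}) / (t_k - t_{k-1}), with the
#' estimate assigned to the interval's right endpoint t_k.
#'
#' @param tc A [time_course()] with at least 2 points.
#' @return A data.frame with columns `time` (right endpoints) and `deriv`.
#' @export
finite_difference_derivatives <- function(tc) {
  stopifnot(inherits(tc, "time_course"))
  if (length(tc$times) < 2L) stop("need at least 2 time points")
  dt <- diff(tc$times)
  if (any(dt == 0)) stop("duplicate time points")
  data.frame(time = tc$times[-1L], deriv = diff(tc$values) / dt)
}

# joint per-species maxima of the measured dynamic courses (normalization
# constants M_i); zero-range species fall back to 1 to avoid division by 0
species_maxima <- function(network, dataset, conditions) {
  M <- vapply(network$dynamic, function(sp) {
    max(vapply(conditions,
               function(cc) max(get_course(dataset, sp, cc)$values), 0))
  }, 0)
  M[M <= 0] <- 1
  M
}

# per-time-point weights: (preceding interval length)^p; the first point
# borrows the first interval
time_weights <- function(times, exponent) {
  dt <- diff(times)
  c(dt[1L], dt)^exponent
}

# measured inputs (lipids + delayed gene folds) at one time point
measured_inputs <- function(network, dataset, condition, t, gene_delay = 3) {
  lip <- vapply(network$input_lipids, function(sp)
    interpolate_input(get_course(dataset, sp, condition), t), 0)
  gen <- if (condition == "control") {
    stats::setNames(rep(1, length(network$genes)), network$genes)
  } else {
    vapply(network$genes, function(sp)
      delayed_gene(get_course(dataset, sp, condition), t, gene_delay), 0)
  }
  c(lip, gen)
}

#' Build the stacked linear regression system Y = X b
#'
#' Discretizes the measured metabolite derivatives (backward differences,
#' assigned to each interval's right endpoint) and assembles the matching
#' design matrix from the per-parameter regressors evaluated at the measured
#' state and (delayed) inputs at that endpoint. Both conditions are stacked
#' when requested; control rows use gene folds of 1.
#'
#' @param network A `sphingo_network`.
#' @param dataset A [condition_dataset()].
#' @param conditions Conditions to stack (default both).
#' @param config A [fit_config()]; controls row normalization and the gene
#'   delay.
#' @return A list of class `regression_system`: `Y` (numeric vector), `X`
#'   (matrix with 29 named columns), `meta` (species/time/condition per row)
#'   and `scale` (the per-species normalization constants applied).
#' @export
build_regression_system <- function(network, dataset,
                                    conditions = c("control", "treatment"),
                                    config = fit_config()) {
  M <- species_maxima(network, dataset, conditions)
  rs <- if (config$normalize_rows) 1 / M else rep(1, length(M))
  Y <- numeric(0); Xr <- list(); meta <- list()
  for (cond in conditions) {
    times <- dataset$times[[cond]]
    if (length(times) < 2L) stop("condition '", cond, "' has < 2 time points")
    states <- course_matrix(dataset, network$dynamic, cond)  # 9 x nt
    derivs <- t(apply(states, 1L, diff)) / rep(diff(times),
                                               each = length(network$dynamic))
    dim(derivs) <- c(length(network$dynamic), length(times) - 1L)
    for (k in seq_along(times)[-1L]) {
      u <- measured_inputs(network, dataset, cond, times[k],
                           config$gene_delay)
      D <- design_block(network, states[, k], u)
      Y <- c(Y, derivs[, k - 1L] * rs)
      Xr[[length(Xr) + 1L]] <- D * rs
      meta[[length(meta) + 1L]] <- data.frame(
        species = network$dynamic, time = times[k], condition = cond)
    }
  }
  structure(list(Y = Y, X = do.call(rbind, Xr), meta = do.call(rbind, meta),
                 scale = rs),
            class = "regression_system")
}

#' Constrained linear least-squares estimate (step 1)
#'
#' Solves min ||Y - X b||^2 subject to b >= lower (nonnegativity) using the
#' Lawson-Hanson active-set algorithm, giving the deterministic initial
#' guess for the nonlinear refinement. Rank deficiency of X is reported as a
#' warning naming the parameters outside the pivoted column basis
#' (identifiability report).
#'
#' @param system A [build_regression_system()] result.
#' @param config A [fit_config()] (bounds).
#' @return Named parameter vector of length 29.
#' @export
linear_estimate <- function(system, config = fit_config()) {
  X <- system$X; Y <- system$Y
  # rank check on column-scaled X so the report reflects directions, not units
  cs <- apply(abs(X), 2L, max); cs[cs == 0] <- 1
  qrX <- qr(sweep(X, 2L, cs, "/"))
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning("design matrix is rank deficient (rank ", qrX$rank, " of ",
            ncol(X), "); weakly identified parameters: ",
            paste(dropped, collapse = ", "))
  }
  b <- pracma::lsqnonneg(X, Y)$x
  b <- pmin(pmax(b, config$lower), config$upper)
  stats::setNames(b, colnames(X))
}

## ---- nonlinear refinement (step 2) --------------------------------------

# fast inner simulation: reuses prebuilt input functions across calls
sim_states <- function(network, params, x0, ufun, times, rtol, atol) {
  deriv <- make_deriv(network, params, ufun)
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol))) return(NULL)
  unclass(sol)[, 1L + seq_along(x0), drop = FALSE]  # nt x 9
}

ic_bounds <- function(m, s, config) {
  half <- ifelse(s > 0, config$ic_window_sem * s,
                 config$ic_window_frac * abs(m))
  lo <- pmax(0, m - half)
  hi <- m + half + 1e-12
  list(lower = lo, upper = hi)
}

# residual machinery shared by refine_nonlinear and shared_parameter_fit;
# `expand` maps the optimizer's free parameter vector to the full 29
make_refiner <- function(network, dataset, config, n_free, expand) {
  conditions <- config$conditions
  np <- length(network$dynamic)
  times <- lapply(conditions, function(cc) dataset$times[[cc]])
  names(times) <- conditions
  obs <- lapply(conditions, function(cc)
    t(course_matrix(dataset, network$dynamic, cc)))  # nt x 9
  names(obs) <- conditions
  M <- species_maxima(network, dataset, conditions)
  w <- lapply(conditions, function(cc)
    time_weights(times[[cc]], config$weight_exponent))
  names(w) <- conditions
  ufun <- lapply(conditions, function(cc)
    input_function(network, dataset, cc, config$gene_delay))
  names(ufun) <- conditions

  x0_meas <- lapply(conditions, function(cc) obs[[cc]][1L, ])
  x0_sem <- lapply(conditions, function(cc)
    vapply(network$dynamic,
           function(sp) get_course(dataset, sp, cc)$sem[1L], 0))
  names(x0_meas) <- names(x0_sem) <- conditions

  n_res <- sum(vapply(conditions, function(cc) length(times[[cc]]), 0L)) * np
  resfun <- function(par) {
    b <- expand(par[seq_len(n_free)])
    out <- numeric(0)
    for (ci in seq_along(conditions)) {
      cc <- conditions[ci]
      x0 <- stats::setNames(
        par[n_free + (ci - 1L) * np + seq_len(np)], network$dynamic)
      st <- sim_states(network, b, x0, ufun[[cc]], times[[cc]],
                       config$sim_rtol, config$sim_atol)
      if (is.null(st)) return(rep(1e6, n_res))
      r <- sweep(st - obs[[cc]], 2L, M, "/") * w[[cc]]
      out <- c(out, as.vector(r))
    }
    out
  }
  list(resfun = resfun, conditions = conditions, np = np,
       x0_meas = x0_meas, x0_sem = x0_sem, M = M, obs = obs,
       times = times, w = w)
}

# LM with restarts: each nls.lm call stops when its own step/ftol criteria
# trigger (often prematurely at an active bound); restarting from the last
# iterate resets the trust region and recovers progress. Stops when the
# objective is at the solver-accuracy floor or no longer improves.
run_lm <- function(par, lower, upper, resfun, config) {
  prev <- Inf
  niter_total <- 0L
  for (round in seq_len(max(1L, config$restarts))) {
    fit <- minpack.lm::nls.lm(
      par = par, lower = lower, upper = upper, fn = resfun,
      control = minpack.lm::nls.lm.control(maxiter = config$maxiter,
                                           ftol = config$ftol,
                                           ptol = config$ptol,
                                           epsfcn = config$epsfcn))
    par <- fit$par
    niter_total <- niter_total + fit$niter
    if (fit$deviance < 1e-10 ||
        (is.finite(prev) && prev - fit$deviance < 1e-6 * prev)) break
    prev <- fit$deviance
  }
  fit$niter <- niter_total
  fit
}

finish_fit <- function(network, env, lm_fit, expand, n_free, start_objective) {
  conditions <- env$conditions; np <- env$np
  par <- lm_fit$par
  b <- expand(par[seq_len(n_free)])
  x0 <- lapply(seq_along(conditions), function(ci)
    stats::setNames(par[n_free + (ci - 1L) * np + seq_len(np)],
                    network$dynamic))
  names(x0) <- conditions
  res <- env$resfun(par)
  # per-species normalized RMS error across all conditions/time points;
  # each condition chunk is column-major over (time, species)
  chunks <- lapply(seq_along(conditions), function(ci) {
    nt <- length(env$times[[conditions[ci]]])
    off <- if (ci == 1L) 0L else sum(vapply(
      conditions[seq_len(ci - 1L)],
      function(cc) length(env$times[[cc]]), 0L)) * np
    matrix(res[off + seq_len(nt * np)], ncol = np)
  })
  rmat <- do.call(rbind, chunks)
  per_species <- stats::setNames(sqrt(colMeans(rmat^2)), network$dynamic)
  structure(list(params = b, x0 = x0, objective = sum(res^2),
                 start_objective = start_objective,
                 per_species_error = per_species,
                 convergence = list(info = lm_fit$info,
                                    message = lm_fit$message,
                                    niter = lm_fit$niter)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result: objective", signif(x$objective, 6),
      "(start", signif(x$start_objective, 6), "),",
      x$convergence$niter, "LM iterations\n")
  print(signif(x$params, 4))
  invisible(x)
}

#' Nonlinear refinement of the rate constants (step 2)
#'
#' Minimizes the weighted, per-species max-normalized squared error between
#' the measured and ODE-predicted concentrations, summed over conditions:
#' sum_c sum_i sum_j w_j^2 (yhat_ij - y_ij)^2 / M_i^2, where M_i is species
#' i's maximum measured value over the fitted conditions and w_j is the 1/4
#' power of the preceding time-interval length. Initial conditions are
#' co-optimized inside a window around the measured t = 0 values (+/- 2 SEM,
#' or +/- 20 percent when the SEM is zero); rate constants are bounded below
#' by zero. Bound-constrained Levenberg-Marquardt (deterministic, started
#' from step 1's estimate) does the minimization.
#'
#' @param network A `sphingo_network`.
#' @param dataset A [condition_dataset()].
#' @param start Named start vector of 29 rate constants (usually
#'   [linear_estimate()] output).
#' @param config A [fit_config()].
#' @return A `fit_result`: refined `params`, optimized `x0` per condition,
#'   final and starting `objective`, per-species normalized RMS errors and
#'   convergence diagnostics.
#' @export
refine_nonlinear <- function(network, dataset, start, config = fit_config()) {
  start <- check_params(network, start)
  if (any(start < config$lower - 1e-12) || any(start > config$upper + 1e-12))
    stop("start parameters outside bounds")
  n_free <- network$n_params
  expand <- function(p) stats::setNames(p, network$param_names)
  env <- make_refiner(network, dataset, config, n_free, expand)

  icb <- lapply(env$conditions, function(cc)
    ic_bounds(env$x0_meas[[cc]], env$x0_sem[[cc]], config))
  par0 <- c(start, unlist(lapply(env$conditions,
                                 function(cc) env$x0_meas[[cc]])))
  lower <- c(rep(config$lower, n_free), unlist(lapply(icb, `[[`, "lower")))
  upper <- c(rep(config$upper, n_free), unlist(lapply(icb, `[[`, "upper")))

  r0 <- env$resfun(par0)
  if (!all(is.finite(r0)) || sum(r0^2) >= 1e12)
    stop("objective is not finite at the starting point")
  fit <- run_lm(par0, lower, upper, env$resfun, config)
  finish_fit(network, env, fit, expand, n_free, sum(r0^2))
}

#' Two-step estimation pipeline
#'
#' Convenience wrapper running [build_regression_system()],
#' [linear_estimate()] and [refine_nonlinear()] in sequence.
#'
#' @inheritParams refine_nonlinear
#' @return A `fit_result` (see [refine_nonlinear()]).
#' @export
fit_rate_constants <- function(network, dataset, config = fit_config()) {
  sys <- build_regression_system(network, dataset, config$conditions, config)
  b0 <- linear_estimate(sys, config)
  refine_nonlinear(network, dataset, b0, config)
}

# enzyme pairs acting on both DHCer and Cer whose constants may be tied
SHARED_PAIRS <- list(c("kf7", "kf24"), c("kf13", "kf17"),
                     c("kf9", "kf19"), c("kb9", "kb19"),
                     c("kf10", "kf20"), c("kb10", "kb20"))

#' Shared-parameter refit
#'
#' Refits the model with selected parameter pairs tied to a single common
#' value. The eligible pairs are the reactions in which the same enzyme
#' (Ugcg, Cerk, Sms1, Sms2) acts on both the dihydro (DHCer) and desaturated
#' (Cer) substrate.
#'
#' @param network A `sphingo_network`.
#' @param dataset A [condition_dataset()].
#' @param pairs List of length-2 character vectors naming the tied pairs
#'   (subset of the eligible set).
#' @param start Full-length start vector (29); each tied pair starts from the
#'   mean of its two entries.
#' @param config A [fit_config()].
#' @return A `fit_result` whose `params` has the tied entries equal; the
#'   tie map is attached as attribute `ties`.
#' @export
shared_parameter_fit <- function(network, dataset, pairs, start,
                                 config = fit_config()) {
  start <- check_params(network, start)
  names(start) <- network$param_names
  for (p in pairs)
    if (!paste(sort(p), collapse = "+") %in%
        vapply(SHARED_PAIRS, function(q) paste(sort(q), collapse = "+"), ""))
      stop("not an eligible tied pair: ", paste(p, collapse = ", "))
  tied_second <- vapply(pairs, `[[`, "", 2L)
  free_names <- setdiff(network$param_names, tied_second)
  map <- match(network$param_names, free_names)
  for (p in pairs) map[match(p[2L], network$param_names)] <-
    match(p[1L], free_names)
  expand <- function(pfree) stats::setNames(pfree[map], network$param_names)

  start_free <- start[free_names]
  for (p in pairs) start_free[p[1L]] <- mean(start[p])
  n_free <- length(free_names)
  env <- make_refiner(network, dataset, config, n_free, expand)
  icb <- lapply(env$conditions, function(cc)
    ic_bounds(env$x0_meas[[cc]], env$x0_sem[[cc]], config))
  par0 <- c(start_free, unlist(lapply(env$conditions,
                                      function(cc) env$x0_meas[[cc]])))
  lower <- c(rep(config$lower, n_free), unlist(lapply(icb, `[[`, "lower")))
  upper <- c(rep(config$upper, n_free), unlist(lapply(icb, `[[`, "upper")))
  r0 <- env$resfun(par0)
  fit <- run_lm(par0, lower, upper, env$resfun, config)
  out <- finish_fit(network, env, fit, expand, n_free, sum(r0^2))
  attr(out, "ties") <- pairs
  out
}
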