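# Build a fast t -> c(lipids, delayed gene folds) function for one condition.
# Control gene folds are pinned to 1 regardless of stored courses.
input_function <- function(network, dataset, condition, gene_delay = 3,
                           freeze_at = NULL) {
  lipf <- lapply(network$input_lipids, function(sp) {
    tc <- get_course(dataset, sp, condition)
    if (!is.null(freeze_at)) {
      v <- interpolate_input(tc, freeze_at)
      function(t) v
    } else if (length(tc$times) == 1L) {
      v <- tc$values
      function(t) v
    } else stats::approxfun(tc$times, tc$values, rule = 2)
  })
  genf <- lapply(network$genes, function(sp) {
    if (condition == "control") return(function(t) 1)
    tc <- get_course(dataset, sp, condition)
    if (!is.null(freeze_at)) {
      v <- interpolate_input(tc, freeze_at - gene_delay)
      return(function(t) v)
    }
    f <- stats::approxfun(tc$times, tc$values, rule = 2)
    function(t) f(t - gene_delay)
  })
  nl <- length(lipf); ng <- length(genf)
  function(t) {
    u <- numeric(nl + ng)
    for (i in seq_len(nl)) u[i] <- lipf[[i]](t)
    for (i in seq_len(ng)) u[nl + i] <- genf[[i]](t)
    u
  }
}

# derivative function shared by simulate/steady-state; closure carries
# precomputed index tables and split kf/kb for speed
make_deriv <- function(network, params, ufun) {
  params <- check_params(network, params)
  kf <- params[match(network$fwd_param, network$param_names)]
  kb <- ifelse(is.na(network$bwd_param), 0,
               params[match(network$bwd_param, network$param_names)])
  fi1 <- network$fwd_idx[, 1L]; fi2 <- network$fwd_idx[, 2L]
  fi3 <- network$fwd_idx[, 3L]
  bi1 <- network$bwd_idx[, 1L]; bi2 <- network$bwd_idx[, 2L]
  bi3 <- network$bwd_idx[, 3L]
  irrev <- !network$reversible
  S <- network$S
  function(t, y, p) {
    z <- c(y, ufun(t), 1)
    v <- kf * (z[fi1] * z[fi2] * z[fi3])
    bp <- kb * (z[bi1] * z[bi2] * z[bi3])
    bp[irrev] <- 0
    list(as.vector(S %*% (v - bp)))
  }
}

#' Simulate the network ODEs under one condition
#'
#' Integrates dx/dt = rhs(x, u(t), params) with the input lipids linearly
#' interpolated from the dataset and gene folds applied with the 3-hr
#' protein delay. The control condition forces all gene folds to 1.
#'
#' @param network A `sphingo_network`.
#' @param params Rate constants (29, named or catalog order).
#' @param x0 Initial state (9, nonnegative).
#' @param dataset A [condition_dataset()] supplying the input courses.
#' @param condition `"control"` or `"treatment"`.
#' @param t_grid Output times (hours). Default: the dataset grid.
#' @param rtol,atol Solver tolerances.
#' @param method deSolve integration method (default `"lsoda"`, which
#'   switches automatically between nonstiff and stiff steppers).
#' @param gene_delay Protein-synthesis delay in hours (default 3).
#' @return A `trajectory` object: list with `times`, `state` (length(t_grid)
#'   x 9 matrix) and `condition`.
#' @export
simulate_network <- function(network, params, x0, dataset, condition,
                             t_grid = NULL, rtol = 1e-6, atol = 1e-10,
                             method = "lsoda", gene_delay = 3) {
  x0 <- check_state(network, x0)
  if (is.null(t_grid)) t_grid <- dataset$times[[condition]]
  ufun <- input_function(network, dataset, condition, gene_delay)
  deriv <- make_deriv(network, params, ufun)
  sol <- deSolve::ode(y = stats::setNames(x0, network$dynamic),
                      times = t_grid, func = deriv, parms = NULL,
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0 || any(!is.finite(sol)))
    stop("ODE solver failed near t = ",
         max(sol[stats::complete.cases(sol), "time"]), " hr")
  st <- unclass(sol)[, network$dynamic, drop = FALSE]
  if (min(st) < -1e-9)
    stop("trajectory went negative (min ", signif(min(st), 3), ") for ",
         network$dynamic[which(st == min(st), arr.ind = TRUE)[1L, 2L]])
  st[st < 0] <- 0
  structure(list(times = t_grid, state = st, condition = condition),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory (", x$condition, "): ", length(x$times), " times, ",
      ncol(x$state), " species\n", sep = "")
  invisible(x)
}

#' Control steady state
#'
#' Integrates the control condition for a long time with all inputs frozen
#' at their t = 0 control values (gene folds 1) and returns the final state.
#' Convergence is verified by requiring the residual derivative to satisfy
#' max|rhs| < tol * max(1, max|x|); otherwise a warning flags
#' non-convergence and the (best available) state is returned with attribute
#' `converged = FALSE`.
#'
#' @param network A `sphingo_network`.
#' @param params Rate constants.
#' @param dataset A [condition_dataset()] with a control condition.
#' @param x0 Starting state; defaults to the measured control t = 0 values.
#' @param t_end Integration horizon in hours (default 1000).
#' @param tol Convergence tolerance on the residual derivative (default 1e-8).
#' @return Named state vector with attributes `converged` and `rhs_norm`.
#' @export
steady_state <- function(network, params, dataset, x0 = NULL,
                         t_end = 1000, tol = 1e-8) {
  if (is.null(x0))
    x0 <- vapply(network$dynamic,
                 function(sp) get_course(dataset, sp, "control")$values[1L],
                 0)
  x0 <- check_state(network, x0)
  ufun <- input_function(network, dataset, "control", freeze_at = 0)
  deriv <- make_deriv(network, params, ufun)
  sol <- deSolve::ode(y = stats::setNames(x0, network$dynamic),
                      times = c(0, t_end), func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  xss <- pmax(unclass(sol)[nrow(sol), network$dynamic], 0)
  r <- deriv(t_end, xss, NULL)[[1L]]
  ok <- max(abs(r)) < tol * max(1, max(abs(xss)))
  if (!ok)
    warning("steady state not converged at t = ", t_end,
            " hr (max|rhs| = ", signif(max(abs(r)), 3), ")")
  structure(xss, converged = ok, rhs_norm = max(abs(r)))
}

#' Numerical Jacobian of the rhs in the state variables
#'
#' Central-difference differentiation of the mass-balance right-hand sides
#' with respect to the 9 state variables, with the inputs frozen at the
#' supplied values.
#'
#' @param network A `sphingo_network`.
#' @param params Rate constants.
#' @param state State vector at which to differentiate.
#' @param inputs Frozen input vector (4 lipids + 9 gene folds).
#' @param h_rel Relative step size (default 1e-6).
#' @return 9 x 9 matrix d rhs_j / d x_i.
#' @export
network_jacobian <- function(network, params, state, inputs, h_rel = 1e-6) {
  state <- check_state(network, state)
  n <- length(state)
  J <- matrix(0, n, n, dimnames = list(network$dynamic, network$dynamic))
  for (i in seq_len(n)) {
    h <- h_rel * max(abs(state[i]), 1)
    if (h == 0 || state[i] + h == state[i]) stop("step underflow for ",
                                                 network$dynamic[i])
    xp <- state; xp[i] <- state[i] + h
    xm <- state; xm[i] <- max(state[i] - h, 0)
    # keep the difference central unless the lower point was clipped at 0
    hh <- xp[i] - xm[i]
    J[, i] <- (network_rhs(network, xp, inputs, params) -
                 network_rhs(network, xm, inputs, params)) / hh
  }
  J
}
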