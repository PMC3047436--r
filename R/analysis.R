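#' One-at-a-time parametric sensitivity scan
#'
#' Simulates the treatment condition with one rate constant set to
#' ratio x its reference value and records, for every metabolite, the
#' fold-change of the trajectory maximum relative to the unperturbed
#' maximum. The local sensitivity (slope) is the central difference of the
#' fold-change with respect to the ratio at ratio 1, using a +/- 10 percent
#' step.
#'
#' @param network A `sphingo_network`.
#' @param params Reference rate constants.
#' @param dataset A [condition_dataset()] supplying inputs and the t = 0
#'   state.
#' @param param_name The rate constant to vary.
#' @param ratios Ratio grid (default 0.5, 2/3, 1, 1.5, 2 -- two-fold up and
#'   down).
#' @param condition Condition to simulate (default treatment).
#' @param t_grid Dense time grid on which trajectory maxima are taken
#'   (default 0-24 hr in 0.1 hr steps).
#' @return A list of class `sensitivity_result`: `param`, `ratios`,
#'   `fold_change` (ratio x metabolite matrix) and `slope` (per metabolite).
#' @export
sensitivity_scan <- function(network, params, dataset, param_name,
                             ratios = c(0.5, 2 / 3, 1, 1.5, 2),
                             condition = "treatment",
                             t_grid = seq(0, 24, by = 0.1)) {
  params <- stats::setNames(check_params(network, params),
                            network$param_names)
  if (!param_name %in% network$param_names)
    stop("unknown parameter: ", param_name)
  x0 <- vapply(network$dynamic, function(sp)
    get_course(dataset, sp, condition)$values[1L], 0)
  run_max <- function(r) {
    p <- params; p[param_name] <- r * params[param_name]
    tr <- simulate_network(network, p, x0, dataset, condition, t_grid)
    apply(tr$state, 2L, max)
  }
  base <- run_max(1)
  base_safe <- ifelse(base > 0, base, 1)
  fc <- t(vapply(ratios, function(r) run_max(r) / base_safe,
                 numeric(length(base))))
  rownames(fc) <- as.character(ratios)
  slope <- (run_max(1.1) - run_max(0.9)) / (0.2 * base_safe)
  structure(list(param = param_name, ratios = ratios, fold_change = fc,
                 slope = stats::setNames(slope, network$dynamic),
                 condition = condition),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("sensitivity_result for", x$param, "(", x$condition, ")\n")
  print(signif(x$fold_change, 4))
  cat("slopes at ratio 1:\n")
  print(signif(x$slope, 3))
  invisible(x)
}

#' Eigenvalue time-scale classification
#'
#' Computes the Jacobian of the mass-balance ODEs at the control steady
#' state (inputs frozen at their control values, gene folds 1), its
#' eigendecomposition, and assigns every metabolite a characteristic time.
#' A metabolite "contributes substantially" to an eigenvector when its
#' component magnitude, normalized by the eigenvector's largest component,
#' is at least `contrib`; among the eigenvalues whose eigenvectors it
#' contributes to, each metabolite is assigned the one of smallest
#' magnitude (the slow manifold governs the approach to steady state).
#' Characteristic times 1/|Re(lambda)| are bucketed into fast (< 3 hr),
#' medium (3-30 hr) and slow (> 30 hr).
#'
#' @param network A `sphingo_network`.
#' @param params Rate constants.
#' @param dataset A [condition_dataset()] with a control condition.
#' @param thresholds Category boundaries in hours, `c(fast, slow)`.
#' @param contrib Eigenvector contribution threshold (default 0.3).
#' @param ss Optional precomputed steady state (skips the 1000-hr run).
#' @return A list of class `timescale_result`: `eigenvalues`,
#'   `eigenvectors`, `table` (metabolite, eigenvalue, characteristic time,
#'   category) and the steady state used.
#' @export
timescale_classification <- function(network, params, dataset,
                                     thresholds = c(fast = 3, slow = 30),
                                     contrib = 0.3, ss = NULL) {
  if (is.null(ss)) ss <- steady_state(network, params, dataset)
  u <- measured_inputs(network, dataset, "control", 0)
  J <- network_jacobian(network, params, as.numeric(ss), u)
  eg <- eigen(J)
  tab <- classify_timescales(eg$values, eg$vectors, network$dynamic,
                             thresholds, contrib)
  structure(list(eigenvalues = eg$values, eigenvectors = eg$vectors,
                 table = tab, steady_state = ss),
            class = "timescale_result")
}

# eigenvalue/eigenvector -> per-metabolite category assignment; a metabolite
# contributing substantially (>= contrib of the eigenvector's largest
# component) to several eigenvectors takes the smallest-magnitude eigenvalue
classify_timescales <- function(lam, V, species,
                                thresholds = c(fast = 3, slow = 30),
                                contrib = 0.3) {
  C <- abs(V)
  C <- sweep(C, 2L, apply(C, 2L, max), "/")
  assigned <- integer(length(species))
  for (j in seq_along(species)) {
    cand <- which(C[j, ] >= contrib)
    if (length(cand) == 0L) cand <- which.max(C[j, ])  # fallback: best match
    assigned[j] <- cand[which.min(abs(Re(lam[cand])))]
  }
  lam_a <- lam[assigned]
  tau <- 1 / abs(Re(lam_a))
  category <- ifelse(tau < thresholds[["fast"]], "fast",
                     ifelse(tau <= thresholds[["slow"]], "medium", "slow"))
  data.frame(metabolite = species, eigenvalue = Re(lam_a),
             characteristic_time_hr = tau, category = category)
}

#' @export
print.timescale_result <- function(x, ...) {
  cat("timescale_result (eigenvalue real parts: ",
      paste(signif(sort(Re(x$eigenvalues)), 3), collapse = ", "), ")\n",
      sep = "")
  print(transform(x$table,
                  eigenvalue = signif(eigenvalue, 3),
                  characteristic_time_hr = signif(characteristic_time_hr, 3)))
  invisible(x)
}

#' Convert a rate from per-DNA to per-protein units
#'
#' Converts pmol/hr/ug-DNA to pmol/min/mg-protein using the measured
#' RAW264.7 relationships of ~3 ug DNA and ~0.25 mg protein per 10^6 cells:
#' x * 3 / 0.25 / 60.
#'
#' @param x Rate(s) in pmol/hr/ug-DNA; must be nonnegative.
#' @param inverse If TRUE, convert pmol/min/mg-protein back to
#'   pmol/hr/ug-DNA.
#' @return Converted rate(s).
#' @export
convert_rate_units <- function(x, inverse = FALSE) {
  if (any(x < 0)) stop("rates must be nonnegative")
  f <- 3 / 0.25 / 60
  if (inverse) x / f else x * f
}
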