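#' Load the C16 sphingolipid reaction network
#'
#' Reads a structured network definition (YAML) describing the simplified
#' C16-branch sphingolipid reaction network: 9 dynamic metabolites, 4 input
#' lipids, 9 gene/protein inputs and 25 mass-action reactions (4 of them
#' reversible, giving 29 rate constants). The default file shipped with the
#' package encodes the RAW264.7 macrophage model; alternative chain lengths
#' can be instantiated by supplying a different definition file.
#'
#' Each reaction record carries the mass-action rate factors (metabolite,
#' input-lipid and gene names whose product, times the rate constant, gives
#' the flux) and the dynamic species it consumes/produces. Flux units are
#' pmol/ug-DNA/hr; time is in hours throughout.
#'
#' @param path Path to a YAML network definition. Defaults to the packaged
#'   C16 network.
#' @return An object of class `sphingo_network`: a list with the species
#'   catalog, reaction table, parameter names, and the 9 x 25 stoichiometry
#'   matrix, plus precomputed index tables used by the flux evaluator.
#' @export
load_network <- function(path = system.file("extdata", "network_c16.yaml",
                                            package = "sphingokinetics")) {
  raw <- yaml::read_yaml(path)
  dyn   <- as.character(raw$species$dynamic)
  lip   <- as.character(raw$species$input_lipids)
  genes <- as.character(raw$species$genes)
  all_names <- c(dyn, lip, genes)
  if (anyDuplicated(all_names))
    stop("species names duplicated across catalog lists: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))

  nr <- length(raw$reactions)
  n_dyn <- length(dyn)
  # z-vector layout used by the evaluator: c(state, lipids, genes, 1)
  pad <- length(all_names) + 1L
  zindex <- function(nm) {
    i <- match(nm, all_names)
    if (anyNA(i)) stop("unknown species name in network file: ",
                       paste(nm[is.na(i)], collapse = ", "))
    i
  }

  S <- matrix(0L, n_dyn, nr, dimnames = list(dyn, NULL))
  fwd_idx <- matrix(pad, nr, 3L)
  bwd_idx <- matrix(pad, nr, 3L)
  fwd_param <- character(nr)
  bwd_param <- rep(NA_character_, nr)
  reversible <- logical(nr)
  reactions <- vector("list", nr)

  for (k in seq_len(nr)) {
    r <- raw$reactions[[k]]
    if (!identical(as.integer(r$id), k))
      stop("reaction ids must be 1..", nr, " in order; got id ", r$id)
    ff <- as.character(r$forward$factors)
    if (length(ff) < 1L || length(ff) > 3L)
      stop("reaction ", k, ": 1-3 forward factors required")
    fwd_idx[k, seq_along(ff)] <- zindex(ff)
    fwd_param[k] <- r$forward$param
    if (!is.null(r$backward)) {
      reversible[k] <- TRUE
      bf <- as.character(r$backward$factors)
      bwd_idx[k, seq_along(bf)] <- zindex(bf)
      bwd_param[k] <- r$backward$param
    }
    cons <- as.character(r$consumes); prod <- as.character(r$produces)
    bad <- setdiff(c(cons, prod), dyn)
    if (length(bad))
      stop("reaction ", k, ": non-dynamic species in stoichiometry: ",
           paste(bad, collapse = ", "))
    for (s in cons) S[s, k] <- S[s, k] - 1L
    for (s in prod) S[s, k] <- S[s, k] + 1L
    reactions[[k]] <- list(id = k, forward_factors = ff,
                           backward_factors = if (reversible[k])
                             as.character(r$backward$factors) else NULL,
                           consumes = cons, produces = prod,
                           forward_param = fwd_param[k],
                           backward_param = bwd_param[k],
                           reversible = reversible[k])
  }

  param_names <- c(fwd_param, bwd_param[reversible])
  if (anyDuplicated(param_names)) stop("duplicate parameter names")

  net <- list(
    dynamic = dyn, input_lipids = lip, genes = genes,
    inputs = c(lip, genes),
    reactions = reactions,
    S = S,
    param_names = param_names,
    n_params = length(param_names),
    fwd_idx = fwd_idx, bwd_idx = bwd_idx,
    fwd_param = fwd_param, bwd_param = bwd_param,
    reversible = reversible, pad = pad
  )
  class(net) <- "sphingo_network"
  net
}

#' @export
print.sphingo_network <- function(x, ...) {
  cat("sphingo_network:", length(x$reactions), "reactions,",
      length(x$dynamic), "dynamic species,",
      length(x$input_lipids), "input lipids,",
      length(x$genes), "genes,", x$n_params, "rate constants\n")
  invisible(x)
}

#' Reference rate constants for the RAW264.7 C16 model
#'
#' Returns the curated set of 29 estimated mass-action rate constants for the
#' C16-branch sphingolipid network in KLA-stimulated RAW264.7 macrophages
#' (model units: per hour, per unit of each co-factor). The reported standard
#' errors are attached as the `"sem"` attribute.
#'
#' @return Named numeric vector of length 29 (kf1..kf25, kb9, kb10, kb19,
#'   kb20), with attribute `sem`.
#' @export
raw264_params <- function() {
  tab <- utils::read.csv(system.file("extdata", "raw264_rate_constants.csv",
                                     package = "sphingokinetics"))
  p <- stats::setNames(tab$value, tab$name)
  attr(p, "sem") <- stats::setNames(tab$sem, tab$name)
  p
}

## ---- validation helpers -------------------------------------------------

check_state <- function(network, state) {
  if (length(state) != length(network$dynamic))
    stop("state must have length ", length(network$dynamic))
  if (!is.null(names(state))) {
    i <- match(network$dynamic, names(state))
    if (anyNA(i)) stop("state is missing species: ",
                       paste(network$dynamic[is.na(i)], collapse = ", "))
    state <- state[i]
  }
  if (any(!is.finite(state))) stop("non-finite state value")
  neg <- state < 0
  if (any(neg)) stop("negative concentration for: ",
                     paste(network$dynamic[neg], collapse = ", "))
  unname(state)
}

check_inputs <- function(network, inputs) {
  if (length(inputs) != length(network$inputs))
    stop("inputs must have length ", length(network$inputs),
         " (4 lipids then 9 gene folds)")
  if (!is.null(names(inputs))) {
    i <- match(network$inputs, names(inputs))
    if (anyNA(i)) stop("inputs missing: ",
                       paste(network$inputs[is.na(i)], collapse = ", "))
    inputs <- inputs[i]
  }
  if (any(!is.finite(inputs))) stop("non-finite input value")
  neg <- inputs < 0
  if (any(neg)) stop("negative input value for: ",
                     paste(network$inputs[neg], collapse = ", "))
  unname(inputs)
}

check_params <- function(network, params) {
  if (length(params) != network$n_params)
    stop("params must have length ", network$n_params)
  if (!is.null(names(params))) {
    i <- match(network$param_names, names(params))
    if (anyNA(i)) stop("params missing: ",
                       paste(network$param_names[is.na(i)], collapse = ", "))
    params <- params[i]
  }
  if (any(!is.finite(params))) stop("non-finite parameter value")
  neg <- params < 0
  if (any(neg)) stop("negative rate constant: ",
                     paste(network$param_names[neg], collapse = ", "))
  unname(params)
}

# forward/backward mass-action factor products at one (state, inputs) point
factor_products <- function(network, state, inputs) {
  z <- c(state, inputs, 1)
  fp <- z[network$fwd_idx[, 1L]] * z[network$fwd_idx[, 2L]] *
    z[network$fwd_idx[, 3L]]
  bp <- z[network$bwd_idx[, 1L]] * z[network$bwd_idx[, 2L]] *
    z[network$bwd_idx[, 3L]]
  bp[!network$reversible] <- 0
  list(fwd = fp, bwd = bp)
}

#' Reaction fluxes at one state
#'
#' Evaluates all 25 mass-action fluxes v_i (pmol/ug-DNA/hr). Reversible
#' reactions (9, 10, 19, 20) return the net forward-minus-backward flux and
#' may be negative; irreversible fluxes are nonnegative for nonnegative
#' arguments.
#'
#' @param network A `sphingo_network`.
#' @param state Numeric state vector (9 dynamic species, catalog order, or
#'   named).
#' @param inputs Numeric input vector (4 input lipids then 9 gene
#'   fold-changes, catalog order, or named).
#' @param params Numeric vector of the 29 rate constants (catalog order, or
#'   named).
#' @return Numeric vector of length 25.
#' @export
flux_vector <- function(network, state, inputs, params) {
  state <- check_state(network, state)
  inputs <- check_inputs(network, inputs)
  params <- check_params(network, params)
  kf <- params[match(network$fwd_param, network$param_names)]
  kb <- ifelse(is.na(network$bwd_param), 0,
               params[match(network$bwd_param, network$param_names)])
  pr <- factor_products(network, state, inputs)
  kf * pr$fwd - kb * pr$bwd
}

#' Time derivatives of the dynamic metabolites
#'
#' The right-hand side of the 9 mass-balance ODEs: the stoichiometry matrix
#' applied to the flux vector.
#'
#' @inheritParams flux_vector
#' @return Numeric vector of length 9 (pmol/ug-DNA/hr), named by species.
#' @export
network_rhs <- function(network, state, inputs, params) {
  v <- flux_vector(network, state, inputs, params)
  stats::setNames(as.vector(network$S %*% v), network$dynamic)
}

#' Stoichiometry matrix
#'
#' @param network A `sphingo_network`.
#' @return Integer 9 x 25 matrix; entry (j, i) is the net coefficient of
#'   dynamic species j in flux v_i. Input lipids and genes carry no rows.
#' @export
stoichiometry_matrix <- function(network) network$S

#' Per-parameter regressor values
#'
#' For each of the 29 rate constants, the mass-action factor product that
#' multiplies it (forward product for kf's, backward product for kb's,
#' unsigned). These are the raw ingredients of the linear-in-parameters
#' decomposition dx/dt = D(x, u) b used by the estimation step.
#'
#' @inheritParams flux_vector
#' @return Named numeric vector of length 29.
#' @export
basis_fluxes <- function(network, state, inputs) {
  state <- check_state(network, state)
  inputs <- check_inputs(network, inputs)
  pr <- factor_products(network, state, inputs)
  out <- numeric(network$n_params)
  names(out) <- network$param_names
  out[network$fwd_param] <- pr$fwd
  rev <- which(network$reversible)
  out[network$bwd_param[rev]] <- pr$bwd[rev]
  out
}

#' Design block of the linear-in-parameters decomposition
#'
#' Assembles the 9 x 29 matrix D(x, u) such that `network_rhs(x, u, b)` equals
#' `D %*% b` for every parameter vector b. Backward-parameter columns carry
#' the negative sign of the reverse flux term.
#'
#' @inheritParams flux_vector
#' @return Numeric 9 x 29 matrix with species rows and parameter columns.
#' @export
design_block <- function(network, state, inputs) {
  state <- check_state(network, state)
  inputs <- check_inputs(network, inputs)
  pr <- factor_products(network, state, inputs)
  D <- matrix(0, length(network$dynamic), network$n_params,
              dimnames = list(network$dynamic, network$param_names))
  for (i in seq_along(network$reactions)) {
    D[, network$fwd_param[i]] <- D[, network$fwd_param[i]] +
      network$S[, i] * pr$fwd[i]
    if (network$reversible[i])
      D[, network$bwd_param[i]] <- D[, network$bwd_param[i]] -
        network$S[, i] * pr$bwd[i]
  }
  D
}
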