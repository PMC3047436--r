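#' Resampling configuration
#'
#' Controls the SEM-resampling procedure that propagates replicate noise in
#' the lipid and gene data into parameter uncertainty.
#'
#' @param k Number of resampled datasets (default 10).
#' @param seed Random seed recorded in the output.
#' @return A list of class `resampling_config`.
#' @export
resampling_config <- function(k = 10, seed = 1) {
  stopifnot(k >= 2)
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "resampling_config")
}

#' Perturb a dataset by its SEMs
#'
#' Creates a candidate dataset with each measured mean replaced by
#' mean + SEM * z, z ~ N(0, 1) drawn independently per point, for all
#' metabolite, input-lipid and gene courses. Negative candidates are floored
#' at zero (a small bias source, documented in the methods vignette).
#' Courses with SEM identically zero are returned unchanged; the control
#' gene folds (defined as 1 with no error) are therefore preserved.
#'
#' Uses R's global random number stream; call `set.seed()` (or use
#' [parameter_sem()], which does) for reproducibility.
#'
#' @param network A `sphingo_network`.
#' @param dataset A [condition_dataset()].
#' @return A perturbed [condition_dataset()].
#' @export
perturb_dataset <- function(network, dataset) {
  out <- dataset
  for (cond in names(dataset$courses)) {
    for (sp in names(dataset$courses[[cond]])) {
      tc <- dataset$courses[[cond]][[sp]]
      if (is.null(tc$sem)) stop("missing SEM for ", sp, " / ", cond)
      v <- pmax(tc$values + tc$sem * stats::rnorm(length(tc$values)), 0)
      out$courses[[cond]][[sp]] <- time_course(sp, cond, tc$times, v, tc$sem)
    }
  }
  out
}

#' Parameter uncertainty by SEM resampling
#'
#' Runs the full two-step estimation on each of k SEM-perturbed candidate
#' datasets and summarizes the spread of the k re-estimates for every rate
#' constant, alongside the point estimate from the unperturbed data. The
#' "SEM" of a parameter is reported both as the standard deviation across
#' the k estimates (`spread`, the spread of re-estimates) and as
#' spread/sqrt(k) (`sem`).
#'
#' @param network A `sphingo_network`.
#' @param dataset A [condition_dataset()] carrying SEMs.
#' @param config A [resampling_config()].
#' @param fitcfg A [fit_config()] used for every fit.
#' @return A list of class `parameter_sem_result`: `table` (data.frame with
#'   name, estimate, spread, sem, fractional_spread), `estimates` (k x 29
#'   matrix), `n_failed`, `seed`.
#' @export
parameter_sem <- function(network, dataset, config = resampling_config(),
                          fitcfg = fit_config()) {
  set.seed(config$seed)
  point <- fit_rate_constants(network, dataset, fitcfg)
  est <- matrix(NA_real_, config$k, network$n_params,
                dimnames = list(NULL, network$param_names))
  n_failed <- 0L
  for (i in seq_len(config$k)) {
    cand <- perturb_dataset(network, dataset)
    fit <- tryCatch(fit_rate_constants(network, cand, fitcfg),
                    error = function(e) NULL)
    if (is.null(fit)) n_failed <- n_failed + 1L
    else est[i, ] <- fit$params
  }
  if (n_failed > config$k / 2)
    stop("more than half of the resampled fits failed (", n_failed, " of ",
         config$k, ")")
  spread <- apply(est, 2L, stats::sd, na.rm = TRUE)
  tab <- data.frame(
    name = network$param_names,
    estimate = unname(point$params),
    spread = unname(spread),
    sem = unname(spread) / sqrt(sum(!is.na(est[, 1L]))),
    fractional_spread = unname(ifelse(point$params > 0,
                                      spread / point$params, NA)))
  structure(list(table = tab, estimates = est, n_failed = n_failed,
                 seed = config$seed, point_fit = point),
            class = "parameter_sem_result")
}

#' @export
print.parameter_sem_result <- function(x, ...) {
  cat("parameter_sem_result (k = ", nrow(x$estimates), ", seed = ", x$seed,
      ", failed = ", x$n_failed, ")\n", sep = "")
  print(transform(x$table, estimate = signif(estimate, 4),
                  spread = signif(spread, 3), sem = signif(sem, 3),
                  fractional_spread = signif(fractional_spread, 3)))
  invisible(x)
}
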