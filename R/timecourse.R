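#' Construct a single time-course
#'
#' A measured (or synthetic) time series for one species under one condition:
#' mean values on a strictly increasing time grid, with per-point standard
#' errors of the mean. The default experimental grid is 0, 0.5, 1, 2, 4, 8,
#' 12, 24 hr.
#'
#' @param species Species name.
#' @param condition `"control"` or `"treatment"`.
#' @param times Numeric times in hours, strictly increasing.
#' @param values Mean concentrations (pmol/ug-DNA) or gene fold-changes.
#' @param sem Nonnegative per-point standard errors (default 0).
#' @return An object of class `time_course`.
#' @export
time_course <- function(species, condition, times, values,
                        sem = rep(0, length(times))) {
  stopifnot(length(times) == length(values), length(sem) == length(times))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(sem < 0)) stop("sem must be nonnegative")
  structure(list(species = species, condition = condition,
                 times = as.numeric(times), values = as.numeric(values),
                 sem = as.numeric(sem)),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("time_course:", x$species, "(", x$condition, "),",
      length(x$times), "points over", min(x$times), "-", max(x$times), "hr\n")
  invisible(x)
}

#' Build a replicate table
#'
#' Per-time-point replicate measurements with biological/technical labels
#' (3 biological x 3 technical by default in the experimental design).
#'
#' @param species,condition As in [time_course()].
#' @param data A data.frame with columns `time_hr`, `replicate_bio`,
#'   `replicate_tech`, `value`.
#' @return An object of class `replicate_table`.
#' @export
replicate_table <- function(species, condition, data) {
  need <- c("time_hr", "replicate_bio", "replicate_tech", "value")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("replicate data missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("empty replicate table")
  structure(list(species = species, condition = condition,
                 data = data[need]),
            class = "replicate_table")
}

# Grubbs critical value for the extreme studentized deviate, two-sided
grubbs_critical <- function(n, alpha) {
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
}

#' Remove replicate outliers
#'
#' Applies a per-time-point Grubbs-type extreme studentized deviate test at
#' level `alpha`, iteratively, removing at most `floor(n/3)` values per time
#' point. Time points with fewer than 3 replicates are returned unchanged
#' (no test is possible).
#'
#' @param replicates A [replicate_table()].
#' @param alpha Significance level (default 0.05).
#' @return A `replicate_table` with flagged values removed.
#' @export
remove_outliers <- function(replicates, alpha = 0.05) {
  stopifnot(inherits(replicates, "replicate_table"))
  d <- replicates$data
  keep <- rep(TRUE, nrow(d))
  for (t0 in unique(d$time_hr)) {
    idx <- which(d$time_hr == t0)
    n0 <- length(idx)
    if (n0 < 3L) next
    max_rm <- floor(n0 / 3)
    removed <- 0L
    repeat {
      live <- idx[keep[idx]]
      n <- length(live)
      if (removed >= max_rm || n < 3L) break
      x <- d$value[live]
      s <- stats::sd(x)
      if (s == 0) break
      dev <- abs(x - mean(x)) / s
      g <- max(dev)
      if (g > grubbs_critical(n, alpha)) {
        keep[live[which.max(dev)]] <- FALSE
        removed <- removed + 1L
      } else break
    }
  }
  replicate_table(replicates$species, replicates$condition, d[keep, ])
}

#' Average replicates into a mean/SEM time-course
#'
#' Mean and standard error of the mean (sd/sqrt(n)) per time point over the
#' surviving replicates. A single replicate yields SEM 0 by convention.
#'
#' @param replicates A [replicate_table()].
#' @return A [time_course()].
#' @export
average_replicates <- function(replicates) {
  stopifnot(inherits(replicates, "replicate_table"))
  d <- replicates$data
  tt <- sort(unique(d$time_hr))
  m <- s <- numeric(length(tt))
  for (i in seq_along(tt)) {
    x <- d$value[d$time_hr == tt[i]]
    if (length(x) == 0L)
      stop("no surviving replicates at time ", tt[i], " hr")
    m[i] <- mean(x)
    s[i] <- if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  }
  time_course(replicates$species, replicates$condition, tt, m, s)
}

#' Piecewise-linear interpolation of a time-course
#'
#' Linear between samples; constant extrapolation outside the measured
#' range (queries before the first or after the last time point return the
#' boundary value).
#'
#' @param tc A [time_course()].
#' @param t Query times (hours).
#' @return Interpolated values.
#' @export
interpolate_input <- function(tc, t) {
  stopifnot(inherits(tc, "time_course"), length(tc$times) >= 1L)
  if (length(tc$times) == 1L) return(rep(tc$values, length(t)))
  stats::approx(tc$times, tc$values, xout = t, rule = 2)$y
}

#' Delayed gene input
#'
#' Protein activity is proxied by the mRNA fold-change with a fixed time
#' delay: p(t) = g(t - delay), default 3 hr. For t < delay the earliest
#' measured fold is held (constant extrapolation), which matches the
#' control convention of fold 1.
#'
#' @param tc A gene fold-change [time_course()].
#' @param t Query times (hours).
#' @param delay Delay in hours (default 3).
#' @return Fold-change values at `t`.
#' @export
delayed_gene <- function(tc, t, delay = 3) {
  interpolate_input(tc, t - delay)
}

#' Assemble a dual-condition dataset
#'
#' Bundles mean/SEM time-courses for all 9 dynamic metabolites, 4 input
#' lipids and 9 genes under both conditions into one object, validated
#' against the network catalog: complete coverage, a shared time grid per
#' condition, and control gene folds identically 1.
#'
#' @param network A `sphingo_network`.
#' @param courses A list of [time_course()] objects, or a long data.frame
#'   with columns `time_hr`, `species`, `condition`, `mean`, `sem`.
#' @param conditions Conditions that must be covered.
#' @return An object of class `condition_dataset` with elements `courses`
#'   (nested list `[[condition]][[species]]`), `times` (per condition) and
#'   `network` catalog names.
#' @export
condition_dataset <- function(network, courses,
                              conditions = c("control", "treatment")) {
  if (is.data.frame(courses)) {
    need <- c("time_hr", "species", "condition", "mean", "sem")
    miss <- setdiff(need, names(courses))
    if (length(miss)) stop("dataset table missing columns: ",
                           paste(miss, collapse = ", "))
    lst <- list()
    for (cond in unique(courses$condition)) {
      for (sp in unique(courses$species[courses$condition == cond])) {
        d <- courses[courses$condition == cond & courses$species == sp, ]
        d <- d[order(d$time_hr), ]
        lst[[length(lst) + 1L]] <- time_course(sp, cond, d$time_hr, d$mean,
                                               d$sem)
      }
    }
    courses <- lst
  }
  all_sp <- c(network$dynamic, network$input_lipids, network$genes)
  out <- stats::setNames(vector("list", length(conditions)), conditions)
  for (tc in courses) {
    if (!tc$condition %in% conditions) next
    out[[tc$condition]][[tc$species]] <- tc
  }
  for (cond in conditions) {
    miss <- setdiff(all_sp, names(out[[cond]]))
    if (length(miss))
      stop("condition '", cond, "' is missing courses for: ",
           paste(miss, collapse = ", "))
    grids <- unique(lapply(out[[cond]][all_sp], function(x) x$times))
    if (length(grids) != 1L)
      stop("condition '", cond, "' courses are not on a shared time grid")
  }
  if ("control" %in% conditions) {
    for (g in network$genes) {
      tc <- out[["control"]][[g]]
      if (any(tc$values != 1))
        stop("control gene fold for ", g, " must be identically 1")
    }
  }
  structure(list(courses = out,
                 times = lapply(out, function(cc) cc[[all_sp[1L]]]$times),
                 dynamic = network$dynamic,
                 input_lipids = network$input_lipids,
                 genes = network$genes),
            class = "condition_dataset")
}

#' @export
print.condition_dataset <- function(x, ...) {
  cat("condition_dataset:", paste(names(x$courses), collapse = ", "),
      "|", length(x$dynamic), "metabolites,",
      length(x$input_lipids), "input lipids,", length(x$genes), "genes\n")
  for (cond in names(x$courses))
    cat("  ", cond, ": ", length(x$times[[cond]]), " time points (",
        paste(x$times[[cond]], collapse = ", "), " hr)\n", sep = "")
  invisible(x)
}

#' Fetch one course from a dataset
#'
#' @param dataset A [condition_dataset()].
#' @param species Species name.
#' @param condition Condition name.
#' @return A [time_course()].
#' @export
get_course <- function(dataset, species, condition) {
  tc <- dataset$courses[[condition]][[species]]
  if (is.null(tc)) stop("no course for ", species, " / ", condition)
  tc
}

# matrix of measured means: rows = species, cols = time points
course_matrix <- function(dataset, species, condition) {
  t(vapply(species,
           function(sp) get_course(dataset, sp, condition)$values,
           numeric(length(dataset$times[[condition]]))))
}

#' Write / read a dataset as CSV
#'
#' Long format with columns `time_hr`, `species`, `condition`, `mean`,
#' `sem` (UTF-8, '.' decimal separator, header row).
#'
#' @param dataset A [condition_dataset()].
#' @param path Output file path.
#' @return `write_condition_dataset` returns `path` invisibly;
#'   `read_condition_dataset` returns a [condition_dataset()].
#' @export
write_condition_dataset <- function(dataset, path) {
  rows <- list()
  for (cond in names(dataset$courses))
    for (tc in dataset$courses[[cond]])
      rows[[length(rows) + 1L]] <- data.frame(
        time_hr = tc$times, species = tc$species, condition = cond,
        mean = tc$values, sem = tc$sem)
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_condition_dataset
#' @param network A `sphingo_network` used to validate coverage.
#' @export
read_condition_dataset <- function(network, path) {
  df <- utils::read.csv(path)
  condition_dataset(network, df, conditions = unique(df$condition))
}
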