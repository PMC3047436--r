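DEFAULT_GRID <- c(0, 0.5, 1, 2, 4, 8, 12, 24)

#' Default input profiles
#'
#' The synthetic study conditions for the 4 input lipids and 9 gene
#' fold-changes on the standard 8-point grid. Treatment encodes the
#' qualitative experimental observations: sphinganine (DHSph) rises to
#' double its baseline at 4 hr and returns to baseline by 24 hr;
#' palmitoyl-CoA (CoA16) increases monotonically over 0-24 hr; gene folds
#' start at 1 and diverge after ~2-4 hr with a distinct piecewise-linear
#' shape per gene (pairwise non-proportional, an identifiability guard).
#' Control profiles are constant, with gene folds identically 1.
#'
#' @param condition `"control"` or `"treatment"`.
#' @return A named list of numeric value vectors (one per input lipid and
#'   gene) with the time grid attached as attribute `times`.
#' @export
default_input_profiles <- function(condition = c("treatment", "control")) {
  condition <- match.arg(condition)
  if (condition == "control") {
    p <- c(list(DHSph = rep(2, 8), CoA16 = rep(0.5, 8),
                C16DG = rep(0.05, 8), C16GPCho = rep(2, 8)),
           stats::setNames(rep(list(rep(1, 8)), 9),
                           c("CerS6", "Sphk1", "Sphk2", "Ugcg", "Sms1",
                             "Sms2", "Smpd1", "Cerk", "Degs1")))
  } else {
    p <- list(
      DHSph    = c(2, 2.2, 2.5, 3, 4, 3.5, 2.8, 2),
      CoA16    = c(0.5, 0.52, 0.55, 0.6, 0.7, 0.8, 0.88, 0.95),
      C16DG    = c(0.05, 0.05, 0.055, 0.06, 0.07, 0.08, 0.075, 0.07),
      C16GPCho = c(2, 2, 2.1, 2.2, 2.4, 2.6, 2.5, 2.4),
      CerS6    = c(1, 1, 1, 1.1, 1.5, 2.5, 3.5, 4),
      Sphk1    = c(1, 1.2, 1.5, 1.8, 1.5, 1.2, 1, 0.9),
      Sphk2    = c(1, 1, 0.95, 0.9, 0.8, 0.7, 0.6, 0.6),
      Ugcg     = c(1, 1, 1.1, 1.4, 2, 2.5, 2.2, 2),
      Sms1     = c(1, 1, 1, 1.2, 1.4, 1.5, 1.6, 1.5),
      Sms2     = c(1, 1, 1, 0.9, 0.8, 0.6, 0.5, 0.45),
      Smpd1    = c(1, 1, 1, 1.05, 1.3, 2, 3, 3.5),
      Cerk     = c(1, 1, 1.3, 1.7, 2, 1.6, 1.2, 1),
      Degs1    = c(1, 1, 1, 1.1, 1.6, 2.2, 2.8, 3))
  }
  attr(p, "times") <- DEFAULT_GRID
  p
}

#' Default initial state
#'
#' Baseline t = 0 concentrations (pmol/ug-DNA) for the 9 dynamic
#' metabolites, chosen near -- but deliberately off -- the control steady
#' state implied by the reference rate constants and control inputs, so the
#' control condition shows relaxation dynamics rather than a flat line.
#' The spread (0.007 for C16 DHCerP up to 590 for C16 SM) mirrors the
#' measured concentration range.
#'
#' @return Named state vector of length 9.
#' @export
default_initial_state <- function() {
  c(C16DHCer = 10.5, DHSph1P = 0.08, C16DHGlcCer = 0.47, C16DHSM = 32,
    C16DHCerP = 0.007, C16Cer = 54, C16CerP = 0.068, C16SM = 590,
    C16GlcCer = 225)
}

#' Specify a synthetic ground truth
#'
#' Fully determines a synthetic dual-condition dataset: the generating rate
#' constants, the initial state, the input/gene profiles per condition, the
#' fractional-SEM noise level, the replicate structure and the seed.
#'
#' @param params Generating rate constants (default: the reference RAW264.7
#'   set, making the printed values the recovery targets).
#' @param x0 Initial state (default [default_initial_state()]).
#' @param profiles Named list with `control` and `treatment` profile lists
#'   (default [default_input_profiles()]).
#' @param noise Fractional SEM of each measured mean (default 0.25,
#'   matching the observed 20-30 percent data noise).
#' @param reps_bio,reps_tech Replicate structure (default 3 x 3).
#' @param noise_model `"lognormal"` (multiplicative; concentrations stay
#'   positive) or `"normal"` (additive, mirroring the resampling model).
#' @param seed Random seed.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(params = raw264_params(),
                            x0 = default_initial_state(),
                            profiles = list(
                              control = default_input_profiles("control"),
                              treatment = default_input_profiles("treatment")),
                            noise = 0.25, reps_bio = 3, reps_tech = 3,
                            noise_model = c("lognormal", "normal"),
                            seed = 1) {
  structure(list(params = params, x0 = x0, profiles = profiles,
                 noise = noise, reps_bio = reps_bio, reps_tech = reps_tech,
                 noise_model = match.arg(noise_model),
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# dataset skeleton holding only the input/gene courses, enough for
# input_function() to interpolate during generation
input_only_dataset <- function(network, truth, condition) {
  times <- attr(truth$profiles[[condition]], "times")
  courses <- stats::setNames(list(list()), condition)
  for (sp in c(network$input_lipids, network$genes))
    courses[[condition]][[sp]] <-
      time_course(sp, condition, times, truth$profiles[[condition]][[sp]])
  structure(list(courses = courses,
                 times = stats::setNames(list(times), condition),
                 dynamic = network$dynamic,
                 input_lipids = network$input_lipids,
                 genes = network$genes),
            class = "condition_dataset")
}

# replicate draws around a mean with target fractional SEM `noise`
draw_replicates <- function(mean_val, noise, n, model) {
  cv <- noise * sqrt(n)  # per-replicate CV so the SEM of the mean ~ noise
  if (model == "lognormal") {
    s <- sqrt(log(1 + cv^2))
    mean_val * exp(stats::rnorm(n, -s^2 / 2, s))
  } else {
    pmax(mean_val * (1 + cv * stats::rnorm(n)), 0)
  }
}

#' Generate a synthetic dual-condition dataset
#'
#' Simulates both conditions from the ground truth, samples the
#' trajectories at the 8-point grid, draws replicate tables with
#' multiplicative noise of the stated fractional SEM for every metabolite,
#' input lipid and (treatment) gene, and reduces them to mean/SEM courses
#' through the standard preprocessing (outlier removal, then averaging).
#' With `noise = 0` the dataset equals the model trajectory exactly and all
#' SEMs are zero. Control gene folds are emitted as exactly 1 with SEM 0.
#'
#' @param network A `sphingo_network`.
#' @param truth A [synthetic_truth()].
#' @param outlier_alpha Significance level for replicate outlier screening
#'   (default 0.05); set to `NULL` to skip.
#' @return A [condition_dataset()] with `truth` attached as an attribute.
#' @export
generate_dataset <- function(network, truth, outlier_alpha = 0.05) {
  set.seed(truth$seed)
  n <- truth$reps_bio * truth$reps_tech
  noisy <- truth$noise > 0 && n > 1L
  courses <- list()
  add_course <- function(sp, cond, times, means, exact = FALSE) {
    if (!noisy || exact) {
      courses[[length(courses) + 1L]] <<- time_course(sp, cond, times, means)
      return(invisible())
    }
    d <- do.call(rbind, lapply(seq_along(times), function(i) {
      data.frame(time_hr = times[i],
                 replicate_bio = rep(seq_len(truth$reps_bio),
                                     each = truth$reps_tech),
                 replicate_tech = rep(seq_len(truth$reps_tech),
                                      truth$reps_bio),
                 value = draw_replicates(means[i], truth$noise, n,
                                         truth$noise_model))
    }))
    rt <- replicate_table(sp, cond, d)
    if (!is.null(outlier_alpha)) rt <- remove_outliers(rt, outlier_alpha)
    courses[[length(courses) + 1L]] <<- average_replicates(rt)
    invisible()
  }
  for (cond in c("control", "treatment")) {
    prof <- truth$profiles[[cond]]
    times <- attr(prof, "times")
    skel <- input_only_dataset(network, truth, cond)
    tr <- simulate_network(network, truth$params, truth$x0, skel, cond,
                           t_grid = times)
    for (sp in network$dynamic)
      add_course(sp, cond, times, tr$state[, sp])
    for (sp in network$input_lipids)
      add_course(sp, cond, times, prof[[sp]])
    for (sp in network$genes)
      add_course(sp, cond, times, prof[[sp]],
                 exact = (cond == "control"))  # control folds are exact 1s
  }
  ds <- condition_dataset(network, courses)
  attr(ds, "truth") <- truth
  ds
}
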