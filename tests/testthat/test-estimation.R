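test_that("backward differences land on the right endpoints", {
  tc <- time_course("X", "control", c(0, 1), c(1, 2))
  fd <- finite_difference_derivatives(tc)
  expect_equal(fd$time, 1)
  expect_equal(fd$deriv, 1)
  const <- time_course("X", "control", c(0, 0.5, 1, 2, 4, 8, 12, 24),
                       rep(3, 8))
  expect_equal(finite_difference_derivatives(const)$deriv, rep(0, 7))
})

test_that("backward differences respect the first-order error bound", {
  grid <- c(0, 0.5, 1, 2, 4, 8, 12, 24)
  tc <- time_course("X", "control", grid, exp(-grid))
  fd <- finite_difference_derivatives(tc)
  truth <- -exp(-grid[-1])
  # |x''| on each interval is bounded by its value at the left endpoint
  bound <- exp(-grid[-8]) * diff(grid) / 2
  expect_true(all(abs(fd$deriv - truth) <= bound + 1e-12))
})

test_that("the stacked regression system has the documented shape", {
  ds <- noise_free_dataset()
  sys <- build_regression_system(NET, ds)
  expect_equal(length(sys$Y), 9 * 7 * 2)
  expect_equal(dim(sys$X), c(126L, 29L))
  expect_identical(colnames(sys$X), NET$param_names)
  # control rows use gene folds of 1: the kf1 and kf2 regressors collapse
  ctrl <- sys$meta$condition == "control"
  expect_equal(sys$X[ctrl, "kf1"], sys$X[ctrl, "kf2"])
  expect_gt(max(abs(sys$X[!ctrl, "kf1"] - sys$X[!ctrl, "kf2"])), 0)
})

test_that("discretization residual shrinks as the grid refines", {
  b <- raw264_params()
  g8 <- c(0, 0.5, 1, 2, 4, 8, 12, 24)
  resid_norm <- vapply(c(1L, 4L, 16L), function(refine) {
    grid <- sort(unique(as.vector(
      vapply(seq_len(7), function(i) {
        seq(g8[i], g8[i + 1], length.out = refine + 1L)
      }, numeric(refine + 1L)))))
    prof_t <- lapply(c("control", "treatment"), function(cc) {
      p <- default_input_profiles(cc)
      out <- lapply(p, function(v)
        approx(g8, v, xout = grid, rule = 2)$y)
      attr(out, "times") <- grid
      out
    })
    names(prof_t) <- c("control", "treatment")
    truth <- synthetic_truth(noise = 0, reps_bio = 1, reps_tech = 1,
                             profiles = prof_t)
    ds <- generate_dataset(NET, truth)
    sys <- build_regression_system(NET, ds)
    sqrt(sum((sys$Y - sys$X %*% b[colnames(sys$X)])^2) / sum(sys$Y^2))
  }, 0)
  expect_true(all(diff(resid_norm) < 0))
  expect_lt(resid_norm[3], 0.05)
})

test_that("nonnegative least squares recovers exact and zero solutions", {
  ds <- noise_free_dataset()
  sys <- build_regression_system(NET, ds)
  b_true <- raw264_params()[colnames(sys$X)]
  sys$Y <- as.vector(sys$X %*% b_true)
  b <- linear_estimate(sys)
  expect_equal(as.numeric(b), as.numeric(b_true), tolerance = 1e-6)
  sys$Y <- rep(0, length(sys$Y))
  expect_equal(unname(linear_estimate(sys)), rep(0, 29))
})

test_that("active nonnegativity constraints match a brute-force search", {
  X <- cbind(c(1, 1, 1), c(1, 2, 3))
  Y <- as.vector(X %*% c(1, -0.5))   # unconstrained optimum has b2 < 0
  sys <- structure(list(Y = Y, X = `colnames<-`(X, c("b1", "b2"))),
                   class = "regression_system")
  b <- linear_estimate(sys)
  expect_equal(unname(b["b2"]), 0)
  # nested grid refinement over the feasible quadrant
  lo <- c(0, 0); hi <- c(2, 2)
  for (round in 1:8) {
    g1 <- seq(lo[1], hi[1], length.out = 21)
    g2 <- seq(lo[2], hi[2], length.out = 21)
    obj <- outer(g1, g2, Vectorize(function(a, c)
      sum((Y - X %*% c(a, c))^2)))
    ij <- which(obj == min(obj), arr.ind = TRUE)[1, ]
    best <- c(g1[ij[1]], g2[ij[2]])
    span <- (hi - lo) / 10
    lo <- pmax(best - span, 0); hi <- best + span
  }
  expect_equal(unname(b), best, tolerance = 1e-6)
})

test_that("column scaling is equivariant", {
  ds <- noise_free_dataset()
  sys <- build_regression_system(NET, ds)
  b <- linear_estimate(sys)
  sys2 <- sys
  sys2$X[, "kf6"] <- 2 * sys2$X[, "kf6"]
  b2 <- linear_estimate(sys2)
  expect_equal(unname(b2["kf6"]), unname(b["kf6"]) / 2, tolerance = 1e-8)
  expect_equal(unname(b2[-match("kf6", names(b2))]),
               unname(b[-match("kf6", names(b))]), tolerance = 1e-6)
})

test_that("proportional kinase profiles are flagged as unidentifiable", {
  prof <- default_input_profiles("treatment")
  prof$Sphk2 <- prof$Sphk1   # identical regressor shapes for kf4 and kf5
  truth <- synthetic_truth(noise = 0, reps_bio = 1, reps_tech = 1,
                           profiles = list(
                             control = default_input_profiles("control"),
                             treatment = prof))
  ds <- generate_dataset(NET, truth)
  sys <- build_regression_system(NET, ds)
  expect_warning(linear_estimate(sys), "kf[45]")
})

test_that("time weights follow the quarter-power interval rule", {
  w <- sphingokinetics:::time_weights(c(0, 1, 17), 0.25)
  expect_equal(w[3] / w[2], 2)         # (16 hr / 1 hr)^(1/4)
  expect_equal(w[1], w[2])             # first point borrows the first interval
})

test_that("refinement at the generating truth stays put with objective ~ 0", {
  ds <- noise_free_dataset()
  truth <- raw264_params()
  fit <- refine_nonlinear(NET, ds, truth,
                          fit_config(maxiter = 3, restarts = 1))
  expect_lt(fit$start_objective, 1e-6)
  expect_lte(fit$objective, fit$start_objective + 1e-12)
  # at the solver-noise floor the sloppy directions (e.g. the kf21/kf22
  # split of SM consumption) may drift; the well-identified constants stay
  targets <- c("kf1", "kf6", "kb9", "kf13", "kf16", "kf22")
  expect_lt(max(abs(fit$params[targets] / truth[targets] - 1)), 1e-2)
})

test_that("tied-pair refits are well specified, nested and intermediate", {
  truth <- raw264_params()
  # (a) truth actually shared: the tied fit recovers the common value
  shared <- truth
  shared["kf7"] <- shared["kf24"] <- 0.021
  ds_sh <- generate_dataset(NET, noise_free_truth(params = shared))
  tied <- shared_parameter_fit(NET, ds_sh, list(c("kf7", "kf24")), shared,
                               fit_config(maxiter = 3, restarts = 1))
  expect_equal(unname(tied$params["kf7"]), 0.021, tolerance = 1e-3)
  expect_equal(unname(tied$params["kf24"]), unname(tied$params["kf7"]))
  expect_lt(tied$objective, 1e-6)

  # (b) truth not shared: tying cannot beat the untied optimum, and the
  # common estimate falls between the two generating values
  ds <- noise_free_dataset()
  untied <- refine_nonlinear(NET, ds, truth,
                             fit_config(maxiter = 3, restarts = 1))
  tied2 <- suppressWarnings(
    shared_parameter_fit(NET, ds, list(c("kf7", "kf24")), truth,
                         fit_config(maxiter = 30, restarts = 2)))
  expect_gte(tied2$objective, untied$objective)
  expect_gt(unname(tied2$params["kf7"]), unname(truth["kf7"]))
  expect_lt(unname(tied2$params["kf7"]), unname(truth["kf24"]))

  expect_error(shared_parameter_fit(NET, ds, list(c("kf1", "kf2")), truth),
               "eligible")
})
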