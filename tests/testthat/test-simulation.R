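test_that("zero rate constants give a constant trajectory", {
  ds <- noise_free_dataset()
  x0 <- default_initial_state()
  tr <- simulate_network(NET, rep(0, 29), x0, ds, "treatment")
  expect_equal(tr$state[nrow(tr$state), ], x0, tolerance = 1e-12)
})

test_that("isolated DHSph1P decay matches the exponential closed form", {
  # dataset with all inputs zero so only the kf6 loss term is active
  grid <- c(0, 1, 2, 4)
  crs <- list()
  for (cond in c("control", "treatment")) {
    for (sp in c(NET$dynamic, NET$input_lipids))
      crs[[length(crs) + 1L]] <- time_course(sp, cond, grid, rep(0, 4))
    for (sp in NET$genes)
      crs[[length(crs) + 1L]] <- time_course(sp, cond, grid, rep(1, 4))
  }
  ds <- condition_dataset(NET, crs)
  p <- setNames(rep(0, 29), NET$param_names); p["kf6"] <- 0.528
  x0 <- setNames(rep(0, 9), NET$dynamic); x0["DHSph1P"] <- 1
  tr <- simulate_network(NET, p, x0, ds, "control", t_grid = grid,
                         rtol = 1e-8, atol = 1e-12)
  expect_equal(tr$state[, "DHSph1P"], exp(-0.528 * grid), tolerance = 1e-6)
  expect_lt(max(abs(tr$state[, setdiff(NET$dynamic, "DHSph1P")])), 1e-10)
})

test_that("stiff and nonstiff solvers agree on the full model", {
  ds <- noise_free_dataset()
  p <- raw264_params(); x0 <- default_initial_state()
  grid <- c(0, 0.5, 1, 2, 4, 8, 12, 24)
  t1 <- simulate_network(NET, p, x0, ds, "treatment", grid,
                         method = "ode45", rtol = 1e-8, atol = 1e-10)
  t2 <- simulate_network(NET, p, x0, ds, "treatment", grid,
                         method = "bdf", rtol = 1e-8, atol = 1e-10)
  M <- apply(t1$state, 2, max)
  expect_lt(max(abs(t1$state - t2$state) / rep(M, each = 8)), 1e-5)
})

test_that("tightening tolerances leaves the trajectory unchanged", {
  ds <- noise_free_dataset()
  p <- raw264_params(); x0 <- default_initial_state()
  a <- simulate_network(NET, p, x0, ds, "treatment", rtol = 1e-7)
  b <- simulate_network(NET, p, x0, ds, "treatment", rtol = 5e-8)
  M <- apply(a$state, 2, max)
  expect_lt(max(abs(a$state - b$state) / rep(M, each = 8)), 1e-6)
})

test_that("with gene folds at 1 and shared lipids the conditions coincide", {
  ds <- flat_dataset()
  p <- raw264_params(); x0 <- default_initial_state()
  tc <- simulate_network(NET, p, x0, ds, "control")
  tt <- simulate_network(NET, p, x0, ds, "treatment")
  expect_equal(tc$state, tt$state, tolerance = 1e-8)
})

test_that("steady state solves simple balances in closed form", {
  ds <- flat_dataset()
  # constant influx u = kf4 * [DHSph] * fold into DHSph1P against kf6 loss
  p <- setNames(rep(0, 29), NET$param_names)
  p["kf4"] <- 0.5; p["kf6"] <- 0.528
  ss <- steady_state(NET, p, ds, t_end = 200)
  expect_true(attr(ss, "converged"))
  expect_equal(unname(ss["DHSph1P"]), 0.5 * 2 / 0.528, tolerance = 1e-6)

  # zero inputs and pure degradation decay to the origin
  grid <- c(0, 24)
  crs <- list()
  for (sp in c(NET$dynamic, NET$input_lipids))
    crs[[length(crs) + 1L]] <- time_course(sp, "control", grid, c(0, 0))
  for (sp in NET$genes)
    crs[[length(crs) + 1L]] <- time_course(sp, "control", grid, c(1, 1))
  ds0 <- condition_dataset(NET, crs, conditions = "control")
  pdeg <- setNames(rep(0.2, 29), NET$param_names)
  ss0 <- steady_state(NET, pdeg, ds0, x0 = rep(1, 9), t_end = 300)
  expect_lt(max(abs(ss0)), 1e-7)
})

test_that("steady state agrees with a direct root of the balance equations", {
  ds <- flat_dataset()
  p <- raw264_params()
  ss <- steady_state(NET, p, ds, t_end = 5000)
  expect_true(attr(ss, "converged"))
  # oracle: the rhs is affine in the state at frozen inputs, so the root
  # solves A x = -u0 with A the analytic Jacobian and u0 = rhs(0)
  u <- c(setNames(c(2, 0.5, 0.05, 2), NET$input_lipids),
         setNames(rep(1, 9), NET$genes))
  A <- oracle_jacobian(u, p)
  u0 <- oracle_rhs(setNames(rep(0, 9), NET$dynamic), u, p)
  root <- solve(A, -u0)
  expect_equal(unname(as.numeric(ss)), unname(root), tolerance = 1e-6)
})

test_that("numerical Jacobian matches the analytic one", {
  set.seed(61)
  p <- raw264_params()
  for (i in 1:5) {
    st <- rand_state(); u <- rand_inputs()
    J <- network_jacobian(NET, p, st, u)
    Ja <- oracle_jacobian(u, p)
    scale <- max(abs(Ja))
    expect_lt(max(abs(J - Ja)) / scale, 1e-6)
  }
  # single-parameter case: lone diagonal entry -kf6
  p0 <- setNames(rep(0, 29), NET$param_names); p0["kf6"] <- 0.3
  J0 <- network_jacobian(NET, p0, setNames(rep(1, 9), NET$dynamic),
                         setNames(rep(1, 13), NET$inputs))
  expect_equal(unname(J0["DHSph1P", "DHSph1P"]), -0.3, tolerance = 1e-8)
  expect_lt(sum(abs(J0)) - abs(J0[2, 2]), 1e-10)
})
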