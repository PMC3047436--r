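test_that("network file loads with the expected catalog and fluxes", {
  expect_s3_class(NET, "sphingo_network")
  expect_length(NET$reactions, 25)
  expect_length(NET$param_names, 29)
  expect_identical(which(NET$reversible), c(9L, 10L, 19L, 20L))
  expect_identical(dim(NET$S), c(9L, 25L))
})

test_that("single-flux examples match the rate laws", {
  p <- setNames(rep(0, 29), NET$param_names)
  # first-order DHSph1P degradation at its reference rate
  p["kf6"] <- 0.528
  st <- setNames(rep(0, 9), NET$dynamic); st["DHSph1P"] <- 1
  u <- setNames(rep(2, 13), NET$inputs)
  v <- flux_vector(NET, st, u, p)
  expect_equal(v[6], 0.528)
  expect_equal(sum(abs(v[-6])), 0)

  # zero state and inputs: all fluxes vanish
  expect_equal(flux_vector(NET, rep(0, 9), rep(0, 13), rand_params()),
               rep(0, 25))

  # detailed balance at the symmetric point for a reversible reaction
  p2 <- setNames(rep(0, 29), NET$param_names)
  p2["kf9"] <- p2["kb9"] <- 0.7
  v2 <- flux_vector(NET, rep(1, 9), rep(1, 13), p2)
  expect_equal(v2[9], 0)
})

test_that("rhs matches a single-term hand computation", {
  p <- setNames(rep(0, 29), NET$param_names)
  p["kf4"] <- 1
  u <- setNames(rep(0, 13), NET$inputs)
  u["DHSph"] <- 2; u["Sphk1"] <- 1.5
  r <- network_rhs(NET, rep(0, 9), u, p)
  expect_equal(unname(r["DHSph1P"]), 3.0)
  expect_equal(sum(abs(r[setdiff(NET$dynamic, "DHSph1P")])), 0)
})

test_that("rhs is linear and homogeneous in the parameters", {
  set.seed(11)
  for (i in 1:10) {
    st <- rand_state(); u <- rand_inputs()
    b1 <- rand_params(); b2 <- rand_params()
    expect_equal(network_rhs(NET, st, u, b1 + b2),
                 network_rhs(NET, st, u, b1) + network_rhs(NET, st, u, b2),
                 tolerance = 1e-12)
    expect_equal(network_rhs(NET, st, u, 2 * b1),
                 2 * network_rhs(NET, st, u, b1), tolerance = 1e-12)
  }
})

test_that("rhs equals the hand-transcribed balance equations", {
  set.seed(21)
  p <- raw264_params()
  for (i in 1:100) {
    st <- rand_state(); u <- rand_inputs()
    expect_equal(network_rhs(NET, st, u, p), oracle_rhs(st, u, p),
                 tolerance = 1e-12)
  }
})

test_that("stoichiometry columns read off the reaction table", {
  S <- stoichiometry_matrix(NET)
  # v6: pure loss of DHSph1P
  expect_equal(unname(S[, 6]), c(0, -1, 0, 0, 0, 0, 0, 0, 0))
  # v16: enzyme-free desaturation DHCer -> Cer
  expect_equal(unname(S["C16DHCer", 16]), -1L)
  expect_equal(unname(S["C16Cer", 16]), 1L)
  expect_equal(sum(abs(S[, 16])), 2L)
})

test_that("design block reproduces rhs for arbitrary parameters", {
  set.seed(31)
  for (i in 1:50) {
    st <- rand_state(); u <- rand_inputs(); b <- rand_params()
    D <- design_block(NET, st, u)
    expect_equal(as.vector(D %*% b),
                 unname(network_rhs(NET, st, u, b)), tolerance = 1e-12)
  }
})

test_that("basis fluxes are the bare factor products", {
  st <- setNames(rep(0, 9), NET$dynamic); st["DHSph1P"] <- 2
  u <- setNames(rep(0, 13), NET$inputs)
  bas <- basis_fluxes(NET, st, u)
  expect_equal(unname(bas["kf6"]), 2)
  expect_equal(basis_fluxes(NET, rep(0, 9), rep(0, 13)),
               setNames(rep(0, 29), NET$param_names))
})

test_that("irreversible fluxes stay nonnegative on nonnegative inputs", {
  set.seed(41)
  irrev <- which(!NET$reversible)
  for (i in 1:25) {
    v <- flux_vector(NET, rand_state(), rand_inputs(), rand_params())
    expect_true(all(v[irrev] >= 0))
  }
})

test_that("zeroing a gene fold silences exactly its reactions", {
  set.seed(51)
  p <- setNames(runif(29, 0.1, 1), NET$param_names)
  st <- setNames(runif(9, 0.5, 2), NET$dynamic)
  for (g in NET$genes) {
    u <- setNames(runif(13, 0.5, 2), NET$inputs)
    u[NET$genes] <- 1
    u[g] <- 0
    v <- flux_vector(NET, st, u, p)
    uses_gene <- vapply(NET$reactions, function(r)
      g %in% c(r$forward_factors, r$backward_factors), TRUE)
    expect_equal(sum(abs(v[uses_gene])), 0)
    expect_true(all(v[!uses_gene] != 0))
  }
})

test_that("invalid states and names are rejected with the offender named", {
  st <- setNames(rep(1, 9), NET$dynamic); st["C16Cer"] <- -1
  expect_error(flux_vector(NET, st, rep(1, 13), raw264_params()), "C16Cer")
  u <- setNames(rep(1, 13), c(NET$inputs[-13], "NotAGene"))
  expect_error(flux_vector(NET, rep(1, 9), u, raw264_params()), "Degs1")
  expect_error(check_params <- flux_vector(NET, rep(1, 9), rep(1, 13),
                                           rep(-1, 29)), "negative")
})
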