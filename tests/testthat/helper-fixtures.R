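# Shared fixtures, built once per test run. The recovery fit is by far the
# most expensive object and is reused by several acceptance checks.

NET <- load_network()

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

noise_free_truth <- function(...)
  synthetic_truth(noise = 0, reps_bio = 1, reps_tech = 1, seed = 1, ...)

noise_free_dataset <- function()
  fixture("noise_free_dataset",
          function() generate_dataset(NET, noise_free_truth()))

# the headline two-step recovery run on noise-free dual-condition data
recovery_fit <- function() {
  fixture("recovery_fit", function() {
    ds <- noise_free_dataset()
    sys <- build_regression_system(NET, ds)
    b0 <- linear_estimate(sys)
    list(linear = b0, fit = refine_nonlinear(NET, ds, b0))
  })
}

noisy_dataset <- function()
  fixture("noisy_dataset",
          function() generate_dataset(NET, synthetic_truth(noise = 0.25,
                                                           seed = 7)))

# a dataset with all-constant inputs (control levels) for both conditions,
# genes pinned to 1 -- used for condition-equivalence checks
flat_dataset <- function() {
  fixture("flat_dataset", function() {
    prof <- default_input_profiles("control")
    truth <- synthetic_truth(
      noise = 0, reps_bio = 1, reps_tech = 1,
      profiles = list(control = prof, treatment = prof))
    generate_dataset(NET, truth)
  })
}

# economical fit settings for tests that only need a rough optimum
quick_config <- function(...)
  fit_config(maxiter = 15, restarts = 1, sim_rtol = 1e-5, sim_atol = 1e-8,
             epsfcn = 1e-4, ...)
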