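# sphingokinetics

Kinetic modelling of the C16-branch of sphingolipid metabolism in
KLA-stimulated RAW264.7 macrophages, for systems biologists who want to turn
paired lipidomics and transcriptomics time-courses into mass-action rate
constants — and to interrogate the resulting model.

## What it implements

The C16 network couples nine dynamic metabolites (C16 DHCer, DHSph1P,
C16 DHGlcCer, C16 DHSM, C16 DHCerP, C16 Cer, C16 CerP, C16 SM, C16 GlcCer)
through 25 mass-action reactions (29 rate constants; the two sphingomyelin
synthase steps on each branch are reversible), driven by four measured input
lipids (DHSph, CoA16, C16 DG, C16 GPCho) and nine enzyme transcripts applied
as fold-changes with a 3-hour protein-synthesis delay, p(t) = g(t − 3).
Every flux is linear in its rate constant, so the balance equations admit
the decomposition dx/dt = D(x, u) · b, which the estimator exploits:

1. **Linear step** — backward-difference derivatives of the measured
   courses against the design matrix evaluated at the interval right
   endpoints; nonnegative least squares (Lawson–Hanson) gives a
   deterministic initial guess.
2. **Nonlinear step** — bound-constrained Levenberg–Marquardt on the full
   ODE predictions, minimizing
   Σ w_j² (ŷ_ij − y_ij)² / M_i², with per-species max normalization M_i and
   time-interval weights w_j = Δt_j^{1/4}, co-optimizing the initial
   conditions inside a window around the measured t = 0 values.

Around the estimator: SEM-resampling parameter uncertainty (k re-fits of
perturbed datasets), one-at-a-time parametric sensitivity (fold-change of
trajectory maxima over a 0.5–2× ratio grid), eigenvalue time-scale
classification of the steady-state Jacobian (fast ~1 hr / medium ~10 hr /
slow ~100 hr pools), a per-DNA → per-protein rate-unit converter, and a
synthetic-data generator that reproduces the experimental design (8 samples
over 24 h, two conditions, 3×3 replicates, 20–30% fractional SEM) for
parameter-recovery validation.

## Worked example

```r
library(sphingokinetics)

net <- load_network()                      # packaged C16 network definition
truth <- synthetic_truth(noise = 0, reps_bio = 1, reps_tech = 1)
dataset <- generate_dataset(net, truth)    # noise-free dual-condition data

sys <- build_regression_system(net, dataset)
b0  <- linear_estimate(sys)                # step 1
fit <- refine_nonlinear(net, dataset, b0)  # step 2
round(fit$params[c("kf1", "kf6", "kb9", "kf16")], 4)
#>     kf1     kf6     kb9    kf16
#> 13.0021  0.5280  1.7262  0.8029
fit$objective
#> [1] 8.69529e-09
```

The generating values were kf1 = 13, kf6 = 0.528, kb9 = 1.7176,
kf16 = 0.803: the estimator recovers them to a fraction of a percent from
data it has only seen through the 8-point sampling grid, and the weighted
fit error collapses to the ODE-solver floor.

Downstream analyses take the fitted constants directly:

```r
sens <- sensitivity_scan(net, fit$params, dataset, "kf16")
round(sens$fold_change["2", c("C16DHCer", "C16Cer")], 3)
#> C16DHCer   C16Cer
#>    0.542    1.063   # doubling kf16 drains DHCer, feeds Cer

ts <- timescale_classification(net, fit$params, dataset,
                               ss = suppressWarnings(
                                 steady_state(net, fit$params, dataset)))
subset(ts$table, metabolite %in% c("C16Cer", "C16SM"))
#>   metabolite  eigenvalue characteristic_time_hr category
#> 6     C16Cer -1.11823552               0.894266     fast
#> 8      C16SM -0.01067758              93.654205     slow
```

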