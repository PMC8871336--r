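# aifmem

Blind arterial input function (AIF) estimation by maximum entropy for
DCE-MRI kinetic modelling.

## The problem

Quantitative analysis of dynamic contrast-enhanced MRI fits a
two-compartment kinetic model to tissue concentration curves:

    Ctis(t) = K1 * integral_0^t Cp(u) * exp(-K2 (t - u)) du

where `Cp(t)` is the arterial plasma concentration (the AIF), and `K1`
(1/min) and `K2` (1/min) are the transfer rate constants of interest.
Measuring `Cp(t)` directly requires arterial blood sampling or a reliable
artery in the field of view; this package instead *estimates* the AIF
blindly from the concentration data by maximum-entropy density estimation,
then recovers `K1`, `K2` by linear least squares (LLSQ) or maximum a
posteriori (MAP) inference.

The maximum-entropy model is the exponential family

    f(x) = exp(-lambda_0 - sum_k lambda_k * phi_k(x))

whose multipliers are chosen so the density reproduces the sample moments
`E[phi_k]`. For the function set `{1, log x, x^p}` this family contains the
Weibull distribution exactly, which makes Weibull AIF shapes a natural
ground truth: six classical Weibull estimators (empirical, method of
moments, MLE, binned MMLE, NLSM and the maximum-entropy route) are included
for comparison, together with a TLBO (teaching-learning-based optimization)
solver as a derivative-free alternative to the damped-Newton dual descent.

## Worked example

Simulate a small study, estimate the AIF density for one patient, and fit
the kinetic parameters:

```r
library(aifmem)

study <- simulate_study(study_config(n_patients = 3, seed = 11))
study
#> Simulated DCE-MRI study: 3 patients, 46 frames (seed 11)
#>   true K1 in [0.377, 0.911], K2 in [0.010, 0.351] 1/min

p   <- study$patients[[1]]
fit <- fit_aif_density(p$cp)
fit$density
#> Maximum-entropy density fit
#>   f(x) = exp(-1.2534*1 - 0.5084*log(x) - 0.0172*x^3)
#>   support [0.003584, 4.761], solver dual_descent, converged: TRUE
#>   max constraint residual: 1.37e-13

kinetic_fit(p$cp, p$ctis, method = "map")
#> Two-compartment kinetic fit (map)
#>   K1 = 0.3691 1/min, K2 = 0.0095 1/min
#>   residual norm: 0.5246
# (truth for this patient: K1 = 0.377, K2 = 0.010)
```

Compare the Weibull estimators on a known sample:

```r
x <- weibull_dist(2.6, 1.738)$sample(10000, seed = 3)
compare_weibull_estimators(x)
#>   method     k     c
#> 1     EM 2.619 1.744
#> 2    MOM 2.607 1.744
#> 3    MLE 2.613 1.745
#> 4   MMLE 2.609 1.744
#> 5   NLSM 2.588 1.746
#> 6   MMEM 2.422 2.239
```

The MMEM row maps fitted multipliers back to `(k, c)` under the fixed
`{1, log x, x^3}` function set, so it is biased when the sample's shape
parameter differs from the assumed exponent — see the vignette.

The end-to-end pipeline (simulate or read curves, fit densities, fit
kinetics, evaluate) writes stamped CSV/JSON artifacts:

```r
res <- run_pipeline(pipeline_config(out_dir = "out", seed = 7))
```

A command-line wrapper around the same stages is installed at
`system.file("cli", "aifmem.R", package = "aifmem")` with subcommands
`simulate`, `fit-aif`, `fit-kinetics`, `evaluate` and `reproduce-example`.

## Package layout

- `R/synthetic.R` — time grids, Weibull/biexponential AIF shapes, study
  simulation, T1-to-concentration conversion
- `R/maxent.R` — known functions, moment constraints, multiplier solving
  (dual descent and TLBO), blind AIF density fitting
- `R/tlbo.R` — teaching-learning-based optimizer
- `R/weibull.R` — distribution object, six estimators, the
  Weibull/multiplier mapping
- `R/kinetic.R` — tissue response convolution, Murase linearization, LLSQ
- `R/map.R` — Bayesian MAP fit with negative-entropy prior
- `R/metrics.R` — KL divergence, entropy, fit metrics, estimator reports
- `R/io.R` — CSV/JSON interfaces and the pipeline
- `vignettes/aifmem-methods.Rmd` — model, assumptions and numerical choices
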