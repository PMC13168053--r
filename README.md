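# cascadefit

Calibration and uncertainty quantification for ODE models of MEK-isoform
ERK signaling, using **hybrid data**: conventional quantitative time series
*and* formalized qualitative comparison statements ("readout A in mutant X
is lower than in the parental line at 300 s").

The package is aimed at systems-biology modelers who have a mechanistic
model, a little quantitative data, and a lot of ordinal/binary knowledge,
and who want maximum-likelihood fits, identifiability analysis, and
Bayesian posteriors that use all of it.

## What is inside

* **Model family** — a mass-action reaction network of
  EGFR → SOS1 → RAS → RAF → MEK1/2 → ERK signaling with ERK-mediated
  negative feedback on SOS1 and on MEK1-T292 (PHP phosphatase recruitment
  acting in cis and on the dimer partner).  Species and reactions are
  expanded programmatically from rules (WT: 58 species, 279 reactions),
  with structural variants for MEK1 knockout (KO) and the N78G, T292A,
  T292D mutations.  Deterministic simulation via `deSolve::lsoda` with a
  compiled right-hand side and analytic Jacobian, plus an independent
  fixed-step RK4 oracle.
* **Property language** — parse/evaluate/write statements of the form
  `WT.MEK_pRDS at time=300 < N78G.MEK_pRDS at time=300`
  (PROP files), and EXP-style time-series tables with `nan` for missing
  values.
* **Hybrid likelihood** — for quantitative records `y_i` in (0, 1] with
  homoscedastic Gaussian noise and model output `f(c_i, θ)` (copy number ×
  scaling factor), and binary outcomes `z_i ~ Bernoulli(p_i)` with the
  logistic link `p_i = 1/(1+exp(−δ_i/s_i))` on the raw copy-number
  difference `δ_i`:

  F(θ) = F_quant + F_qual,
  F_quant = Σ_i (y_i − f(c_i,θ))²,
  F_qual = Σ_i w_i [max(0, −δ_i) + (1 − z_i) δ_i],  w_i = 1/s_i,

  where each hinge term approximates the exact logistic negative
  log-likelihood term to within log 2, so minimizing F is
  maximum-likelihood estimation.
* **Global fit** — differential evolution (rand/1/bin) under box
  constraints, log10 search space for wide boxes, reflection at bounds,
  bitwise-reproducible seeded runs, multistart.
* **Profile likelihood** — warm-started profiles with a
  χ²(1)-based practical-identifiability call and profile confidence
  intervals.
* **Bayesian UQ** — adaptive Metropolis over (d3, u3, three scaling
  factors, σ), rank-normalized split-Rhat and bulk/tail ESS diagnostics,
  posterior predictive bands, per-statement satisfaction fractions.
* **Synthetic data** — study-shaped bundles (18 WT measurements, 90
  statements across 5 variants) generated from known ground truth under
  the stated noise models, so the whole pipeline is testable end to end.

## Worked example

```r
library(cascadefit)

net <- build_network("WT")
net
#> cascade_network [WT]: 58 species, 279 reactions

traj <- simulate_cascade(net, default_params(), c(60, 300, 1800, 3600))
round(traj$observables)
#>   time MEK_pRDS pERK1_2_wt  pEGFR  pSOS1
#> 1   60     1727      93866 244997    274
#> 2  300   104726    2799203 384964  76692
#> 3 1800     7068    1802470  90929 138910
#> 4 3600     2849    1187334  15331 140309
```

Phospho-ERK peaks near 300 s (2.8M of 3M ERK molecules doubly
phosphorylated), receptor signal decays through ligand-induced
degradation, and feedback-phosphorylated SOS1 accumulates — the
qualitative shape the cascade is known for.

```r
bundle <- make_bundle(seed = 5, truth = ground_truth(sigma = 0))
bundle
#> cascade_bundle: 18 quantitative records (0 missing), 90 statements (deterministic)

problem <- cascade_problem(bundle$data, bundle$props)
bd <- objective_breakdown(bundle$truth_effective$theta, problem)
#> objective at ground truth: 1.74e-12 (Fquant 1.74e-12, Fqual 0)

fit <- fit_cascade(problem, free = c("d3", "u3"),
                   pinned = bundle$truth_effective$theta,
                   config = de_config(pop_size = 16, generations = 80,
                                      seed = 3, tol = 1e-4))
fit
#> cascade_fit: best objective 7.7891e-05 after 320 evaluations
signif(fit$theta, 3)
#>       d3       u3
#> 0.000992 0.001010
```

A noise-free bundle is reproduced exactly by its ground truth (objective
~0, all 90 statements satisfied), and a two-parameter refit recovers the
true rate constants (both 1e-3) to within 1%.

A command-line front end over the same pipeline lives at
`inst/cli/cascadefit.R` with subcommands `simulate`, `fit`, `profile`,
`sample`, `check`, and `synth` driven by a flat key-value config file.

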