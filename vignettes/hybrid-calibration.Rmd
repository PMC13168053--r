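---
title: "Calibrating MEK-isoform ERK signaling models with hybrid quantitative and qualitative data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating MEK-isoform ERK signaling models with hybrid quantitative and qualitative data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Much of what is known about MEK-isoform biology comes from low-resolution
case-control comparisons: a readout in a mutant cell line is scored *up* or
*down* relative to the parental line at a handful of time points.  Such
binary orderings are usually discarded when ODE models of the RAS/RAF/MEK/ERK
cascade are calibrated, even though for mutant lines they are often the
*only* data available.  `cascadefit` implements a complete, reusable pipeline
that treats those orderings as first-class observations alongside
conventional time-series measurements: a deterministic mass-action model of
EGF-stimulated ERK activation in five cellular backgrounds, a small formal
language for comparison statements, a likelihood combining both data types,
global optimization, profile-likelihood identifiability analysis, and
adaptive MCMC for Bayesian uncertainty quantification.

## The model family

The network describes EGFR → SOS1 → RAS → RAF → MEK1/2 → ERK signaling with
two layers of negative feedback delivered by doubly phosphorylated ERK:
phosphorylation of SOS1 (which can then no longer activate RAS) and
phosphorylation of MEK1 on T292, which recruits the PHP phosphatase.  A
PHP-bound MEK1 protomer strips activation-site phosphate from its own
protomer *and from its dimer partner* — this in-trans action is the
mechanistic reason MEK1-containing heterodimers let the T292 feedback reach
MEK2, and hence the reason the dimerization-dead N78G mutant escapes the
feedback.

Species are generated programmatically: a MEK1 protomer carries an
activation-site state, a T292 state, and PHP occupancy; MEK2 carries only
the activation-site state; dimerization is restricted to monomers and
preserves protomer states, with dimer labels canonicalized so that the pair
(A, B) equals (B, A).  Applying the rules to a fixpoint yields 58 species
and 279 mass-action reactions for the parental (WT) network.  Four variants
are derived structurally rather than only numerically:

* **KO** — MEK1 knockout: no MEK1 seed species (19 species remain);
* **N78G** — no MEK1 homo- or heterodimerization (`b2 = b4 = 0`);
* **T292A** — no ERK-mediated T292 phosphorylation (`p4 = 0`), so the
  feedback mark is unreachable;
* **T292D** — phosphomimetic: every MEK1 starts T292-phosphorylated and the
  mark is permanent (`u4 = 0`).

Two conventions matter when comparing against other realizations of the
same biology.  First, for a homodimerization step A + A → B the flux is
`k[A]^2` and each event consumes two A.  Second, there is no pre-stimulation
equilibration: the state at t = 0 *is* the tabulated initial copy numbers,
receptor/SOS1 turnover (`s1`, `d1`, `s2`, `d2`) is inert, and ligand
engagement switches on at t = 0 with rate `c1L`.  Feedback phosphorylation
of SOS1 acts on the free pool, and only unphosphorylated SOS1 binds the
receptor; this realizes "phospho-SOS1 cannot activate RAS" with a finite
species set.

Integration uses `deSolve::lsoda` with a compiled right-hand side and an
analytic Jacobian.  Reporting tolerances default to `rtol = 1e-8`,
`atol = 1e-2` molecules; repeated objective evaluations inside optimization
and sampling use `rtol = 1e-5`, `atol = 1`, which agrees with the tight
setting to ~3 parts in 10^4 on all observables while being roughly twice as
fast.  A fixed-step RK4 integrator (dt = 1 ms), written independently of
the adaptive path, serves as the numerical oracle in the test suite.

## The likelihood

Quantitative data are relative intensities `y_i` in (0, 1], one per
(observable, time) pair, WT only.  With homoscedastic Gaussian noise the
negative log-likelihood is

    (n/2) log(2 pi sigma^2) + F_quant / (2 sigma^2),
    F_quant = sum_i (y_i - f(c_i, theta))^2,

where `f` is the simulated copy number times an adjustable scaling factor
(one each for pEGFR, pERK, pSOS1).  Missing values (`nan` in EXP files)
drop out of both the sum and `n`.

A qualitative observation is the binary outcome `z_i` of comparing two
conditions; its model counterpart is the sign of the output difference
`delta_i = g(a_i) - g(b_i)` in raw copy numbers (cross-condition
comparisons of the same observable are scale-free, so scaling factors never
enter).  Modeling `z_i ~ Bernoulli(p_i)` with the logistic link
`p_i = 1/(1 + exp(-delta_i/s_i))` gives the exact term

    log(1 + exp(-delta_i/s_i)) + (1 - z_i) * delta_i/s_i,

computed with the `log1p`/`max` decomposition so saturated statements
neither overflow nor lose their linear tail.  Replacing it by the hinge
penalty `w_i [max(0, -delta_i) + (1 - z_i) delta_i]` with `w_i = 1/s_i`
changes each term by at most `log 2` (exactly `log 2` at `delta = 0`), so
minimizing `F = F_quant + F_qual` is maximum-likelihood estimation up to
that bounded gap.  Ties use `H(0) = 1`: an exact tie satisfies ">=" and
violates "<".  The default statement scale is `s_i = 1` (so `w_i = 1`),
overridable per statement (`weight=`) or per file.

## Global fitting

Differential evolution (rand/1/bin) under box constraints: population 50,
mutation factor 0.85, crossover 0.7, 500 generations by default, all
configurable.  Coordinates whose bounds are positive and span at least a
decade are searched in log10 space; initialization is uniform in the search
space (log-uniform on the original scale).  Out-of-bounds mutant
coordinates are reflected back inside rather than clipped, which avoids
pile-up on the box faces.  Objective evaluations are pure and independent —
the contract a parallel dispatcher needs — and seeded runs are bitwise
reproducible.  The 18 tabulated quantities that were fixed in the original
study (turnover bookkeeping and initial copy numbers) are refused as free
parameters.

## Profile likelihood

A profile holds one parameter fixed on a grid (default: 20 log-spaced
points across its box) and re-minimizes everything else, sweeping outward
from the MLE with warm starts.  The identifiability call converts the
objective to the -log L scale with the plug-in estimate
`sigma^2 = F_quant(MLE)/n` plus the exact logistic term, then takes
`{grid : nll <= min + 1.92}` (chi-square(1) 95%/2) as the profile
confidence set; a parameter is practically identifiable iff that set
excludes both grid endpoints.  The threshold is a configuration choice —
the raw curves are always reported so any other threshold can be applied
post hoc.

## Bayesian uncertainty quantification

Following the study design, sampling is restricted to `d3` (degradation of
ligand-bound receptor dimers), `u3` (reversal of SOS1 feedback
phosphorylation), the three scaling factors, and `sigma`, with everything
else pinned.  The sampler is adaptive random-walk Metropolis: rate
constants and scaling factors move in log10 coordinates (the box prior is
kept uniform on the *original* scale by adding the Jacobian to the target);
`sigma` moves linearly.  After a burn-in phase with scalar step-size tuning
toward a 15–40% acceptance band, the proposal covariance is re-estimated
during a dedicated adaptation phase as `(2.38^2/d) * cov(history) + jitter`
and then frozen, so production draws form a fixed-kernel Markov chain.
Default lengths are 25k/25k/250k over five chains.  Convergence is
summarized by rank-normalized split-Rhat (maximum of bulk and folded forms)
and bulk/tail effective sample sizes using Geyer's initial positive
monotone sequence on FFT autocorrelations — implemented here directly, and
validated in the test suite on analytic targets (iid chains give
Rhat ~ 1 and ESS ~ n; disjoint chains are flagged).

Posterior predictive bands propagate parametric uncertainty only (no noise
injection): every retained draw (thinned to a configurable cap) is
simulated and summarized by per-time medians and nested central quantile
bands from 10% to 95%, per variant and observable.  Per-statement
satisfaction fractions across draws reproduce the constraint-level view of
posterior uncertainty.

## The synthetic-data generator

All tests run on study-shaped synthetic data generated from a known ground
truth: the tabulated reference rate constants, scaling factors of
4.5e-5 (pEGFR; the geometric middle of its box, since the published
best-fit value lies outside the printed box), 3.2e-6 (pERK), and 1.1e-4
(pSOS1), and noise scale `sigma* = 1` AU.  Quantitative data: simulate WT,
scale, add N(0, sigma*^2), then divide each observable series by its
maximum so values lie in (0, 1] (floored at 1e-6), emulating relative
intensity measurements — 3 observables x 6 times = 18 records at
t = 60, 300, 600, 1200, 1800, 3600 s, a grid chosen to span the rise, peak,
and relaxation of the stimulated cascade.  Qualitative data: 90 statements
— all 10 variant pairs at 300/1800/3600 s for phospho-MEK and phospho-ERK
(60), plus within-variant time comparisons (30) — with outcomes either the
sign of the true difference (deterministic mode) or Bernoulli draws through
the logistic link (stochastic mode).

Max-normalization has an important consequence: the *effective* scaling
factor of a normalized series is pinned near 1/(peak copy number),
regardless of the nominal scale, and the effective noise is
`sigma*/max`.  The bundle therefore records an effective ground truth
(which reproduces a noise-free bundle exactly, objective 0), and posterior
analyses of bundles use `bundle_bayes_bounds()`: the default absolute scale
boxes keep their multiplicative widths but are re-centered on the bundle's
effective scales.  Without this, the scale prior and the data normalization
contradict each other and `sigma` absorbs the mismatch.

Two honest caveats, both visible in the package's own experiments.  First,
deterministic-mode statements can be *near-ties*: at the reference
parameters, WT and KO phospho-ERK at t = 300 s differ by ~10 molecules out
of ~2.8 million, so the generated statement places the ground truth
essentially on the boundary of the feasible region, and marginal credible
intervals for parameters whose perturbation flips such a statement (notably
`d3`) can sit with the truth near one CI edge.  This is a property of
hard, noise-free ordinal data — the study's own posterior constraint
fractions below 1 reflect the same phenomenon — not of the sampler;
recovery of the same parameters by maximum likelihood is accurate to a few
percent.  Second, the generator emulates neither densitometry saturation
nor blot-specific artifacts, so passing tests say nothing about those
features of real data.

## Problem sizes used by the tests and the acceptance script

Analyses are scaled to desk size as the package's own experimental design:
recovery studies use 10 seeded replicates with only `d3`/`u3` free
(population 12, 30 generations); profiles use single-coordinate
re-optimization (population 8, 25 generations) on the default 20-point
bounds-spanning grid for identifiability calls and on matched local grids
(0.03 decades per step around the MLE) for interval widths, since the d3
profile is too sharp for the default grid to resolve; MCMC recovery
replicates in the test suite use chains of 1k burn-in / 1k adaptation / 8k
production (the acceptance script uses 2k/2k/10k), with posterior
predictive checks over 300 thinned draws — fewer under-resolves the 2.5%
tails that bound a 95% band.  The analytic
sampler checks use a 2-D standard normal target at 10k production draws per
chain.

## Known limitations

* The reaction inventory is a reconstruction from the tabulated parameter
  descriptions and mutation annotations; published rule-based encodings of
  the same biology may differ in detail (e.g., whether PHP acts on the
  dimer partner, or the order of SOS1 binding), so absolute trajectories
  are comparable only qualitatively.
* Full temporal logic (eventually/always operators, window thresholds,
  peak-time constraints) is out of scope; the property language covers
  point-in-time binary comparisons only.
* The sampler is single-kernel adaptive Metropolis; no tempering or
  gradient-based methods, and no model-evidence estimation.
* EGFR/SOS1 synthesis and turnover are carried as inert parameters; the
  receptor pool only decays after stimulation.
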