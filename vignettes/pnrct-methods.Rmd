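---
title: "Models and simulation methodology for partially nested trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and simulation methodology for partially nested trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnrct)
```

## The design problem

In a partially nested randomised controlled trial (pnRCT) participants are
individually randomised, but the intervention is delivered in groups or by a
shared care provider, so outcomes are correlated *within clusters in one arm
only*. The control arm ("usual care") has no cluster structure. Ignoring the
clustering understates the uncertainty of the intervention effect; imposing
full two-arm clustering misstates the design in the other direction. `pnrct`
implements the data-generating mechanism, the candidate analysis models and
the Monte Carlo machinery needed to study this trade-off quantitatively.

## Data-generating mechanism

A scenario is `(c, m, θ, ρ, γ)`: `c` intervention-arm clusters of `m`
participants, matched by an equal-size non-clustered control arm (1:1
randomisation with fixed equal arm totals; the balanced allocation is part of
the study conditions, not an option). With `u_j ~ N(0,1)` cluster effects and
`z_ij ~ N(0,1)` individual deviates,

* intervention arm: `y_ij = θ + u_j √ρ + z_ij √(1−ρ)`
* control arm:      `y_ij = z_ij √(γ(1−ρ))`

and the intercept is fixed at zero. This normalisation makes the
intervention-arm marginal variance exactly 1, so `ρ` is both the
between-cluster variance and the intracluster correlation coefficient (ICC),
and under `γ = 1` the two arms are homoscedastic at total variance 1 and `θ`
is a standardised effect size. `γ` is the ratio of control-arm to
intervention-arm *individual-level* variance: `γ = 4` means control outcomes
are four times as variable as the residual variation around cluster means.

Replicate `r` of a scenario draws its own random substream: a master seed
deterministically yields a table of distinct substream seeds
(`sample.int()` under the master seed) and replicate `r` uses the `r`-th
entry. The same applies one level up, each scenario of a grid drawing its
substream from the grid seed and its scenario index. Consequently results
are bit-reproducible and independent of execution order, and two replicates
never share a stream.

What the generator deliberately does **not** emulate: varying cluster sizes,
attrition, covariates, non-normal outcomes, or latent low-level clustering
in the control arm. Operating characteristics estimated here therefore speak
to idealised balanced trials; real pnRCTs with very unequal cluster sizes or
skewed outcomes may behave worse than these results suggest.

## The candidate models

All models share the fixed-effect structure `β0 + θ·t` and are fitted by
restricted maximum likelihood (REML):

| Model | Random structure | Residuals |
|---|---|---|
| `linear` | none | common `σ²_ε` |
| `fully-clustered` | cluster intercept, both arms | common `σ²_ε` |
| `pn-hom` | cluster intercept, intervention arm only | common `σ²_ε` |
| `pn-het` | cluster intercept, intervention arm only | `σ²_ε` (intervention), `σ²_r` (control) |

The fully clustered model needs cluster labels in the control arm, which the
design does not provide; `control_coding()` supplies the three conventions
(singletons, one large cluster, `k` random pseudo clusters of equal size,
default `k = c`). For the partially nested models the labels are
mathematically irrelevant — the random intercept enters only through the
intervention arm — and the implementation is exactly invariant to the
coding choice. Pseudo-cluster assignment is a seeded uniform permutation;
because control outcomes are exchangeable, the assignment rule can change
individual replicates but no distributional property. The model ICC is
`ρ̂ = σ̂²_u / (σ̂²_u + σ̂²_ε)`, with `σ̂²_ε` the intervention-arm residual
variance under `pn-het`.

## REML by block compound symmetry

Every model's marginal covariance is block diagonal, each block
`σ² I + σ²_u J` for one cluster (or a 1×1 block for an independent row).
The package never forms an n×n matrix: determinants and inverses use

* `log|σ² I + σ²_u J| = (n_b − 1) log σ² + log(σ² + n_b σ²_u)`
* `(σ² I + σ²_u J)^{-1} = σ^{-2} (I − σ²_u/(σ² + n_b σ²_u) J)`

and, since arm membership is constant within a block, the whole restricted
log-likelihood reduces to a handful of scalar operations per distinct block
type. `reml_loglik()` exposes the criterion (with full constants, so values
are directly comparable to `logLik()` from other mixed-model software).

Maximisation profiles out a residual variance and searches the variance
*ratio* `φ = σ²_u/σ²_ε` on `[0, 1000]` by 1-D golden-section/parabolic
search. Working on the (bounded) variance-ratio scale rather than a log
scale is essential: the boundary `σ̂²_u = 0` must be attainable, because the
behaviour of the partially nested models at `ρ = 0` — conservative tests,
inflated mean ICC — is driven by the positive probability of boundary
estimates. Two closed forms bypass the search entirely:

* `linear`: `σ̂²_ε = RSS/(n − 2)` (the OLS estimator);
* `pn-het`: the criterion separates into an intervention-arm one-way layout
  plus an i.i.d. control sample, so on balanced data the REML estimates are
  the ANOVA estimators `σ̂²_ε = MSW`, `σ̂²_u = (MSB − MSW)/m` truncated at
  zero, and `σ̂²_r` is the control sample variance.

Numerical choices: search tolerance `1e-8` on `φ`; the boundary is declared
when the profiled criterion at 0 is within `1e-9` of the interior optimum;
residual variances below `1e-10`, or an outcome vector with zero residual
variation, flag the fit as non-converged (`converged = FALSE`, never an
error). A fit whose ratio hits the upper bound is likewise flagged. These
fits stay in the replicate records and enter the convergence-rate
denominator.

The variance-parameter covariance `A` used for the degrees of freedom is the
inverse *observed* information, a central-finite-difference Hessian of the
restricted log-likelihood on the variance scale (step
`1e-5 · max(σ̂, 1)`). An expected-information variant is not implemented;
for these models and sample sizes the observed information was always
adequate and matches `lmerTest`'s Satterthwaite df to ~4 figures.

## Satterthwaite degrees of freedom

For the intervention contrast with variance `v(σ) = [(X'V^{-1}X)^{-1}]_{22}`,

`ν = 2 v(σ̂)² / (g' A g)`, `g = ∂v/∂σ` (central differences),

and the test/CI use `t_ν`. Two special cases matter:

* `linear`: the algebra collapses exactly to `ν = n − 2`, returned
  analytically.
* boundary fits (`σ̂²_u = 0`): the boundary estimate is not an interior
  maximum, so its information row does not estimate a sampling variance.
  The package treats `σ²_u` as fixed and computes `g` and `A` over the
  interior parameters only. Under `pn-het` this reproduces the classical
  Welch–Satterthwaite two-sample df, and under `pn-hom` it collapses to the
  residual df — i.e. boundary replicates are analysed as if unclustered,
  which is exactly the source of the models' conservatism at `ρ = 0`.

If the information matrix is unusable even after the boundary reduction,
the residual df `n − 2` is used and flagged (`df_method`).

## Performance measures and aggregation

`run_scenario()` generates each replicate dataset once and fits every model
to it (paired comparisons). `summarize_scenario()` computes bias, MSE,
coverage, the 5% rejection rate (Type I error under `θ = 0`, power
otherwise), mean estimated ICC and the convergence rate; proportions carry
the binomial Monte Carlo standard error `√(p(1−p)/n)`. The denominator for
all measures is the converged replicates (configurable to all replicates);
convergence failures are rare (≥95% convergence across the design space)
so the choice is immaterial in practice. Grid-level summaries
(`aggregate_measure()`) are unweighted means and SDs *across scenario
means*, the usual convention for reporting factorial simulation studies;
coverage is reported under the alternative (`θ ∈ {0.2, 0.5}`).

## Problem sizes

The full factorial is `{3,6,12,24} × {5,10,20,30} × {0,0.2,0.5} ×
{0,0.01,0.05,0.1,0.2,0.3} × {0.25,0.5,1,2,4}` — 1440 scenarios. Because the
aggregate of interest is a mean over 80–960 scenarios, its Monte Carlo error
shrinks with both replicates and scenarios; modest replicate counts per
scenario already give aggregate errors an order of magnitude below the
between-scenario SDs. The package's own reproduction protocol
(`scripts/acceptance.R`) uses 1000 replicates per scenario for the linear
model (closed-form fits) and 100 for the mixed models; the test suite uses
25–200. At 100 replicates and 480 scenarios the MC SE of a mean rejection
rate near 0.05 is about 0.001.

## Known limitations

* Only the observed-information variance-parameter covariance is offered.
* The one-large-cluster fully clustered variant (model 2.2 in the study's
  numbering) is deliberately fitted as specified although `σ²_u` is weakly
  identified there; its pathological inference (severely conservative
  tests) is an exhibit, not a defect. Its exact Type I error at small ICC
  is sensitive to the optimiser's boundary behaviour: software that cannot
  attain `σ̂²_u = 0` (log-scale parameterisations) reports rates of
  essentially zero, while this package's boundary replicates fall back to
  OLS-like inference and keep the rate small but nonzero.
* Unequal cluster sizes are supported by the fitting code (the profiled
  search handles arbitrary block sizes) but not by the generator, and none
  of the reported operating characteristics cover them.
* No covariates, no ML (non-REML) fitting, no Kenward–Roger or
  between-within df.
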