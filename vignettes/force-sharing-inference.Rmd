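---
title: "Methods: the force-sharing model and its Bayesian estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the force-sharing model and its Bayesian estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forceshare)
```

## The model and its assumptions

A participant holds a static total force target $g$ with two fingers, one
per hand. Finger forces are modeled as independent Gaussians around the
motor commands, $x_i \sim N(u_i, (k_i u_i)^2)$ — *signal-dependent*
noise, with the coefficient of variation $k_i$ and the maximum voluntary
contraction $MVC_i$ characterizing each finger. The cost attributed to a
command pair is

$$J = \tilde\nu\,\mathbb E[(x_i + x_j - g)^2]
     + \tilde\lambda\,(u_i^2 + u_j^2)
     + \tilde\mu\left[\left(\tfrac{u_i}{MVC_i}\right)^2
     + \left(\tfrac{u_j}{MVC_j}\right)^2\right],$$

which expands to the quadratic
$\tilde\nu (u_i + u_j - g)^2 + a_i u_i^2 + a_j u_j^2$ with
$a_i = \tilde\nu k_i^2 + \tilde\lambda + \tilde\mu / MVC_i^2$. The raw
weights $(\nu, \lambda, \mu)$ are constrained to the unit simplex — the
cost is unit-free and only ratios matter — and divided by normalization
constants $b_\nu = \mathbb E[k_i^2 + k_j^2]$, $b_\lambda = 2$,
$b_\mu = \mathbb E[1/MVC_i^2 + 1/MVC_j^2]$ (sample means over the
analyzed participants), so that equal raw weights mean equal influence at
the optimum.

Setting the gradient to zero gives the unique minimizer

$$u_i^* = \frac{g\,a_j}{a_i + a_j + a_i a_j/\tilde\nu},\qquad
u_j^* = \frac{a_i}{a_j}\,u_i^*,$$

and the optimal share of finger $i$,
$c^* = a_j/(a_i + a_j)$, free of both $g$ and the weight scale. We note a
deliberate algebraic choice here: the command formula is implemented with
the *normalized* error weight $\tilde\nu$ and an explicit factor $g$,
which is the unique form consistent with minimizing the quadratic above —
`optimal_command()` is verified against an independent solve of the
normal equations to $10^{-8}$ in the test suite. Whether the raw or
normalized error weight sits in that denominator does not affect the
share $c^*$, the quantity the inference fits; only predicted absolute
forces (`predict_forces()`) would differ between the two readings, and we
use the internally consistent one.

The model is static per force level: no force trajectories, no temporal
dynamics, no fatigue or learning across trials.

## Calibration of finger profiles

`estimate_cv()` regresses each finger's per-level force SD on its mean
force *through the origin* — the noise model $\sigma = k u$ has no
intercept — by iteratively re-weighted least squares with bisquare
weights (tuning constant 4.685, the standard 95%-efficiency value;
convergence $10^{-8}$, at most 100 iterations, via `MASS::rlm`). Robust
weighting keeps a single corrupted level (a slip, a transient) from
biasing $k$; on exactly collinear data the OLS slope is returned
directly, since the IRLS scale degenerates there.

Trials are summarized over the middle 5 s of each 7 s hold (drop the
first 1.5 s of ramp-up and the last 0.5 s). The recordings carry no
explicit window definition, so this is the package's own choice, fixed
once; it is configurable (`window`, a fraction pair) and all estimates
are reported with the default. SDs use the $n-1$ denominator.

`estimate_mvc()` operationalizes "the largest force that can be reached
and maintained": the highest target whose windowed mean reaches at least
95% of the target (threshold configurable). Note the criterion can accept
a target up to $MVC/0.95$, a small upward tolerance that mirrors how a
maintained-force rule behaves in practice.

`cv_mvc_association()` quantifies the $k$–$MVC$ relationship across all
fingers and participants by OLS with intercept, reporting the slope, its
$t$ statistic on $n-2$ degrees of freedom, and Pearson $r$. With the
reference design of 14 participants and 4 fingers this gives
$t(54)$.

## Likelihood, priors, and the sampler

Observed shares $y_{lm}(n) \in (0,1)$ of the weaker finger are Gaussian
around the participant-specific $c^*_{lm}$ with variance
$\sigma^2_{y,lm}$; each force level $l$ is fitted independently. The
weight prior is uniform on the simplex; each variance has the
scale-invariant prior $\pi(\sigma^2) \propto \sigma^{-2}$ (an
$\mathrm{InvGa}(0,0)$ limit). A flat-variance variant
($\pi(\sigma^2)\propto 1$) is available via `prior = "flat"` and gives
essentially identical weight posteriors (asserted in the tests).

The simplex constraint makes the weights dependent a posteriori, so the
sampler works on stick-breaking coordinates
$w = \nu$, $z = \lambda/(1-\nu)$, which are independent $U(0,1)$ a
priori. Each cycle:

1. adaptive random-walk Metropolis update of $w$;
2. the same for $z$;
3. $\mu = (1-w)(1-z)$ deterministically;
4. exact Gibbs draw of every $\sigma^2_{y,lm}$ from its inverse-gamma
   full conditional $\mathrm{InvGa}(N_{lm}/2,\ SS_{lm}/2)$.

Proposals are made on the logit scale with the Jacobian correction in the
acceptance ratio — the bounded support then never truncates a proposal,
so adaptation is not distorted by boundary rejections. The proposal
log-SD adapts after every batch of 50 proposals by
$\pm\min(0.01, b^{-1/2})$ toward a target acceptance of 0.44 (the
univariate optimum); the diminishing step preserves ergodicity.
Initialization is $w = z = 0.5$ with variances at the per-participant
sample variance of $y$. Default run length is $T = 90000$ cycles with a
40000-cycle burn-in; the tests and the acceptance script use a reduced
$T = 9000/4000$, which the recovery and grid-quadrature checks show is
already accurate at their problem sizes.

Reduced models pin stick coordinates at vertices: $\nu = 0$ fixes
$w = 0$; $\mu = 0$ fixes $z = 1$; $\lambda = 0$ fixes $z = 0$;
single-term models sample only variances. A pooled variance
(`variance = "pooled"`, one $\sigma^2_{y,l}$ per level) replaces step 4
by a single draw.

Two implementation details matter numerically. Per-participant residual
sums of squares are computed from sufficient statistics
$(\sum y, \sum y^2, N)$, making each posterior evaluation $O(M)$
regardless of the number of observations. And participants with constant
$y$ are rejected at validation: their variance conditional is improper
the moment the model fits their share exactly, and failing loudly beats
sampling from a distribution that does not exist.

## Model comparison

`averaged_loglik()` is the arithmetic mean of the data log-likelihood
over retained samples — a posterior average of the log-likelihood, used
as the fit measure and for Bayes factors on its scale. It is *not* a true
marginal likelihood, and no bridge or path sampling is attempted; the
quantity is implemented exactly as the comparison it supports defines it.
For AIC, the maximum log-likelihood is taken as the maximum over retained
MCMC samples (no separate optimizer is defined for this posterior), and
the parameter count is `levels × (free weights + variance parameters)` —
2 free weights for the full model, 1 for two-term models, 0 for
single-term ones, plus $M$ (or 1, pooled) variances per level. Because
the averaged log-likelihood is not the maximized one, published
comparison tables built this way need not satisfy
$AIC = -2\,\overline{\log L} + 2d$ row by row; our table is exactly
self-consistent by construction
(`aic(max_loglik, d)`, asserted in the tests).

## What the synthetic generator emulates — and what it does not

`sample_population()` draws each finger's $(k, MVC)$ from zero-truncated
(optionally correlated) normals at the reference means and SDs of the
measured study population (e.g. left little $k$: 2.38% ± 1.2%, $MVC$:
12.71 ± 2.30 N; right index: 1.62% ± 0.59%, 23.29 ± 5.18 N; defaults
$M = 14$). `simulate_unimanual()` produces 7 s, 200 Hz recordings with a
1.5 s linear ramp and i.i.d. signal-dependent noise, plateauing at MVC
for over-target trials. `simulate_share_data()` draws
$y = c^* + N(0, \sigma_{y}^2)$ truncated to $(0,1)$ by resampling —
the direct generative reading of the observation model; under the
default noise scale ($\sigma_y = 0.05$, chosen so that share SDs sit in
the few-percent range seen in reliable isometric share measurements)
truncation touches well under 0.1% of draws, and the generator warns if
a scenario violates that.

The default scenario uses seven levels (4–28 N), 50 observations per
participant per level, a constant small error weight $\nu = 0.1$, and an
absolute-effort weight falling linearly 0.7 → 0.35 with the normalized
weight rising correspondingly — the qualitative crossing expected at
large forces.

Real recordings are not i.i.d. within a trial (tremor and drift induce
autocorrelation), shares may be non-Gaussian near the boundary, fatigue
couples trials, and what constitutes one observation $y_{lm}(n)$ is an
analysis choice (`N_lm` is a free scenario knob here). Passing tests on
generated data therefore demonstrate that the estimation machinery is
correct *under the model*, and that the pipeline recovers known truths at
realistic dimensions — not that the model is an adequate description of
any particular laboratory dataset.

## Verification strategy and problem sizes

The load-bearing correctness checks are all against independent oracles:
the closed-form commands against a direct solve of the quadratic's normal
equations (1000 random draws, $10^{-8}$); the sampler's $(w, z)$ medians
against dense $400 \times 400$ grid quadrature of the
variance-integrated posterior on a two-participant instance (within
0.02); the Gibbs draws against analytic inverse-gamma medians, moments
and quantiles (KS at 1%); the expanded cost against Monte-Carlo
evaluation of its expectation form; and the likelihood against naive
per-point summation. Recovery is checked at the study dimensions —
$M = 14$, $N_{lm} = 50$, truth $(\nu,\lambda,\mu) = (0.1, 0.7, 0.2)$,
100 seeded replicates at $T = 9000/4000$ — requiring 95% intervals to
cover each weight in at least 90 of 100 replicates with mean median-bias
below 0.05, and the level-wise crossing of $\lambda$ and $\mu$ must be
recovered with a perfect negative rank correlation under the default
scenario. All generators and chains are pure functions of their seeds;
identical seeds give bit-identical output, which the workflow tests
assert down to the written CSV artifacts.

## Known limitations

* The sampler updates $w$ and $z$ one at a time; for strongly correlated
  posteriors a joint proposal would mix faster. At the dimensions used
  here mixing is adequate (verified by the grid-quadrature and coverage
  checks), but very small $\sigma_y$ with few participants will slow it.
* The maximum log-likelihood for AIC is a posterior-sample maximum and so
  is a slightly conservative lower bound on the true maximum; with tens
  of thousands of retained samples the gap is negligible for the
  comparisons made.
* The MVC criterion inherits the granularity of the target ladder (2 N
  steps by default); $k$–$MVC$ association results use these discretized
  MVC values, as the measurement procedure does.
* Per-level independence is a modeling assumption, not a finding: the
  package deliberately provides no mechanism for sharing weight
  information across levels.
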