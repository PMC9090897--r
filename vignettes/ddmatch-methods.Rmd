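---
title: "Drift-diffusion modelling of shape–label matching: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drift-diffusion modelling of shape-label matching: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In a shape–label matching task, participants first learn arbitrary
associations between geometric shapes and people (e.g. triangle = you,
square = your best friend) and then judge, trial by trial, whether a
displayed shape–label pair matches the learned association.
*Self-prioritization* is the robust finding that matching judgements are
faster and more accurate for self-associated than other-associated
stimuli. This package implements a complete drift-diffusion analysis of
such data under manipulations of stimulus frequency: how often
self-related versus friend-related shapes appear, and whether the
participant's expectations about those frequencies are confirmed or
disconfirmed.

The package covers three study designs:

* **Equivalent context** (experiment 1): one 200-trial block, 50 trials
  per Shape Association (self/friend) × Matching Condition
  (matching/nonmatching) cell.
* **Confirmatory context** (experiment 2): two 200-trial blocks; in each,
  the frequent target contributes 150 trials (75 matching, 75
  nonmatching) and the infrequent target 50 (25/25), so each block keeps
  100 matching and 100 nonmatching trials and the response keys stay
  unbiased.
* **Dis-confirmatory context** (experiment 3): physically identical to
  experiment 2, but participants were led to expect the opposite
  frequencies; the analysis therefore adds trial-by-trial dynamics.

## The decision model

Each two-choice decision is modelled as a Wiener diffusion process with
within-trial noise scale fixed at $s = 1$: evidence accumulates from a
starting point between two absorbing boundaries until one is reached.
The models are *response coded* — the upper boundary is the "matching"
response and the lower boundary the "nonmatching" response, so drift
rates on nonmatching trials are expected to be negative. Parameters:

* $a > 0$ — boundary separation (response caution);
* $v$ — drift rate in evidence units/second (signed; quality and speed of
  evidence uptake);
* $z \in (0,1)$ — *relative* starting point; $z = 0.5$ is unbiased,
  $z > 0.5$ is a response bias towards "matching" (absolute start is
  $z\,a$);
* $t_0 \ge 0$ — non-decision time in seconds (encoding + motor);
* $sv$ — SD of a normal inter-trial distribution on $v$;
* $st$, $sz$ — full widths of uniform inter-trial distributions on $t_0$
  and $z$. Validity requires $z \pm sz/2$ inside $(0,1)$ and
  $t_0 - st/2 \ge 0$.

The first-passage-time density is evaluated with the standard dual-series
representation in normalised time $u = t/a^2$ — an image-method
small-time expansion and a spectral large-time expansion — selecting
whichever needs fewer terms at the truncation tolerance
(`series_tolerance`, default $10^{-7}$). The drift variability $sv$ is
marginalised in closed form; $st$ and $sz$ are marginalised by
Gauss–Legendre quadrature with `quadrature_nodes` nodes per dimension
(default 11, odd so the midpoint is always included; the smoother $z$
dimension can use fewer via `quadrature_nodes_z`). The $t_0$ nodes are
restricted to the physically admissible sub-interval
$[\max(0, t_0 - st/2),\ \min(\mathrm{rt}, t_0 + st/2)]$, weighted by its
share of the uniform range — the integrand is zero outside and kinked at
the edge, and removing the kink is what keeps small node counts
accurate. The boundary
absorption probability has the closed form
$P(\text{lower}) = \frac{e^{-2vza} - e^{-2va}}{1 - e^{-2va}}$, with a
series expansion guarding $|2va| < 10^{-8}$ and the exact limit
$P(\text{upper}) = z$ at $v = 0$.

Impossible observations (RT at or below the earliest possible
non-decision time) contribute a floored log density of $\log 10^{-10}$
during sampling so that chains remain finite; `strict = TRUE` in
`loglik_trial()` gives exact $-\infty$.

## Model ladders

Model comparison follows fixed ladders of nested parameterisations.

* **Experiment 1** (4 models): (1) $v$ by Matching Condition, $z = 0.5$;
  (2) as 1 with $z$ free; (3) $v$ by Shape × Matching, $z = 0.5$;
  (4) $v$ by Shape × Matching with $z$ free. In models 1–2 self and
  friend deliberately share a drift rate.
* **Experiment 2** (3 models): (1) $v$ by Frequency × Shape × Matching
  with one free $z$; (2) additionally $z$ by Stimulus Frequency;
  (3) additionally $a$ by Stimulus Frequency.
* **Experiment 3**: the experiment-2 ladder with identity-link
  trial-number regressions on $z$, $v$ and $a$ — one slope per condition
  cell of the regressed parameter, applied as
  $\text{base} + \text{slope} \times \text{trial number}$ and clipped to
  the valid domain ($z$ to $[0.01, 0.99]$, $a$ to $[0.05, 10]$, $t_0$
  non-negative).

The trial-number covariate is the raw 1-based within-block index,
uncentred: the printed slope magnitudes (order $10^{-4}$–$10^{-2}$) are
consistent with an uncentred 1–200 range. Slopes are group-level
scalars shared across participants; the posterior tables report a single
slope per cell, and participant-varying slopes would be weakly
identified at 200 trials per block. All models estimate $sv$, $st$,
$sz$ as global scalars.

## Synthetic data

`simulate_trials()` is the generative counterpart of the fitted model
and stands in for the raw data. Cell-level parameters for each
simulated participant are drawn from normals around the group means,
truncated to the valid domain, with package-default dispersion SDs
($a$: 0.1, $v$: 0.3, $z$: 0.03, $t_0$: 0.05) — no participant-level
dispersion estimates are available to pin these down, so they are
documented defaults chosen to produce realistic between-participant
spread. The canonical group means are the posterior means of each
study's best-fitting model (`ddm_ground_truth("expt1")`, `"expt2"`,
`"expt3"`, the last including the trial-number slopes).

Trials are drawn by Euler–Maruyama integration at `dt = 1e-4` s with two
accuracy refinements: linear interpolation of the crossing time when a
step lands outside a boundary, and a Brownian-bridge correction for
crossings *inside* a step (without it the discretisation bias is
detectable in a Kolmogorov–Smirnov test against the analytic
distribution at $n = 5000$; with it the simulated RT distributions pass).
Trial order is randomised within block, trial numbers are assigned after
randomisation, and block order alternates across participants. There is
no contaminant/lapse process, matching the fitted model.

What the generator does *not* emulate: real participants' lapses,
fatigue and post-error slowing, RT contaminants, display-timing
quantisation, and any true heterogeneity structure beyond independent
normal dispersion. Passing recovery tests therefore demonstrates the
correctness and calibration of the pipeline on model-consistent data,
not robustness of the model to real-data violations.

RT preprocessing: `filter_rt()` excludes responses *strictly* faster
than 200 ms ("faster than" is read literally, so ties at exactly 200 ms
are retained); there is no upper cutoff.

## Estimation

`fit_hddm()` performs hierarchical Bayesian estimation by adaptive
Metropolis-within-Gibbs: single-parameter Gaussian random-walk
proposals, with proposal scales multiplicatively adapted towards a
20–50% acceptance rate during burn-in only. Participant-level values of
every free $a/v/z/t_0$ cell are normal around group means with one group
SD per parameter type; $sv$, $st$, $sz$ and slopes are group-level
scalars carrying the full-data likelihood. Because the likelihood
factorises over trials, the sampler caches per-trial log densities and
recomputes only the trials a proposal actually touches.

Default priors (the package's choices; weakly informative on the
$s = 1$ scale): $a \sim \mathrm{TN}(1.5, 1, [0.1, 5])$,
$v \sim N(0, 3)$, $z \sim \mathrm{TN}(0.5, 0.25, [0.05, 0.95])$,
$t_0 \sim \mathrm{TN}(0.4, 0.3, [0.05, 1])$, $sv \sim U(0, 2)$,
$st \sim U(0, 0.6)$, $sz \sim U(0, 0.7)$, group SDs
$\sim \mathrm{HalfNormal}(0.5)$, slopes $\sim N(0, 0.02)$.
Initialisation is prior-guided and seed-jittered, with $t_0$ started
below the smallest observed RT; a bounded number of re-initialisations
guards against a degenerate start. Domain truncation of participant
values is enforced by proposal rejection; the truncated-normal
normalising constant is ignored (standard practice), which slightly
tilts hierarchical group-mean marginals near domain bounds — the
prior-recovery test therefore exercises the pooled sampler, where the
prior is exact.

The default configuration is 10,000 samples with 1,000 burn-in and one
chain, the package's standard analysis setting. Recovery studies use
two chains and gate on split-$\hat R < 1.1$ for the core group means.
`fit_hddm(hierarchical = FALSE)` gives a pooled Bayesian fit and
`fit_pooled_mle()` a multi-start L-BFGS-B maximum-likelihood fit; the
two agree within posterior uncertainty when variabilities are switched
off, which the tests exploit as a cross-check.

## Evaluation

* **DIC**: $\bar D + p_D$ with $\bar D$ the posterior mean deviance and
  $p_D = \bar D - D(\hat\theta)$ the classic plug-in at the posterior
  means of all sampled parameters (group and participant level). Lower
  is better. Negative $p_D$ is reported with a warning, never clamped.
* **Directional tests**: `p_bayes()` returns the fraction of posterior
  draws in which the stated direction *fails* — the complement
  convention, so values near 0 are strong evidence for the direction and
  0.5 is equivocal. Before comparing drift magnitudes on nonmatching
  trials, `flip_nonmatching_drifts()` negates those (negative) drift
  draws; the transformation is an involution and flipped fits are used
  only for contrasts.
* **Recovery**: `recovery_report()` tabulates bias, posterior SD,
  z-score and 95%-interval coverage per group parameter.

## Problem sizes and numerical settings in the shipped studies

The analysis scripts and tests run reduced-size versions of the full
configuration, chosen as the package's standard verification sizes:
recovery fits use 1,100–2,000 samples (400–650 burn-in) with 2 chains
and a 7-node ($t_0$) by 3-node ($z$) quadrature; the model-recovery and
dynamic-slope replicate studies use pooled fits with $st = sz = 0$ in
both generator and models (drift variability kept free), since the
ladders differ only in the $v/z/a$ factorisation and the uniform
variabilities are orthogonal to that comparison. The full-length
settings (10,000/1,000, 11 nodes, hierarchical everywhere) remain the
package defaults.

## Known limitations

* The sampler is a random-walk scheme: strongly correlated parameters
  ($a$ with $sv/sz$, $t_0$ with $st$) mix slowly, and the inter-trial
  variability scalars are weakly identified at typical trial counts —
  their posteriors should be read with care.
* One group SD per parameter type is a modelling simplification; cells
  of the same parameter share their dispersion.
* The quadrature marginalisation is a controlled approximation; with
  very wide $sz$ (near the containment bound) a higher node count is
  advisable.
* Identity-link regression with post-hoc clipping can create flat spots
  at the domain edges for extreme slope proposals.
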