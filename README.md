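# ddmatch

Drift-diffusion analysis of self-prioritization in shape–label matching
tasks under stimulus-frequency manipulations.

## What this is for

In a shape–label matching task, participants learn arbitrary
associations between geometric shapes and people (triangle = you,
square = your best friend) and then judge whether displayed shape–label
pairs match those associations. Responses are typically faster and more
accurate for self-associated stimuli — *self-prioritization*. This
package provides, for researchers studying such two-choice decisions, a
complete and tested pipeline to ask *where* in the decision process such
effects live:

* a response-coded Wiener diffusion likelihood (upper boundary =
  "matching" response, lower = "nonmatching") with inter-trial
  variabilities in drift rate (`sv`), starting point (`sz`) and
  non-decision time (`st`), implemented as a dual small/large-time
  series in C++ with closed-form drift-variability marginalisation and
  Gauss–Legendre quadrature for `st`/`sz`;
* a trial-level simulator emulating three study designs — an
  equivalent-frequency block (200 trials, 50 per Shape × Matching cell)
  and two-block designs with 75%/25% stimulus-frequency splits under
  confirmed or disconfirmed expectations;
* declarative model ladders mapping design factors (and, for the
  dynamic models, trial number) to free parameters;
* hierarchical Bayesian estimation by adaptive Metropolis-within-Gibbs,
  DIC model comparison, directional posterior tests (`p_bayes`), and
  parameter-recovery reporting.

## The model

Evidence accumulates as a Wiener process with drift *v* between
absorbing boundaries 0 and *a* (diffusion scale *s* = 1), starting at
relative point *z* (0.5 = unbiased; *z* > 0.5 = bias towards
"matching"); the observed RT is the boundary-crossing time plus
non-decision time *t₀*. Drift varies across trials as N(*v*, *sv*);
*z* and *t₀* vary uniformly with full widths *sz* and *st*. The
absorption probability at the lower boundary has the closed form
(e^(−2vza) − e^(−2va)) / (1 − e^(−2va)). Model comparison uses
DIC = D̄ + pD; directional evidence uses the complement convention:
`p_bayes` is the fraction of posterior draws in which the stated
direction *fails*, so values near 0 mean strong evidence.

## Worked example

Simulate the equivalent-context design at its canonical generating
parameters, refit the generating model and test the self-prioritization
contrast:

```r
library(ddmatch)

truth  <- ddm_ground_truth("expt1")          # group means of the winning model
trials <- simulate_trials(make_design(1, 20), truth, seed = 42)
trials <- filter_rt(trials)$trials           # drop sub-200 ms anticipations

fit <- fit_hddm(trials, build_model_ladder(1)$m4,
                mcmc = mcmc_config(n_samples = 2000, n_burn = 650,
                                   n_chains = 2, seed = 7),
                cfg = density_config(quadrature_nodes = 7,
                                     quadrature_nodes_z = 3))
recovery_report(truth, fit)[1:7, c("parameter", "truth", "post_mean", "post_sd")]
p_bayes(fit, "v(matching.self)", "v(matching.friend)")
p_bayes(fit, "z", 0.5)
```

A run of this example printed (about 5 minutes on one CPU):

```
              parameter  truth post_mean post_sd
1                     a  0.957    0.9546 0.02216
2      v(matching.self)  1.744    1.6961 0.11752
3    v(matching.friend)  0.790    0.9757 0.11763
4   v(nonmatching.self) -1.372   -1.3226 0.11767
5 v(nonmatching.friend) -1.399   -1.3550 0.11983
6                     z  0.544    0.5259 0.01143
7                    t0  0.437    0.4312 0.01155
[1] 0
[1] 0.007037037
```

Every generating value is recovered within a couple of posterior SDs.
The first directional test is 0 — no posterior draw had friend-drift
exceeding self-drift on matching trials — and the bias test is 0.007,
with almost every draw placing the starting point above 0.5: decisive
evidence for faster information uptake from self-related stimuli and
for a response bias towards "matching", the qualitative signature the
pipeline is built to detect.

## Analysis workflow

The `analysis/` scripts run the full study pipeline over the package,
writing tables to `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic datasets, all 3 designs
Rscript analysis/02_descriptives.R    # exclusions, per-cell RT/accuracy
Rscript analysis/03_fit_expt1.R       # 4-model DIC ladder + contrasts
Rscript analysis/04_fit_expt2.R       # 3-model ladder, frequency effects
Rscript analysis/05_dynamic_expt3.R   # trial-number dynamic-bias models
Rscript analysis/06_recovery.R        # parameter-recovery report
```

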