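---
title: "Modelling explore/exploit choice with the reinforcement-learning drift-diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling explore/exploit choice with the reinforcement-learning drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlddm)
```

## The scientific problem

In a two-armed bandit with probabilistic rewards, a decision maker who has
learned which option pays more can either *exploit* it or *explore* the
currently worse option. In a reversal-learning design the contingencies swap
midway through, so some exploration is adaptive; but even in stable phases
humans reliably make "non-greedy" choices. This package models that
behaviour for the task design used in deep-brain-stimulation (DBS) studies
of the pallidum: three 40-trial sessions, two options rewarded at 80%:20%,
contingencies reversing after trial 60, a 3-second response window, and
subjects tested under multiple conditions (stimulation ON, OFF, healthy
controls).

The quantity of interest is **P(Explore)**: the fraction of responded trials
in a window on which the subject chose the option with the *lower* expected
value. Expected values are latent, so P(Explore) is defined through a model
of learning, and the choice mechanism is modelled jointly with decision
times.

## The model

The reinforcement-learning drift-diffusion model (RLDDM) couples delta-rule
value learning to a diffusion choice rule.

**Learning.** Each option carries an expected value `Q` updated after
feedback:

\[ Q_{t} = Q_{t-1} + \alpha (R_t - Q_{t-1}) \]

with outcome \(R_t \in \{0, 1\}\). The dual-rate variant uses
\(\alpha^{+}\) when the prediction error is positive and \(\alpha^{-}\) when
it is negative; the single-rate variant ties them. Only the chosen option is
updated; omitted trials update nothing.

**Choice.** The decision on trial \(t\) is a Wiener diffusion between
boundaries 0 and \(a\) starting at \(z \cdot a\), with drift proportional to
the current value difference:

\[ v_t = m \, (Q_{A,t} - Q_{B,t}) \]

The joint likelihood of choice and decision time is the Wiener
first-passage-time (WFPT) density with non-decision time \(t_{er}\). The
scaling parameter \(m\) plays the role of the softmax inverse temperature:
large \(m\) amplifies value differences (exploitation), \(m = 0\) makes
choice value-blind, so P(Explore) sits at chance. This monotone link is the
mechanistic claim the package's validation checks quantify.

**Parameters and scales.**

| parameter | meaning | scale | default group mean (ON / OFF / HC) |
|---|---|---|---|
| `a` | boundary separation (evidence units) | \(a > 0\) | 1.78 / 1.96 / 1.96 |
| `m` | drift-rate scaling (evidence per unit value difference) | unbounded | 3.40 / 4.51 / 2.80 |
| `alpha_pos_raw` | learning rate, positive prediction errors | unbounded; logistic-squashed at use | 0.22 / -0.85 / -0.85 |
| `alpha_neg_raw` | learning rate, negative prediction errors | unbounded; logistic-squashed | -2.65 / -2.97 / -1.65 |
| `t` | non-decision time (s) | \(t \ge 0\) | 0.57 / 0.57 / 0.42 |
| `z_raw` | start-point bias (logit) | unbounded; \(z = \mathrm{logit}^{-1}(z_{raw})\) | 0 (unbiased) |

Learning rates are reported on the unbounded scale because group-level
summaries of such models are routinely negative there; the logistic
transform is the only monotone map consistent with negative summaries and
rates in (0, 1). The diffusion coefficient is fixed at 1 — parameter values
are only comparable under one scale convention, and this is the convention
of the hierarchical DDM ecosystem.

## The synthetic-data generator

`make_schedule()`, `cohort_spec()`, `sample_cohort()` and
`generate_cohort_data()` produce fully synthetic cohorts with the
statistical structure the analysis assumes:

* subject parameters are drawn from normal group distributions on the
  estimation scale (`a` and `t` truncated at zero by rejection), with
  condition-specific means and shared-within-subject `t` and `z_raw`;
* the generative loop is closed: drift from the current Q-difference,
  a simulated first passage, an outcome drawn from the schedule, a Q update;
* omissions arise from an independent Bernoulli mechanism (the default is 0.015 per trial,
  matching omission counts typical of this task) *and* from simulated responses that exceed the
  3-s window — both are recorded as omissions, carry no outcome, and
  trigger no value update.

The group means default to the estimated ON/OFF/HC values above. The
between-subject spreads (`default_group_sds()`: 0.25 for `a`, 1.0 for `m`,
0.75 for the raw rates, 0.08 s for `t`, 0.25 for `z_raw`) are not reported
quantities; they were fixed once, before any testing, at magnitudes that
produce subject scatter comparable to subject-level estimate plots reported
for this task. The HC means for parameters without a reported value reuse
the OFF values, with `m` and `alpha_neg_raw` shifted by the reported
HC-vs-OFF contrasts.

What the generator does **not** emulate: within-subject session order
effects, post-error slowing, motor-symptom interference with responding,
fractal-specific biases, and any inter-trial variability in diffusion
parameters. Passing validation on synthetic data therefore demonstrates the
estimation and analysis machinery is self-consistent — not that the model
family is adequate for any particular empirical dataset.

## Numerical choices

* **WFPT density**: small-time and large-time series with the standard
  accuracy-based term selection at truncation error `1e-7`; `dt <= t`
  returns `-Inf` (impossible observation), distinct from `NaN` for invalid
  parameters. A quadrature oracle checks that both boundary densities
  integrate to 1.
* **Simulation**: Euler–Maruyama with step `1e-4` s and a 10-s cap.
  Discrete boundary monitoring biases first-passage times upward by
  \(O(\sqrt{\mathrm{step}})\); the simulator therefore shifts both
  boundaries inward by \(0.5826\sqrt{\mathrm{step}}\) (the standard
  continuity correction), reducing the bias to \(O(\mathrm{step})\). At the
  default step the simulator matches the density with Kolmogorov–Smirnov
  distance well below 0.01 at \(10^5\) draws.
* **Q initialisation**: `q0 = (0.5, 0.5)`, the midpoint of the outcome
  range. Other conventions (0, or first outcome) shift estimated learning
  rates slightly; the choice is exposed as an argument everywhere.
* **Tie rule**: a choice with exactly equal Q values is *not* exploratory
  (P(Explore) counts strictly-lower-value choices). This matters mainly for
  trial 1 and for `m = 0` maps, where it pulls P(Explore) just below 0.5.
* **Windowed refits** (`window = "pre"` / `"post"`, split at trial 60)
  restart the value trajectory at `q0`: each window is treated as its own
  learning episode.

## Hierarchical estimation

The package ships a hierarchical MCMC sampler (in C++) specialised for the
trial-sequential RLDDM likelihood: adaptive random-walk
Metropolis on the subject-level parameters (target acceptance 0.44,
Robbins–Monro adaptation during burn-in only), conjugate Gibbs updates for
group means, and log-scale Metropolis with half-normal priors for group
spreads. Condition-dependent parameters (`a`, `m`, both rates) get
per-condition group distributions; `t` and `z_raw` are shared across
conditions within a subject, reflecting the a-priori assumption that
stimulation does not alter encoding/motor time or starting bias.

Priors (`rlddm_priors()`) are weakly informative: broad normals on group
locations, half-normals on spreads. Reported group estimates for this
model family rarely come with their priors, so posterior summaries can
differ modestly from reported tables even on identical data; the defaults here are deliberately vague
relative to the likelihood at 120 trials/subject.

The reference budget is 4 chains with 7000 burn-in and 15000 retained draws
(the convention in this literature); the reduced budget used in the package's checks
is 2 chains with 1000 + 1000, which the parameter-recovery results show is
already informative at the 18-subject, 120-trial scale. Convergence is
monitored by split-chain Gelman–Rubin statistics on the group-level nodes
and deviance, warning above 1.1. Model comparison uses
`DIC = mean(D) + pD`, `pD = mean(D) - D(posterior mean)`, evaluated at the
posterior means of the subject-level parameters.

Significance of a condition contrast follows the field's implicit rule: the
95% highest-density interval of the draw-wise group-mean difference
excludes zero (85% HDIs are reported alongside).

## Validation machinery

* **Posterior-predictive checks** simulate 50 full experiments from the
  subject-level posterior means (a full-posterior variant would simply
  resample draws; the point-estimate convention is standard for
  this model family) and compare observed learning curves with the 95% band across
  simulations.
* **Parameter recovery** refits five generated sets at the reduced budget
  and correlates generating with recovered subject-level values, per
  parameter.
* **The P(Explore) parameter map** simulates 20 datasets per cell of a grid
  centred on the OFF-state group means. Its two decisive features: chance
  exploration at `m = 0`, and monotone decline of exploration in `m`.

## The connectivity R-map

`voxelwise_rmap()` correlates, at every voxel, per-subject seed-connectivity
values with a behavioural regressor (here: the maximum within-session
ON-minus-OFF increase in P(Explore)). Prediction then scores each subject's
map against an R-map and regresses behaviour on the scores.

One design point deserves emphasis. If each subject is scored against the
R-map built from *all* subjects (including themselves), the scores are
circular: as the voxel count grows, the score–behaviour correlation
converges to 1 for *any* regressor, and the analysis loses all power (the
permutation p-value is still valid — the inflation applies equally to every
permutation — but it hovers near 0.5 regardless of signal). The package
therefore defaults to **leave-one-out scoring**
(`rmap_similarity_scores(..., loo = TRUE)`): each subject is scored against
the R-map of the remaining subjects, computed efficiently by rank-1
downdates of the full-sample sums. This matches the convention of scoring
individuals against "non-behavioural" reference maps in the
lesion/stimulation network-mapping literature, keeps \(R^2\) interpretable,
and restores power. The circular variant remains available (`loo = FALSE`)
for comparison.

The permutation test (default 1000 re-orderings)
recomputes the entire pipeline per permutation and reports the
add-one-smoothed two-sided p (the directional p is returned alongside,
since a one-sided hypothesis is also defensible for an "optimal network"
claim). Whether whole-brain voxels or a grey-matter mask were used in the
original analysis is unstated; the package correlates over all finite
voxels and lets the caller mask beforehand.

`heatmap_overlap()` implements the stimulation-volume n-map (per-voxel count
of covering volumes) and the weighted region overlap (sum of n-map values
inside a region mask binarised at 50% probability), on a common grid with an
explicit error — never silent resampling — on grid mismatch.

## Problem sizes used by the checks

The packaged tests and the acceptance script run: the WFPT/simulator
comparison at \(10^5\) draws per grid point; recovery on 5 sets of 18
subjects x 2 conditions x 120 trials at the reduced budget; the parameter
map at 20 simulations per cell; posterior-predictive checks at 50
replications; DIC comparison on one 18-subject cohort; and R-map calibration
on 200 null replicates of 14-subject cohorts on small grids. These sizes
were chosen as the smallest at which each property is a sharp test of the
mechanism rather than of Monte-Carlo noise.

## Known limitations

* The sampler is a random-walk scheme: it needs its burn-in, and posterior
  tails for weakly identified subjects (e.g. near-zero learning rates) mix
  more slowly than an HMC sampler would.
* No inter-trial variability parameters (`sv`, `st`, `sz`): the
  four-parameter model is the deliberate scope.
* The normal group model with rejection at zero for `a` and `t` is an
  approximation; its truncation mass is negligible at the estimated scales
  but would matter for group means near zero.
* DIC is the only comparison criterion implemented; it is reported because
  it is the field's convention for this model family, not because it is the
  best available criterion.
* Synthetic voxel cohorts plant a linear, homoscedastic effect in a compact
  mask — real connectivity maps have spatial autocorrelation that makes
  voxelwise nulls optimistic; the permutation test, not the voxelwise map,
  is the inferential statement.
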