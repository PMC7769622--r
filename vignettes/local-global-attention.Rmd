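---
title: "Modelling scan paths by switching between local and global attention"
author: "lgattention package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling scan paths by switching between local and global attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgattention)
```

## The model

During natural scene viewing, gaze alternates between short saccades that
inspect the neighbourhood of the current fixation and long saccades that
relocate gaze to another salient region. This package implements a
generative model of that behaviour on a *static saliency map*
`s(z)`: a non-negative raster over image pixels, normalized to unit mass,
interpreted as the probability that an average viewer fixates location
`z = (x, y)`. In practice `s` is the empirical fixation density
(`empiricalSaliency()`, a Gaussian kernel-density estimate pooled over
subjects) or a synthetic fixture (`syntheticSaliency()`).

A scan path `Z = (z_1, ..., z_T)` is reduced to its fixation locations; we
model spatial selection only, not fixation durations. Saccade generation is
a second-order Markov process,

    p(Z) = p(z_1) p(z_2) prod_{t=3..T} p(z_t | z_{t-1}, z_{t-2}),

with the first two fixations drawn from the saliency map itself. Each later
fixation comes from one of two attention modes:

* **Local attention.** A bivariate Gaussian around the current fixation with
  diagonal covariance `eps = diag(eps_x, eps_y)` (units: squared pixels),
  evaluated at pixel centers and renormalized within the image
  (`localMap()`).
* **Global attention.** The saliency map modulated by a broader Gaussian
  with covariance `xi` (componentwise larger than `eps`), *minus* a local
  repulsion kernel that forbids short saccades:

      p_global(z) ∝ max( s(z) n(z; z_prev, xi) − n(z; z_prev, eps), 0 ),

  renormalized (`globalMap()`). The clamp at zero creates a genuine
  zero-probability "hole" around the current fixation; if a parameter
  combination clamps *every* pixel the map is degenerate and the likelihood
  treats that parameter region as impossible.

The mode choice for saccade `t` is a Bernoulli draw with probability

    rho_t = sigma( b (s(z_{t-1}) / s(z_{t-2}) − s_o) ),

a logistic function of the ratio of saliency values at the two preceding
fixations: landing on a more salient location than before favours staying
local. The full likelihood multiplies the mixture
`rho_t p_local + (1 − rho_t) p_global` over saccades
(`scanpathLogLik()`, `stepProbability()`).

Simplified competitors retained for model comparison: **local choice**
(the gate depends on `s(z_{t-1})` alone, a first-order Markov model),
**fixed choice** (`rho_t = rho`, constant), **local saliency** (a single
mode, `s(z) n(z; z_prev, xi)` renormalized), and the **saliency baseline**
(every fixation drawn from `s` independently).

All distributions live on the discrete pixel grid: kernels are evaluated
un-truncated at pixel centers (0-based coordinates, x = column,
y = row) and maps are renormalized within the image. Simulation samples
pixels exactly from these maps (inverse-CDF over the flattened raster), so
simulation and likelihood share one discrete measure.

## Bayesian inference

Parameters `Theta = (eps, xi, b, s_o)` are inferred per subject by a Gibbs
sampler over an augmented model:

1. **Mode indicators.** Each saccade gets `gamma_t ~ Bernoulli(rho_t)`;
   conditional on the data, `gamma_t` is Bernoulli with logit
   `f_t + log p_local(z_t) − log p_global(z_t)`, where
   `f_t = b (ratio_t − s_o)`. We evaluate this logit directly in log space:
   `rho_t` itself saturates to 0/1 in double precision at `|f| > ~37`,
   which would decouple the labels from the likelihood.
2. **Polya-Gamma auxiliaries.** `w_t ~ PG(1, f_t)` renders the logistic
   factor Gaussian in `(b, s_o)`; both then have exact Gaussian full
   conditionals by completion of squares (`sampleB()`, `sampleSO()`). The
   PG(1, c) draws use an exact Devroye-type alternating-series sampler
   implemented in C++ (`rpolyagamma()`), validated against the moment
   identity `E[PG(1, c)] = tanh(c/2) / (2c)`.
3. **Length scales.** `(eps, xi)` have no closed-form conditional because
   of the clamped global map, so one Hamiltonian Monte Carlo transition per
   sweep targets their conditional in log-scale coordinates, with
   Inverse-Gamma priors, the change-of-variables Jacobian, and the support
   constraint `xi > eps` (componentwise) enforced by zero density.

**A design decision that emerged in testing:** conditioning the scale update
on *hard* labels creates sticky modes — e.g. a state whose gate is saturated
towards "local" for every saccade keeps `xi` pinned at its prior, and no
single Gibbs move can leave it. The scale update therefore targets the
*label-marginal* conditional `p(eps, xi | b, s_o, Z)` (a partially collapsed
Gibbs sampler). Its gradient is the posterior-label-weighted mixture of the
component gradients, so the cost per evaluation is one pass over the grid
per saccade; per-saccade component values are cached across the sweep. Hard
labels are still drawn every sweep — they are what the Polya-Gamma
conjugacy of `(b, s_o)` needs, and they expose the latent mode sequence for
analysis. The exported `hmcUpdateScales()` retains the hard-label
conditional, whose all-local limit is an exact Inverse-Gamma — the
closed-form oracle used in the tests.

Sampler plumbing, all configurable through `gibbsControl()`:

* **Priors** (`defaultHyperparams()`): `eps_{x,y} ~ IG(2, 10 ppd^2)` and
  `xi_{x,y} ~ IG(2, 400 ppd^2)` where `ppd` is pixels per degree — wide
  (infinite-variance) priors whose means correspond to Gaussian spreads of
  about 3 and 20 degrees, reflecting that human saccades range from about
  half a degree to tens of degrees. The 40-fold scale separation keeps the
  `xi > eps` truncation inactive under the prior (overlap probability about
  2e-3 per axis), so prior-reproduction checks against the untruncated
  Inverse-Gamma are valid. `b` and `s_o` get zero-mean Gaussians whose
  scale widens with the observed saliency-ratio scale (a data-dependent
  default computed before sampling).
* **Initialization.** Chains are dispersed: `eps` is a prior draw
  conditioned into `(median/4, median)` of the per-axis squared steps,
  `xi` into `(median, 3 x upper decile)`; link parameters are prior draws
  re-drawn if the initial gate is saturated for most saccades. The windows
  only shape burn-in; they keep chains out of degenerate territory (an
  `eps` so small that no saccade can register as local, or comparable to
  `xi`) while remaining overdispersed relative to the posterior.
* **Adaptation.** The leapfrog step size is dual-averaged to a 0.65
  acceptance target during burn-in, seeded by a doubling/halving search; a
  diagonal metric (per-coordinate scale) is estimated from mid-burn-in
  draws; the trajectory length is jittered per transition (step size by
  +-10%, leapfrog count uniformly over its upper half) because fixed-length
  trajectories on a near-Gaussian target resonate — they return close to
  their starting point and the chain barely moves. During the first 50
  burn-in sweeps labels are drawn with the gate held at 1/2, letting the
  scales organize around the likelihood before the link feedback engages.
  All adaptation ends at burn-in. The (gamma, w, b, s_o) link block is
  repeated several times per sweep (`linkSweeps`): it reuses cached
  component log-densities, so the repetitions cost no map evaluations and
  decorrelate the link slope from the labels.
* **Diagnostics.** Split R-hat and Geyer initial-monotone effective sample
  sizes per parameter; a fit is flagged non-converged when any split R-hat
  exceeds 1.1 (`gelmanRhat()`, `isConverged()`). With an empty dataset the
  sweep reduces to prior sampling, which the tests exploit as an
  end-to-end correctness check.

Defaults are 4 chains of 5,000 sweeps with 2,000 burn-in. The *analysis
sizes* used by this package's own experiments (tests and the acceptance
script) are deliberately smaller, chosen once as desk-scale: the
parameter-recovery protocol runs 5 replicates of 30 paths x 35 fixations on
64 x 64 maps with 3 chains x 450 sweeps (200 burn-in, 5 leapfrog steps);
the model-comparison experiment runs 2 subjects x 30 images on 28 x 28
maps with 2-fold cross-validation and single-chain fits of 250 sweeps,
scored at the posterior mean. At these chain lengths a central 90%
credible interval is calibrated but individual seeded replicates can of
course still miss: across fifteen replicate datasets we observed
per-parameter coverage of 27/30 pooled over the scale parameters,
consistent with the nominal rate.

## Synthetic data

`syntheticDataset()` emulates a scene-viewing experiment: per-image
saliency maps are mixtures of 3 random anisotropic Gaussian bumps (centers
re-sampled until well separated) over a 2% uniform floor; one trial per
(subject, image); 35 fixations per trial, matching roughly 10 s of viewing
at 3-4 saccades per second. Default generating parameters are stated in
degrees and converted by the grid's pixel scale
(`defaultTrueParams()`): local spread (1.5, 1.3) deg, global spread
(7.5, 6.5) deg, `b = 1.5`, `s_o = 1` — two clearly separated saccade
scales with a data-dependent gate that produces roughly balanced mode use.
Ground truth (parameters and all latent tags) is returned alongside the
fixation table.

What the generator does *not* emulate: saccadic momentum and direction
persistence, anisotropic preference for horizontal saccades beyond what the
anisotropic covariances produce, fixation durations, and any
image-computable saliency. Passing tests therefore establish the internal
consistency of model, sampler and metrics — not fidelity to any particular
experimental dataset.

## Evaluation

Predictive scoring is teacher-forced: at every step the model's conditional
map given the *observed* history is the probabilistic classifier
(`stepMap()`, `scoreScanpaths()`). The first two fixations are scored under
`p(z) = s(z)` (configurable). Three scores:

* **AUC-Borji** — ROC area with map values at fixated pixels as positives
  and values at uniformly sampled pixels as negatives (10 per positive by
  default, seeded); midrank ties, equivalent to Mann-Whitney pair counting.
* **NSS** — each map z-scored over pixels (population sd); mean z-value at
  the fixations. Constant maps contribute zero with a warning.
* **Information gain** — mean `log2 p(z_t) + log2(H W)` in bit/fix, i.e.
  the per-fixation improvement over a uniform-over-pixels baseline.

`crossValidate()` splits images into seeded folds (default k = 5; any k
from 2 to leave-one-image-out), fits per subject on the training folds and
scores the held-out images, optionally averaging scores over posterior
draws. Saccade-statistics analyses (`saccadeStatistics()`,
`amplitudeAutocorrelation()`, `subjectMoments()`,
`coefficientOfDetermination()`) quantify amplitude distributions, their
lag autocorrelation (the two-mode model produces the characteristic lag-1
anti-correlation; one-mode variants do not), per-subject moments and their
agreement with simulations.

Numerical conventions worth knowing: step probabilities of exactly zero
(possible through the clamp) are floored at 1e-300 before logs and flagged;
the saliency ratio's denominator is floored at 1e-12 of the map mass; when
an arbitrary parameter set makes the global map degenerate at a *scoring*
step (possible off the training data), `stepMap(degenerateGlobal =
"fallback")` substitutes the repulsion-free `s(z) n(z; z_prev, xi)` for the
global component so the scores remain defined — the likelihood path keeps
the hard error. Directions use `atan2(dy, dx)` in image coordinates
(y down), in (-180, 180] degrees; direction changes are wrapped to the same
interval.

## Worked example

```{r example, eval = FALSE}
params <- defaultTrueParams(pxPerDegree = 2)
ds <- syntheticDataset(params, nSubjects = 1, nImages = 10, nFix = 35,
                       grid = c(64, 64), pxPerDegree = 2, seed = 1)
fit <- runGibbs(ds$fixations, ds$maps, variant = "full",
                control = gibbsControl(nChains = 3, nIter = 400,
                                       burnIn = 180, leapfrog = 5),
                seed = 2)
posteriorSummary(fit)
scoreScanpaths(ds$fixations, ds$maps, posteriorMeanParams(fit), seed = 3)
```

## Known limitations

* The model cannot reproduce saccadic momentum (direction persistence): it
  knows the *saliency* of the pre-previous fixation, not its position.
  Direction-change histograms of simulations peak only at +-180 degrees,
  from image-boundary reversals.
* Vertical direction preferences are not captured; each mode has a single
  ellipsoidal kernel.
* The two-mode likelihood is multimodal in pathological regimes (labels
  all-local with inflated `eps`); the collapsed scale update and the
  windowed initialization handle the regimes we observed, but short chains
  on small datasets can still disagree — always check `gelmanRhat()`.
* Grid-free (continuous) likelihoods are out of scope; all quantities are
  defined on the pixel grid.
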