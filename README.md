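# lgattention

Generative modelling of saccadic scan paths in natural scene viewing, for
researchers in eye-movement and visual-attention modelling who want a
likelihood-based, per-subject account of *where* gaze goes next given a
static saliency map.

## The model

Given a normalized saliency map `s(z)` over image pixels, scan-path
generation is a second-order Markov process in which every saccade is made
in one of two latent attention modes:

* **local** — the next fixation is Gaussian around the current one,
  covariance `diag(eps_x, eps_y)` (squared pixels): short saccades;
* **global** — the next fixation follows the saliency map modulated by a
  broader Gaussian (covariance `xi > eps`) minus a local repulsion kernel,
  `p_global(z) ∝ max(s(z) n(z; z_prev, xi) − n(z; z_prev, eps), 0)`:
  long saccades towards salient regions.

The mode is a Bernoulli draw with probability
`rho_t = sigma(b (s(z_{t-1})/s(z_{t-2}) − s_o))` — landing on a more
salient spot than before favours staying local. Parameters
`Theta = (eps, xi, b, s_o)` are inferred per subject by a Gibbs sampler:
Bernoulli mode indicators, Polya-Gamma auxiliaries that make `(b, s_o)`
conditionally Gaussian (exact Devroye PG(1, c) sampler in C++), and a
Hamiltonian Monte Carlo step for the length scales under Inverse-Gamma
priors. Simplified variants (local choice, fixed choice, local saliency,
saliency baseline) and likelihood-based predictive scores (AUC-Borji, NSS,
information gain in bit/fix) support model comparison with k-fold
cross-validation by image.

## Worked example

```r
library(lgattention)

params <- defaultTrueParams(pxPerDegree = 2)   # eps ~ (9, 6.8) px^2, xi ~ (225, 169) px^2, b = 1.5, s_o = 1
ds <- syntheticDataset(params, nSubjects = 1, nImages = 10, nFix = 35,
                       grid = c(64, 64), pxPerDegree = 2, seed = 1)

fit <- runGibbs(ds$fixations, ds$maps, variant = "full",
                control = gibbsControl(nChains = 3, nIter = 400,
                                       burnIn = 180, leapfrog = 5), seed = 2)
posteriorSummary(fit)
#>  parameter   mean    sd   mode  lower  upper rhat ess
#>      eps_x   8.72  0.43   8.89   7.98   9.41 1.00 660
#>      eps_y   6.50  0.20   6.60   6.16   6.81 1.00 533
#>       xi_x 292.60 53.71 279.61 221.92 390.33 1.02 369
#>       xi_y 167.95 24.85 160.05 132.88 207.98 1.00 605
#>          b   1.20  0.21   1.20   0.86   1.53 1.02 128
#>        s_o   0.94  0.11   0.93   0.77   1.12 1.00 640
```

The posterior concentrates around the generating values (here
`eps = (9, 6.76)`, `xi = (225, 169)`, `b = 1.5`, `s_o = 1`): the local
mode's spread, the global mode's reach, and the gate's slope and offset are
recovered from just 10 scan paths, with credible intervals that reflect how
weakly 330 saccades constrain the broad global scale. Scoring the fitted
model on the same data:

```r
sc <- scoreScanpaths(ds$fixations, ds$maps, posteriorMeanParams(fit), seed = 3)
round(c(auc = sc$auc, nss = sc$nss, ig = sc$ig), 3)
#>   auc   nss    ig
#> 0.947 3.934 3.018
```

AUC is the probability that a fixated pixel outscores a random pixel under
the model's step maps; NSS the mean z-scored map value at fixations; IG the
information gained per fixation (in bits) over a uniform baseline.

The CLI wrapper (`inst/scripts/lga-tool.R`) exposes the same workflows as
`simulate | fit | recover | evaluate` subcommands driven by a YAML config.
See the vignette (`vignettes/local-global-attention.Rmd`) for the model,
priors, sampler design and limitations.

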