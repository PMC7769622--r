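Package: lgattention
Title: Local and Global Attention Modelling of Saccadic Scan Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative modelling of saccadic scan paths on a static saliency
    map as a switching process between a local attention mode (short saccades,
    Gaussian around the current fixation) and a global attention mode (long
    saccades towards salient regions, with a local repulsion kernel). Provides
    exact scan-path likelihoods for the full model and its simplified variants,
    forward simulation with latent mode tags, fully Bayesian parameter
    inference via a Polya-Gamma augmented Gibbs sampler with Hamiltonian Monte
    Carlo updates for the Gaussian length scales, predictive scoring
    (AUC-Borji, normalized scanpath saliency, information gain), saccade
    statistics analyses, a cross-validation harness, and a synthetic-data
    generator emulating scene-viewing experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
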