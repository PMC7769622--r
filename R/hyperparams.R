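#' Construct Hyperparams
#'
#' @param alphaEps,betaEps,alphaXi,betaXi Inverse-Gamma shape/scale per axis
#'   for the variances \eqn{\epsilon_{x/y}} and \eqn{\xi_{x/y}}; scalars are
#'   recycled to both axes.
#' @param muB,sigmaB,muSo,sigmaSo Gaussian prior means/sds for b and s_o.
#' @param betaA,betaB Beta prior for the fixed-choice probability.
#' @return a [Hyperparams-class].
#' @export
hyperparams <- function(alphaEps = 2, betaEps = 40, alphaXi = 2,
                        betaXi = 1600, muB = 0, sigmaB = 5, muSo = 0,
                        sigmaSo = 5, betaA = 1, betaB = 1) {
  new("Hyperparams",
      alphaEps = rep_len(as.numeric(alphaEps), 2L),
      betaEps = rep_len(as.numeric(betaEps), 2L),
      alphaXi = rep_len(as.numeric(alphaXi), 2L),
      betaXi = rep_len(as.numeric(betaXi), 2L),
      muB = as.numeric(muB), sigmaB = as.numeric(sigmaB),
      muSo = as.numeric(muSo), sigmaSo = as.numeric(sigmaSo),
      betaA = as.numeric(betaA), betaB = as.numeric(betaB))
}

setMethod("show", "Hyperparams", function(object) {
  cat("Hyperparams\n")
  cat(sprintf("  eps ~ IG(%.3g, %.3g)/(%.3g, %.3g);  xi ~ IG(%.3g, %.3g)/(%.3g, %.3g)\n",
              object@alphaEps[1], object@betaEps[1], object@alphaEps[2],
              object@betaEps[2], object@alphaXi[1], object@betaXi[1],
              object@alphaXi[2], object@betaXi[2]))
  cat(sprintf("  b ~ N(%.3g, %.3g);  s_o ~ N(%.3g, %.3g);  rho ~ Beta(%.3g, %.3g)\n",
              object@muB, object@sigmaB, object@muSo, object@sigmaSo,
              object@betaA, object@betaB))
})

#' Default wide priors
#'
#' Prior hyperparameters chosen from known characteristics of human saccades
#' (amplitudes ranging from about half a degree up to tens of degrees): the
#' Inverse-Gamma scales put the local variance prior mean at a spread of
#' about 3 degrees and the global one at about 20 degrees, both with shape 2
#' (infinite prior variance, i.e. deliberately wide), and the strong scale
#' separation keeps the \eqn{\xi > \epsilon} support constraint essentially
#' inactive under the prior. The link priors are zero-mean Gaussians whose
#' scale can be widened to match the observed saliency-ratio scale
#' (`ratios`), a data-dependent default computed before sampling.
#'
#' @param pxPerDegree pixels per degree of the stimulus grid (default 2).
#' @param ratios optional vector of observed saliency ratios
#'   \eqn{s_{t-1}/s_{t-2}} used to scale the link priors.
#' @return a [Hyperparams-class].
#' @export
defaultHyperparams <- function(pxPerDegree = 2, ratios = NULL) {
  sB <- 5
  if (!is.null(ratios) && length(ratios)) {
    r <- ratios[is.finite(ratios)]
    sB <- max(5, 2 * stats::quantile(abs(r), 0.9, names = FALSE))
  }
  hyperparams(alphaEps = 2, betaEps = 10 * pxPerDegree^2,
              alphaXi = 2, betaXi = 400 * pxPerDegree^2,
              muB = 0, sigmaB = sB, muSo = 0, sigmaSo = sB,
              betaA = 1, betaB = 1)
}
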