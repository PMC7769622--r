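#' SaliencyMap: a normalized fixation-density raster
#'
#' A non-negative raster over an H x W pixel grid, normalized to sum to one,
#' representing the probability that an average viewer fixates each pixel.
#' Pixel (x, y) has its center at integer coordinates, x = 0..W-1 (column),
#' y = 0..H-1 (row).
#'
#' @slot values numeric matrix (H x W) of non-negative values summing to 1.
#' @slot pxPerDegree pixels per degree of visual angle (NA if unknown); used
#'   only for converting reported quantities to degrees.
#'
#' @seealso [SaliencyMap()], [empiricalSaliency()], [syntheticSaliency()]
#' @export
setClass("SaliencyMap",
  representation(values = "matrix", pxPerDegree = "numeric"),
  prototype(pxPerDegree = NA_real_)
)

setValidity("SaliencyMap", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (nrow(v) < 2L || ncol(v) < 2L) return("grid must be at least 2 x 2")
  if (anyNA(v)) return("'values' contains NA")
  if (any(v < 0)) return("'values' must be non-negative")
  if (abs(sum(v) - 1) > 1e-9) return("'values' must sum to 1 within 1e-9")
  p <- object@pxPerDegree
  if (length(p) != 1L) return("'pxPerDegree' must be a single number")
  if (!is.na(p) && p <= 0) return("'pxPerDegree' must be positive")
  TRUE
})

#' ScanPath: one trial's ordered fixation locations
#'
#' @slot locations numeric matrix (T x 2, columns x and y) of pixel
#'   coordinates, T >= 2.
#' @slot tags character vector of latent generation tags, either empty or of
#'   length T with values "initial" (first two fixations), "local" or
#'   "global".
#'
#' @seealso [scanPath()], [sampleScanpath()]
#' @export
setClass("ScanPath",
  representation(locations = "matrix", tags = "character"),
  prototype(tags = character(0))
)

setValidity("ScanPath", function(object) {
  loc <- object@locations
  if (!is.numeric(loc) || ncol(loc) != 2L)
    return("'locations' must be a numeric T x 2 matrix")
  if (nrow(loc) < 2L) return("a scan path needs at least 2 fixations")
  if (anyNA(loc)) return("'locations' contains NA")
  tg <- object@tags
  if (length(tg)) {
    if (length(tg) != nrow(loc))
      return("'tags' must be empty or one per fixation")
    if (!all(tg %in% c("initial", "local", "global")))
      return("tags must be 'initial', 'local' or 'global'")
    if (!all(tg[1:2] == "initial"))
      return("the first two fixations must be tagged 'initial'")
  }
  TRUE
})

.VARIANTS <- c("full", "local_choice", "fixed_choice", "local_saliency",
               "saliency_baseline")

#' ModelParams: parameters of the attention model
#'
#' Holds the parameter set \eqn{\Theta = \{\epsilon, \xi, b, s^o\}} (or the
#' variant-appropriate subset). \eqn{\epsilon = diag(\epsilon_x, \epsilon_y)}
#' is the covariance (in squared pixels) of the local-attention Gaussian,
#' \eqn{\xi} the covariance of the global-attention modulation (componentwise
#' larger than \eqn{\epsilon}), and (b, s_o) the slope and offset of the
#' logistic link gating the two modes. `rhoFixed` is used only by the
#' fixed-choice variant.
#'
#' @slot epsX,epsY,xiX,xiY positive variances in squared pixels.
#' @slot b,sO logistic-link slope and offset.
#' @slot variant one of "full", "local_choice", "fixed_choice",
#'   "local_saliency", "saliency_baseline".
#' @slot rhoFixed mixing probability in \[0, 1\] (fixed-choice variant).
#'
#' @seealso [modelParams()]
#' @export
setClass("ModelParams",
  representation(epsX = "numeric", epsY = "numeric",
                 xiX = "numeric", xiY = "numeric",
                 b = "numeric", sO = "numeric",
                 variant = "character", rhoFixed = "numeric"),
  prototype(b = 0, sO = 0, variant = "full", rhoFixed = NA_real_)
)

setValidity("ModelParams", function(object) {
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!all(vapply(list(object@epsX, object@epsY, object@xiX, object@xiY),
                  num1, logical(1))))
    return("scale parameters must be single finite numbers")
  if (length(object@variant) != 1L || !object@variant %in% .VARIANTS)
    return(paste("'variant' must be one of:", paste(.VARIANTS, collapse = ", ")))
  if (any(c(object@epsX, object@epsY, object@xiX, object@xiY) <= 0))
    return("all scale parameters must be positive")
  if (object@variant %in% c("full", "local_choice", "fixed_choice")) {
    if (object@xiX <= object@epsX || object@xiY <= object@epsY)
      return("the global scales must dominate: xi_x > eps_x and xi_y > eps_y")
  }
  if (object@variant %in% c("full", "local_choice")) {
    if (!num1(object@b) || !num1(object@sO))
      return("'b' and 'sO' must be single finite numbers")
  }
  if (object@variant == "fixed_choice") {
    r <- object@rhoFixed
    if (length(r) != 1L || is.na(r) || r < 0 || r > 1)
      return("'rhoFixed' must be a probability in [0, 1]")
  }
  TRUE
})

#' Hyperparams: prior hyperparameters for Bayesian inference
#'
#' Conjugate prior family: Inverse-Gamma(shape, scale) per axis for the
#' variances \eqn{\epsilon_{x/y}} and \eqn{\xi_{x/y}}, Gaussians for the link
#' parameters b and s_o, and a Beta prior on the fixed-choice mixing
#' probability.
#'
#' @slot alphaEps,betaEps,alphaXi,betaXi length-2 numerics (x, y axes):
#'   Inverse-Gamma shapes and scales.
#' @slot muB,sigmaB,muSo,sigmaSo Gaussian prior means and standard deviations
#'   for b and s_o.
#' @slot betaA,betaB Beta prior parameters for the fixed-choice probability.
#'
#' @seealso [hyperparams()], [defaultHyperparams()]
#' @export
setClass("Hyperparams",
  representation(alphaEps = "numeric", betaEps = "numeric",
                 alphaXi = "numeric", betaXi = "numeric",
                 muB = "numeric", sigmaB = "numeric",
                 muSo = "numeric", sigmaSo = "numeric",
                 betaA = "numeric", betaB = "numeric")
)

setValidity("Hyperparams", function(object) {
  len2 <- function(x) length(x) == 2L && all(is.finite(x))
  if (!len2(object@alphaEps) || !len2(object@betaEps) ||
      !len2(object@alphaXi) || !len2(object@betaXi))
    return("IG shapes/scales must be length-2 (x, y) finite numerics")
  if (any(c(object@alphaEps, object@betaEps, object@alphaXi, object@betaXi) <= 0))
    return("IG shapes and scales must be positive")
  if (object@sigmaB <= 0 || object@sigmaSo <= 0)
    return("prior standard deviations must be positive")
  if (object@betaA <= 0 || object@betaB <= 0)
    return("Beta prior parameters must be positive")
  TRUE
})

#' PosteriorSamples: MCMC draws of the model parameters
#'
#' @slot draws list of per-chain numeric matrices (post burn-in, one row per
#'   kept iteration) with variant-appropriate columns among `eps_x`, `eps_y`,
#'   `xi_x`, `xi_y`, `b`, `s_o`, `rho`, plus `log_posterior`.
#' @slot variant model variant the chains target.
#' @slot acceptRate per-chain HMC acceptance rate after burn-in.
#' @slot diagnostics list with elements `rhat` (split R-hat per parameter),
#'   `ess` (effective sample size per parameter) and `converged`.
#' @slot control sampler settings used ([gibbsControl()] list).
#' @slot seed master seed of the run (NA if none supplied).
#'
#' @seealso [runGibbs()], [draws()], [gelmanRhat()], [posteriorSummary()]
#' @export
setClass("PosteriorSamples",
  representation(draws = "list", variant = "character",
                 acceptRate = "numeric", diagnostics = "list",
                 control = "list", seed = "numeric"),
  prototype(seed = NA_real_)
)

setValidity("PosteriorSamples", function(object) {
  if (!length(object@draws)) return("no chains stored")
  if (!all(vapply(object@draws, is.matrix, logical(1))))
    return("'draws' must be a list of matrices")
  cols <- lapply(object@draws, colnames)
  if (!all(vapply(cols, identical, logical(1), cols[[1]])))
    return("all chains must share the same parameter columns")
  TRUE
})
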