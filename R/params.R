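#' Construct ModelParams
#'
#' @param epsX,epsY local-attention Gaussian variances (squared pixels).
#' @param xiX,xiY global-attention modulation variances (squared pixels);
#'   must dominate `epsX`/`epsY` componentwise for variants with a global
#'   component.
#' @param b,sO slope and offset of the logistic link gating local vs global
#'   attention (used by the "full" and "local_choice" variants).
#' @param variant one of `"full"`, `"local_choice"`, `"fixed_choice"`,
#'   `"local_saliency"`, `"saliency_baseline"`.
#' @param rhoFixed fixed mixing probability (fixed-choice variant only).
#' @return a [ModelParams-class].
#' @examples
#' modelParams(epsX = 9, epsY = 7, xiX = 225, xiY = 169, b = 1.5, sO = 1)
#' @export
modelParams <- function(epsX, epsY = epsX, xiX = 25 * epsX, xiY = 25 * epsY,
                        b = 0, sO = 0, variant = "full",
                        rhoFixed = NA_real_) {
  new("ModelParams", epsX = as.numeric(epsX), epsY = as.numeric(epsY),
      xiX = as.numeric(xiX), xiY = as.numeric(xiY),
      b = as.numeric(b), sO = as.numeric(sO),
      variant = variant, rhoFixed = as.numeric(rhoFixed))
}

#' @rdname lgattention-generics
#' @export
setMethod("variantName", "ModelParams", function(x) x@variant)

#' Parameter vector of a ModelParams
#'
#' @param object a [ModelParams-class].
#' @param ... unused.
#' @return named numeric vector with the variant-appropriate entries among
#'   `eps_x`, `eps_y`, `xi_x`, `xi_y`, `b`, `s_o`, `rho`.
#' @export
setMethod("coef", "ModelParams", function(object, ...) {
  v <- object@variant
  out <- switch(v,
    full = ,
    local_choice = c(eps_x = object@epsX, eps_y = object@epsY,
                     xi_x = object@xiX, xi_y = object@xiY,
                     b = object@b, s_o = object@sO),
    fixed_choice = c(eps_x = object@epsX, eps_y = object@epsY,
                     xi_x = object@xiX, xi_y = object@xiY,
                     rho = object@rhoFixed),
    local_saliency = c(xi_x = object@xiX, xi_y = object@xiY),
    saliency_baseline = c())
  out
})

setMethod("show", "ModelParams", function(object) {
  cat(sprintf("ModelParams (variant: %s)\n", object@variant))
  cf <- coef(object)
  if (length(cf))
    cat(" ", paste(sprintf("%s = %.4g", names(cf), cf), collapse = ", "), "\n")
})

#' Reference parameter values for synthetic experiments
#'
#' Ground-truth parameters used by default in parameter-recovery and
#' model-comparison experiments, chosen once to mimic realistic scene-viewing
#' saccade statistics: local saccade spread about 1.5 deg, global spread about
#' 7 deg, with the logistic gate centered at a saliency ratio of 1.
#'
#' @param pxPerDegree pixels per degree of the simulation grid.
#' @param variant model variant; the fixed-choice variant uses
#'   `rhoFixed = 0.5`.
#' @return a [ModelParams-class].
#' @export
defaultTrueParams <- function(pxPerDegree = 2, variant = "full") {
  modelParams(
    epsX = (1.5 * pxPerDegree)^2, epsY = (1.3 * pxPerDegree)^2,
    xiX = (7.5 * pxPerDegree)^2, xiY = (6.5 * pxPerDegree)^2,
    b = 1.5, sO = 1, variant = variant,
    rhoFixed = if (variant == "fixed_choice") 0.5 else NA_real_)
}
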