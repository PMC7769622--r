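#' @name lgattention-generics
#' @title Accessor generics
#' @description Accessors for the package's S4 classes. `mapValues()` returns
#'   the normalized raster of a [SaliencyMap-class]; `pxPerDegree()` its pixel
#'   scale; `gridSize()` the (H, W) pixel counts. `locations()` and
#'   `pathTags()` return a [ScanPath-class]'s fixation coordinates and latent
#'   mode tags; `nFixations()` its length. `variantName()` returns the model
#'   variant of a [ModelParams-class] or [PosteriorSamples-class];
#'   `draws()` the per-chain draw matrices of a [PosteriorSamples-class].
#' @param x object.
#' @return See the description per generic.
NULL

#' @rdname lgattention-generics
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname lgattention-generics
#' @export
setGeneric("pxPerDegree", function(x) standardGeneric("pxPerDegree"))

#' @rdname lgattention-generics
#' @export
setGeneric("gridSize", function(x) standardGeneric("gridSize"))

#' @rdname lgattention-generics
#' @export
setGeneric("locations", function(x) standardGeneric("locations"))

#' @rdname lgattention-generics
#' @export
setGeneric("pathTags", function(x) standardGeneric("pathTags"))

#' @rdname lgattention-generics
#' @export
setGeneric("nFixations", function(x) standardGeneric("nFixations"))

#' @rdname lgattention-generics
#' @export
setGeneric("variantName", function(x) standardGeneric("variantName"))

#' @rdname lgattention-generics
#' @export
setGeneric("draws", function(x) standardGeneric("draws"))
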