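# Step distributions and scan-path likelihoods of the attention model and its
# variants, on the discrete pixel grid. All Gaussian kernels are evaluated
# un-truncated at pixel centers and the resulting maps are renormalized within
# the image, so each returned map is a probability mass function over pixels.

.check_loc <- function(z, H, W, what = "location") {
  if (length(z) != 2L || anyNA(z))
    stop("'", what, "' must be a length-2 (x, y) coordinate")
  if (z[1] < 0 || z[1] >= W || z[2] < 0 || z[2] >= H)
    stop("'", what, "' (", z[1], ", ", z[2], ") is outside the ",
         H, " x ", W, " grid")
  invisible(z)
}

.map_at <- function(map, z) map[floor(z[2]) + 1L, floor(z[1]) + 1L]

#' Local attention map
#'
#' The probability map of the next fixation under the local attention mode: a
#' bivariate Gaussian with diagonal covariance \eqn{(\epsilon_x, \epsilon_y)}
#' centered on the current fixation, evaluated at pixel centers and
#' renormalized over the image.
#'
#' @param zPrev current fixation, (x, y) pixel coordinates.
#' @param params a [ModelParams-class].
#' @param grid integer (H, W) pixel counts, or a [SaliencyMap-class] whose
#'   geometry is used.
#' @return H x W matrix of per-pixel probabilities summing to 1.
#' @export
localMap <- function(zPrev, params, grid) {
  if (is(grid, "SaliencyMap")) grid <- gridSize(grid)
  H <- as.integer(grid[1]); W <- as.integer(grid[2])
  .check_loc(zPrev, H, W, "zPrev")
  cpp_local_map(H, W, zPrev[1], zPrev[2], params@epsX, params@epsY)
}

#' Global attention map
#'
#' The probability map of the next fixation under the global attention mode:
#' the saliency map modulated by a broad Gaussian (covariance \eqn{\xi}),
#' minus a local repulsion kernel (covariance \eqn{\epsilon}) that suppresses
#' short saccades, clamped at zero and renormalized:
#' \deqn{p(z) \propto \max(s(z)\, n(z; z_{prev}, \xi) - n(z; z_{prev},
#'   \epsilon),\, 0).}
#'
#' @inheritParams localMap
#' @param saliency a [SaliencyMap-class].
#' @param unnormalized return the raw clamped map (before division by its
#'   total mass) — used by the inference machinery.
#' @return H x W matrix; the normalized map sums to 1. If every pixel is
#'   clamped to zero the parameter region is invalid and an error of class
#'   `lga_degenerate_map` is raised.
#' @export
globalMap <- function(zPrev, params, saliency, unnormalized = FALSE) {
  s <- mapValues(saliency)
  .check_loc(zPrev, nrow(s), ncol(s), "zPrev")
  if (params@xiX <= params@epsX || params@xiY <= params@epsY)
    stop("globalMap needs xi > eps componentwise")
  raw <- cpp_global_map(s, zPrev[1], zPrev[2], params@epsX, params@epsY,
                        params@xiX, params@xiY)
  if (unnormalized) return(raw$map)
  if (raw$total <= 0)
    stop(structure(class = c("lga_degenerate_map", "error", "condition"),
                   list(message = "global attention map is everywhere zero (degenerate parameters)",
                        call = sys.call())))
  raw$map / raw$total
}

#' Local-saliency step map (one-mode simplified variant)
#'
#' The saliency map modulated by a single Gaussian around the current
#' fixation: \eqn{p(z) \propto s(z)\, n(z; z_{prev}, \xi)}.
#'
#' @inheritParams globalMap
#' @return H x W probability matrix summing to 1.
#' @export
localSaliencyMap <- function(zPrev, params, saliency) {
  s <- mapValues(saliency)
  .check_loc(zPrev, nrow(s), ncol(s), "zPrev")
  raw <- cpp_local_saliency_map(s, zPrev[1], zPrev[2], params@xiX, params@xiY)
  if (raw$total <= 0)
    stop("local-saliency map has zero mass")
  raw$map / raw$total
}

#' Saliency-baseline step map
#'
#' The history-independent baseline: every fixation is drawn from the
#' saliency map itself.
#'
#' @param saliency a [SaliencyMap-class].
#' @return H x W probability matrix (the saliency raster).
#' @export
saliencyBaselineMap <- function(saliency) mapValues(saliency)

#' Gating probability between local and global attention
#'
#' The probability \eqn{\rho_t} of taking a local step, a logistic function
#' of the saliency history: for the full model
#' \eqn{\rho_t = \sigma(b (s_{t-1}/s_{t-2} - s^o))}, for the local-choice
#' variant \eqn{\rho_t = \sigma(b (s_{t-1} - s^o))}, and a constant
#' `rhoFixed` for the fixed-choice variant. The denominator saliency is
#' floored at 1e-12 of the map mass before division.
#'
#' @param sPrev saliency value at the most recent fixation (vectorized).
#' @param sPrev2 saliency value at the fixation before it (ignored by the
#'   local-choice and fixed-choice variants).
#' @param params a [ModelParams-class].
#' @return gating probabilities in (0, 1).
#' @export
rhoLink <- function(sPrev, sPrev2 = NULL, params) {
  switch(params@variant,
    full = {
      if (is.null(sPrev2)) stop("the full variant needs 'sPrev2'")
      ratio <- sPrev / pmax(sPrev2, .RATIO_FLOOR)
      plogis(params@b * (ratio - params@sO))
    },
    local_choice = plogis(params@b * (sPrev - params@sO)),
    fixed_choice = rep_len(params@rhoFixed, length(sPrev)),
    stop("rhoLink is undefined for variant '", params@variant, "'"))
}

#' Step-transition probability with its mixture breakdown
#'
#' Probability of observing fixation `zT` given the two preceding fixations,
#' as the convex mixture \eqn{\rho_t p_{local} + (1 - \rho_t) p_{global}}
#' of the local and global attention maps (mixture variants), together with
#' the pieces the inference and evaluation modules need.
#'
#' @param zT next fixation (x, y).
#' @param zPrev,zPrev2 the two preceding fixations (most recent first).
#' @param params a [ModelParams-class] with variant "full", "local_choice"
#'   or "fixed_choice".
#' @param saliency a [SaliencyMap-class].
#' @return list with `prob`, `rho`, `pLocal`, `pGlobal` (per-pixel values at
#'   `zT` of the two component maps).
#' @export
stepProbability <- function(zT, zPrev, zPrev2, params, saliency) {
  if (!params@variant %in% c("full", "local_choice", "fixed_choice"))
    stop("stepProbability applies to the mixture variants only")
  s <- mapValues(saliency)
  .check_loc(zT, nrow(s), ncol(s), "zT")
  pl <- .map_at(localMap(zPrev, params, saliency), zT)
  pg <- .map_at(globalMap(zPrev, params, saliency), zT)
  rho <- rhoLink(.map_at(s, zPrev), .map_at(s, zPrev2), params)
  list(prob = rho * pl + (1 - rho) * pg, rho = rho, pLocal = pl, pGlobal = pg)
}

#' Full step-prediction map for the upcoming fixation
#'
#' The conditional distribution over all pixels for the next fixation given
#' the (observed) history, under any variant. This is the per-step
#' probabilistic classifier used by the evaluation metrics.
#'
#' @inheritParams stepProbability
#' @param zPrev2 required by the full variant only.
#' @param degenerateGlobal what to do when the clamped global map has no
#'   positive pixel at this step: "error" (the likelihood contract) or
#'   "fallback", which substitutes the repulsion-free saliency-modulated
#'   Gaussian ([localSaliencyMap()]) for the global component so that
#'   predictive scoring of arbitrary parameter sets stays defined.
#' @return H x W probability matrix summing to 1.
#' @export
stepMap <- function(zPrev, zPrev2 = NULL, params, saliency,
                    degenerateGlobal = c("error", "fallback")) {
  degenerateGlobal <- match.arg(degenerateGlobal)
  switch(params@variant,
    saliency_baseline = saliencyBaselineMap(saliency),
    local_saliency = localSaliencyMap(zPrev, params, saliency),
    {
      s <- mapValues(saliency)
      rho <- rhoLink(.map_at(s, zPrev),
                     if (is.null(zPrev2)) NULL else .map_at(s, zPrev2),
                     params)
      glob <- if (degenerateGlobal == "fallback")
        tryCatch(globalMap(zPrev, params, saliency),
                 lga_degenerate_map = function(e)
                   localSaliencyMap(zPrev, params, saliency))
      else globalMap(zPrev, params, saliency)
      rho * localMap(zPrev, params, saliency) + (1 - rho) * glob
    })
}

#' Scan-path log-likelihood
#'
#' The log-likelihood of an observed scan path: the first two fixations are
#' scored under the saliency map itself, and each subsequent fixation under
#' the variant's step distribution conditioned on the observed history,
#' \deqn{\log p(Z|\Theta) = \log s(z_1) + \log s(z_2) +
#'   \sum_{t=3}^{T} \log p(z_t | z_{t-1}, z_{t-2}).}
#' Per-step probabilities of exactly zero (possible through the clamp in the
#' global map) are floored at 1e-300 before the log; the affected steps are
#' reported in the `zeroSteps` attribute.
#'
#' @param path a [ScanPath-class] or T x 2 coordinate matrix.
#' @param params a [ModelParams-class].
#' @param saliency a [SaliencyMap-class].
#' @param base logarithm base for the returned value: "nat" (natural, the
#'   default) or "bits" (base 2, as used by information gain).
#' @return the log-likelihood, with attributes `steps` (per-fixation log
#'   probabilities, length T) and `zeroSteps` (indices of floored steps).
#' @export
scanpathLogLik <- function(path, params, saliency, base = c("nat", "bits")) {
  base <- match.arg(base)
  loc <- if (is(path, "ScanPath")) locations(path) else as.matrix(path)
  T_ <- nrow(loc)
  if (T_ < 2L) stop("a scan path needs at least 2 fixations")
  s <- mapValues(saliency)
  for (t in seq_len(T_)) .check_loc(loc[t, ], nrow(s), ncol(s), "fixation")
  steps <- numeric(T_)
  zero <- integer(0)
  for (t in 1:2) {
    p <- .map_at(s, loc[t, ])
    if (p <= 0) zero <- c(zero, t)
    steps[t] <- log(max(p, .PROB_FLOOR))
  }
  if (T_ >= 3L) for (t in 3:T_) {
    p <- switch(params@variant,
      saliency_baseline = .map_at(s, loc[t, ]),
      local_saliency = .map_at(localSaliencyMap(loc[t - 1L, ], params,
                                                saliency), loc[t, ]),
      stepProbability(loc[t, ], loc[t - 1L, ], loc[t - 2L, ], params,
                      saliency)$prob)
    if (p <= 0) zero <- c(zero, t)
    steps[t] <- log(max(p, .PROB_FLOOR))
  }
  if (base == "bits") steps <- steps / log(2)
  structure(sum(steps), steps = steps, zeroSteps = zero)
}
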