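#' Construct a SaliencyMap
#'
#' Wraps a non-negative raster as a [SaliencyMap-class], renormalizing it to
#' unit total mass.
#'
#' @param values numeric H x W matrix of non-negative values (rows are image
#'   rows, i.e. the y axis; columns the x axis).
#' @param pxPerDegree optional pixels-per-degree scale for unit conversion.
#' @param normalize divide by the total mass (default). With
#'   `normalize = FALSE` the input must already sum to 1.
#' @return a [SaliencyMap-class].
#' @examples
#' m <- SaliencyMap(matrix(1, 8, 8))
#' sum(mapValues(m))
#' @export
SaliencyMap <- function(values, pxPerDegree = NA_real_, normalize = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("saliency raster contains NA")
  if (any(values < 0)) stop("saliency raster must be non-negative")
  if (normalize) {
    tot <- sum(values)
    if (tot <= 0) stop("saliency raster has zero total mass")
    values <- values / tot
  }
  new("SaliencyMap", values = unname(values),
      pxPerDegree = as.numeric(pxPerDegree))
}

#' @rdname lgattention-generics
#' @export
setMethod("mapValues", "SaliencyMap", function(x) x@values)

#' @rdname lgattention-generics
#' @export
setMethod("pxPerDegree", "SaliencyMap", function(x) x@pxPerDegree)

#' @rdname lgattention-generics
#' @export
setMethod("gridSize", "SaliencyMap",
          function(x) c(H = nrow(x@values), W = ncol(x@values)))

setMethod("dim", "SaliencyMap", function(x) dim(x@values))

setMethod("show", "SaliencyMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("SaliencyMap: %d x %d pixels", d[1], d[2]))
  if (!is.na(object@pxPerDegree))
    cat(sprintf(" (%.3g px/deg)", object@pxPerDegree))
  cat(sprintf("\n  max %.3g at (x=%d, y=%d), min %.3g\n",
              max(object@values),
              (which.max(object@values) - 1L) %/% nrow(object@values),
              (which.max(object@values) - 1L) %% nrow(object@values),
              min(object@values)))
})

#' Read / write a saliency raster as a dense text matrix
#'
#' The on-disk format is a plain whitespace- or comma-delimited dense matrix
#' (H rows x W columns, row-major). An optional sidecar file `<path>.meta`
#' with a `px_per_degree: <value>` line carries the pixel scale.
#'
#' @param path file path.
#' @param map a [SaliencyMap-class] (for writing).
#' @return `readSaliencyMap` returns a [SaliencyMap-class];
#'   `writeSaliencyMap` returns `path` invisibly.
#' @export
readSaliencyMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  vals <- as.matrix(read.table(path, header = FALSE, sep = sep))
  ppd <- NA_real_
  meta <- paste0(path, ".meta")
  if (file.exists(meta)) {
    ln <- grep("^\\s*px_per_degree\\s*:", readLines(meta), value = TRUE)
    if (length(ln))
      ppd <- as.numeric(sub("^\\s*px_per_degree\\s*:\\s*", "", ln[1]))
  }
  SaliencyMap(vals, pxPerDegree = ppd)
}

#' @rdname readSaliencyMap
#' @export
writeSaliencyMap <- function(map, path) {
  stopifnot(is(map, "SaliencyMap"))
  write.table(format(mapValues(map), digits = 17), path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  if (!is.na(pxPerDegree(map)))
    writeLines(sprintf("px_per_degree: %.17g", pxPerDegree(map)),
               paste0(path, ".meta"))
  invisible(path)
}

#' Empirical saliency map by kernel density estimation
#'
#' Approximates the saliency map of an image by the experimentally observed
#' fixation density: an isotropic Gaussian kernel-density estimate of all
#' fixations recorded on the image (pooled over subjects and trials),
#' evaluated at pixel centers and renormalized within the image. Kernels are
#' evaluated inside the image only (no wraparound or reflection).
#'
#' @param fixations a fixation table (see [loadFixationTable()]).
#' @param imageId the image to estimate; must occur in `fixations$image_id`.
#' @param grid integer (H, W) pixel counts of the image raster.
#' @param bandwidth kernel standard deviation in pixels. Default: one degree
#'   of visual angle when `pxPerDegree` is given, otherwise W / 35.
#' @param pxPerDegree optional pixel scale, stored on the result and used for
#'   the default bandwidth.
#' @return a [SaliencyMap-class].
#' @export
empiricalSaliency <- function(fixations, imageId, grid,
                              bandwidth = NULL, pxPerDegree = NA_real_) {
  fixations <- validateFixationTable(fixations, grid)
  fx <- fixations[fixations$image_id == imageId, , drop = FALSE]
  if (!nrow(fx)) stop("no fixations for image_id '", imageId, "'")
  if (is.null(bandwidth))
    bandwidth <- if (!is.na(pxPerDegree)) pxPerDegree else grid[2] / 35
  if (bandwidth <= 0) stop("'bandwidth' must be positive")
  H <- as.integer(grid[1]); W <- as.integer(grid[2])
  # separable kernels accumulated per fixation
  vals <- matrix(0, H, W)
  xs <- 0:(W - 1L); ys <- 0:(H - 1L)
  for (i in seq_len(nrow(fx))) {
    kx <- dnorm(xs, mean = fx$x[i], sd = bandwidth)
    ky <- dnorm(ys, mean = fx$y[i], sd = bandwidth)
    vals <- vals + outer(ky, kx)
  }
  SaliencyMap(vals, pxPerDegree = pxPerDegree)
}

#' Synthetic multi-modal saliency map
#'
#' Generates a fixture saliency map standing in for an empirical fixation
#' density: a mixture of `nModes` random anisotropic Gaussian bumps plus a
#' small uniform floor, normalized to unit mass. Bump centers are resampled
#' until pairwise well separated so that the requested number of local maxima
#' is actually present. Deterministic given `seed`.
#'
#' @param grid integer (H, W) pixel counts.
#' @param nModes number of Gaussian bumps (>= 1).
#' @param seed integer seed (NULL: use the current RNG stream).
#' @param floorMass total mass of the uniform floor (default 0.02).
#' @param pxPerDegree optional pixel scale stored on the result.
#' @return a [SaliencyMap-class].
#' @export
syntheticSaliency <- function(grid, nModes = 3L, seed = NULL,
                              floorMass = 0.02, pxPerDegree = NA_real_) {
  if (nModes < 1L) stop("'nModes' must be >= 1")
  H <- as.integer(grid[1]); W <- as.integer(grid[2])
  with_seed(seed, {
    sds <- cbind(runif(nModes, W / 16, W / 8), runif(nModes, H / 16, H / 8))
    minsep <- 2.5 * max(sds)
    centers <- matrix(NA_real_, nModes, 2)
    for (k in seq_len(nModes)) {
      for (try in 1:200) {
        cand <- c(runif(1, 0.12 * W, 0.88 * W), runif(1, 0.12 * H, 0.88 * H))
        if (k == 1L) break
        d <- sqrt(rowSums((centers[seq_len(k - 1L), , drop = FALSE] -
                           matrix(cand, k - 1L, 2, byrow = TRUE))^2))
        if (all(d >= minsep)) break
      }
      centers[k, ] <- cand
    }
    rot <- runif(nModes, -pi / 4, pi / 4)
    wts <- runif(nModes, 0.5, 1)
    wts <- wts / sum(wts)
    xs <- 0:(W - 1L); ys <- 0:(H - 1L)
    vals <- matrix(0, H, W)
    for (k in seq_len(nModes)) {
      dx <- outer(rep(1, H), xs - centers[k, 1])
      dy <- outer(ys - centers[k, 2], rep(1, W))
      u <- cos(rot[k]) * dx + sin(rot[k]) * dy
      v <- -sin(rot[k]) * dx + cos(rot[k]) * dy
      vals <- vals + wts[k] *
        exp(-0.5 * (u / sds[k, 1])^2 - 0.5 * (v / sds[k, 2])^2) /
        (2 * pi * sds[k, 1] * sds[k, 2])
    }
    vals <- (1 - floorMass) * vals / sum(vals) + floorMass / (H * W)
    SaliencyMap(vals, pxPerDegree = pxPerDegree)
  })
}
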