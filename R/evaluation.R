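# Likelihood-based predictive scores and saccade-statistics analyses. The
# per-step conditional probability map (conditioned on the *observed*
# history) is used as the probabilistic classifier for every score.

#' AUC-Borji from positive and negative classifier scores
#'
#' ROC area with the model's map values at true fixations as positives and
#' map values at uniformly sampled image coordinates as negatives, computed
#' by midrank (equivalent to trapezoidal integration of the ROC curve and to
#' the Mann-Whitney pair-count statistic).
#'
#' @param positives classifier scores at fixated locations.
#' @param negatives classifier scores at uniformly sampled locations.
#' @return AUC in \[0, 1\]; exactly 0.5 (with a warning) if all scores are
#'   identical.
#' @export
aucBorji <- function(positives, negatives) {
  n1 <- length(positives); n0 <- length(negatives)
  if (!n1 || !n0) stop("need at least one positive and one negative score")
  if (length(unique(c(positives, negatives))) == 1L) {
    warning("all classifier scores identical; AUC = 0.5")
    return(0.5)
  }
  r <- rank(c(positives, negatives))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Normalized scanpath saliency of a set of scored steps
#'
#' Each step's prediction map is z-scored over the image (population standard
#' deviation); the NSS is the mean z-value at the true fixations. Steps with
#' a constant map contribute 0 with a warning.
#'
#' @param values map values at the true fixations.
#' @param mapMeans,mapSds per-step mean and population sd of the prediction
#'   maps.
#' @return the NSS.
#' @export
nssScore <- function(values, mapMeans, mapSds) {
  z <- numeric(length(values))
  const <- mapSds <= 0
  if (any(const)) warning("constant prediction map; step contributes 0 to NSS")
  z[!const] <- (values[!const] - mapMeans[!const]) / mapSds[!const]
  mean(z)
}

#' Information gain over the uniform baseline
#'
#' Mean, over fixations, of the model's log2 step probability relative to a
#' uniform distribution over pixels:
#' \deqn{IG = mean_t [\log_2 p(z_t) + \log_2(H W)]} in bit/fix.
#'
#' @param logProb per-fixation natural-log step probabilities (floored
#'   upstream, so finite).
#' @param nPixels number of pixels H * W.
#' @return information gain in bit/fix.
#' @export
informationGain <- function(logProb, nPixels) {
  mean(logProb / log(2) + log2(nPixels))
}

#' Score scan paths under a model
#'
#' Teacher-forced predictive scoring: for every fixation of every path the
#' step-prediction map conditioned on the observed history is computed
#' ([stepMap()]; the first two fixations are scored under the saliency map
#' itself), and AUC-Borji, NSS and information gain are accumulated.
#'
#' @param fixations fixation table of the paths to score.
#' @param maps named list of [SaliencyMap-class] keyed by image_id.
#' @param params a [ModelParams-class].
#' @param nNegatives uniformly sampled negatives per positive for the AUC.
#' @param scoreFirstTwo score the first two fixations under \eqn{p(z) = s(z)}
#'   (default); otherwise only steps t >= 3 are scored.
#' @param seed seed for the negative sampling.
#' @return list with `auc`, `nss`, `ig` (bit/fix), `n` (scored fixations)
#'   and the per-fixation score table `perFixation`.
#' @export
scoreScanpaths <- function(fixations, maps, params, nNegatives = 10L,
                           scoreFirstTwo = TRUE, seed = NULL) {
  if (is(maps, "SaliencyMap")) maps <- list(maps)
  paths <- fixationsToPaths(fixations)
  with_seed(seed, {
    pos <- zval <- lp <- numeric(0)
    negs <- list()
    npx <- NA_integer_
    for (p in paths) {
      imap <- maps[[attr(p, "image_id")]]
      s <- mapValues(imap)
      npx <- length(s)
      loc <- locations(p)
      T_ <- nrow(loc)
      start <- if (scoreFirstTwo) 1L else 3L
      for (t in seq(start, T_)) {
        m <- if (t <= 2L) s
             else stepMap(loc[t - 1L, ], if (t >= 3L) loc[t - 2L, ], params,
                          imap, degenerateGlobal = "fallback")
        v <- .map_at(m, loc[t, ])
        mu <- mean(m); sdv <- sqrt(mean((m - mu)^2))
        pos <- c(pos, v)
        zval <- c(zval, if (sdv > 0) (v - mu) / sdv else 0)
        lp <- c(lp, log(max(v, .PROB_FLOOR)))
        ix <- sample.int(npx, nNegatives, replace = TRUE)
        negs[[length(negs) + 1L]] <- m[ix]
      }
    }
    list(auc = aucBorji(pos, unlist(negs)),
         nss = mean(zval),
         ig = informationGain(lp, npx),
         n = length(pos),
         perFixation = data.frame(value = pos, z = zval, logp = lp))
  })
}

#' Saccade amplitudes, directions and direction changes
#'
#' Saccades are the vectors between consecutive fixations: amplitude is the
#' Euclidean length in pixels (divide by the map's `pxPerDegree` for
#' degrees), direction the `atan2(dy, dx)` angle in degrees in (-180, 180\]
#' (image coordinates, y pointing down), and direction change the circular
#' difference of consecutive directions wrapped to (-180, 180\].
#'
#' @param x a fixation table, a [ScanPath-class], or a list of
#'   [ScanPath-class].
#' @return data.frame with one row per saccade: `path` (trial key),
#'   `amplitude`, `direction`, and `directionChange` (NA for the first
#'   saccade of each path).
#' @export
saccadeStatistics <- function(x) {
  paths <- if (is(x, "ScanPath")) list(path = x)
           else if (is.data.frame(x)) fixationsToPaths(x)
           else x
  keys <- names(paths) %||% as.character(seq_along(paths))
  rows <- lapply(seq_along(paths), function(k) {
    loc <- locations(paths[[k]])
    d <- diff(loc)
    amp <- sqrt(rowSums(d^2))
    dir <- atan2(d[, 2], d[, 1]) * 180 / pi
    dir[dir <= -180] <- dir[dir <= -180] + 360
    dch <- c(NA_real_, .wrap_angle(diff(dir)))
    sid <- attr(paths[[k]], "subject_id")
    data.frame(path = keys[k],
               subject_id = if (is.null(sid)) NA_character_ else sid,
               amplitude = amp, direction = dir, directionChange = dch)
  })
  do.call(rbind, rows)
}

# wrap angles (degrees) to (-180, 180]
.wrap_angle <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a[a <= -180] <- a[a <= -180] + 360
  a
}

#' Mean amplitude autocorrelation over paths
#'
#' The standard sample autocorrelation of each path's saccade-amplitude
#' sequence at lags 0..`maxLag`, averaged over paths; paths too short for a
#' lag (fewer than lag + 2 amplitudes) are excluded at that lag.
#'
#' @param x fixation table or list of [ScanPath-class].
#' @param maxLag largest lag.
#' @return data.frame with `lag`, `acf` (mean over paths), `nPaths`.
#' @export
amplitudeAutocorrelation <- function(x, maxLag = 20L) {
  paths <- if (is.data.frame(x)) fixationsToPaths(x) else x
  amps <- lapply(paths, function(p) {
    loc <- locations(p)
    sqrt(rowSums(diff(loc)^2))
  })
  out <- matrix(NA_real_, length(amps), maxLag + 1L)
  for (k in seq_along(amps)) {
    a <- amps[[k]]
    if (length(a) < 2L || sd(a) == 0) next
    lagmax <- min(maxLag, length(a) - 2L)
    ac <- drop(acf(a, lag.max = lagmax, plot = FALSE, demean = TRUE)$acf)
    out[k, seq_len(lagmax + 1L)] <- ac
  }
  data.frame(lag = 0:maxLag,
             acf = colMeans(out, na.rm = TRUE),
             nPaths = colSums(!is.na(out)))
}

#' Per-subject amplitude moments
#'
#' @param fixations fixation table.
#' @return data.frame with `subject_id`, `meanAmplitude`, `sdAmplitude`,
#'   `nSaccades`.
#' @export
subjectMoments <- function(fixations) {
  st <- saccadeStatistics(fixations)
  agg <- split(st$amplitude, st$subject_id)
  data.frame(subject_id = names(agg),
             meanAmplitude = vapply(agg, mean, numeric(1)),
             sdAmplitude = vapply(agg, sd, numeric(1)),
             nSaccades = lengths(agg), row.names = NULL)
}

#' Amplitude-density confidence bands from posterior uncertainty
#'
#' Propagates parameter uncertainty into the saccade-amplitude density: each
#' of `nDraws` parameter sets drawn from the posterior generates one
#' simulated dataset (one path per image), whose amplitude density is
#' evaluated on a common grid; pointwise mean and central 95% band are
#' returned.
#'
#' @param posterior a [PosteriorSamples-class].
#' @param maps named list of [SaliencyMap-class] to simulate on.
#' @param nFix fixations per simulated path.
#' @param nDraws posterior draws (default 50).
#' @param at amplitudes (pixels) at which the density is evaluated; default
#'   a grid to the image diagonal.
#' @param seed integer seed.
#' @return data.frame with `amplitude`, `mean`, `lower`, `upper` (2.5% and
#'   97.5% pointwise quantiles over draws).
#' @export
amplitudeDensityBands <- function(posterior, maps, nFix = 35L, nDraws = 50L,
                                  at = NULL, seed = NULL) {
  if (is(maps, "SaliencyMap")) maps <- list(img1 = maps)
  if (is.null(at)) {
    d <- gridSize(maps[[1]])
    at <- seq(0, sqrt(sum(d^2)), length.out = 128L)
  }
  seeds <- spawn_seeds(seed, nDraws + 1L)
  paramSets <- posteriorDrawParams(posterior, nDraws, seed = seeds[[1]])
  dens <- vapply(seq_len(nDraws), function(i) {
    tab <- sampleCohort(maps, paramSets[[i]], nFix = nFix,
                        seed = seeds[[i + 1L]])
    amp <- saccadeStatistics(tab)$amplitude
    kd <- density(amp, from = min(at), to = max(at), n = length(at))
    kd$y
  }, numeric(length(at)))
  data.frame(amplitude = at,
             mean = rowMeans(dens),
             lower = apply(dens, 1, quantile, 0.025, names = FALSE),
             upper = apply(dens, 1, quantile, 0.975, names = FALSE))
}

#' Coefficient of determination against the identity line
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the simulated values taken as
#' predictions of the observed ones (so a constant prediction yields
#' \eqn{R^2 \le 0}, which is reported as is).
#'
#' @param observed,simulated per-subject statistics (same order).
#' @return the coefficient of determination.
#' @export
coefficientOfDetermination <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 2L)
    stop("need >= 2 paired values")
  1 - sum((observed - simulated)^2) / sum((observed - mean(observed))^2)
}
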