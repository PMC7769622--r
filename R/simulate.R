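# Forward simulation: categorical sampling of fixations from the model's
# per-step probability maps (exact inverse-CDF sampling over pixels, no
# within-pixel jitter, so simulation and likelihood share the same discrete
# measure).

.sample_pixel <- function(map) {
  i <- sample.int(length(map), 1L, prob = as.vector(map))
  H <- nrow(map)
  c((i - 1L) %/% H, (i - 1L) %% H)  # (x, y), 0-based
}

#' Simulate one scan path from the model
#'
#' The first two fixations are drawn independently from the saliency map
#' (\eqn{p(z) = s(z)}). For every later fixation of a mixture variant, a
#' latent mode indicator \eqn{\gamma_t \sim Bernoulli(\rho_t)} selects the
#' local (\eqn{\gamma_t = 1}) or global (\eqn{\gamma_t = 0}) attention map,
#' and the fixation is drawn from the selected map. The one-mode variants
#' draw directly from their step map.
#'
#' @param saliency a [SaliencyMap-class].
#' @param params a [ModelParams-class].
#' @param nFix number of fixations T >= 2. Default 35, about 10 s of viewing
#'   at 3.5 saccades per second.
#' @param seed integer seed (NULL: current RNG stream).
#' @param recordTags record the latent local/global tags (mixture variants).
#' @return a [ScanPath-class]; tags are present when recorded.
#' @export
sampleScanpath <- function(saliency, params, nFix = 35L, seed = NULL,
                           recordTags = TRUE) {
  stopifnot(is(saliency, "SaliencyMap"), is(params, "ModelParams"))
  if (nFix < 2L) stop("'nFix' must be >= 2")
  s <- mapValues(saliency)
  mixture <- params@variant %in% c("full", "local_choice", "fixed_choice")
  with_seed(seed, {
    loc <- matrix(NA_real_, nFix, 2)
    tags <- if (recordTags && mixture) rep(NA_character_, nFix) else character(0)
    loc[1, ] <- .sample_pixel(s)
    loc[2, ] <- .sample_pixel(s)
    if (length(tags)) tags[1:2] <- "initial"
    if (nFix >= 3L) for (t in 3:nFix) {
      map <- switch(params@variant,
        saliency_baseline = s,
        local_saliency = localSaliencyMap(loc[t - 1L, ], params, saliency),
        {
          rho <- rhoLink(.map_at(s, loc[t - 1L, ]), .map_at(s, loc[t - 2L, ]),
                         params)
          g <- runif(1) < rho
          if (length(tags)) tags[t] <- if (g) "local" else "global"
          if (g) localMap(loc[t - 1L, ], params, saliency)
          else tryCatch(globalMap(loc[t - 1L, ], params, saliency),
                        lga_degenerate_map = function(e)
                          stop("degenerate global map at step ", t, ": ",
                               conditionMessage(e)))
        })
      loc[t, ] <- .sample_pixel(map)
    }
    scanPath(loc, tags = if (length(tags)) tags else character(0))
  })
}

#' Simulate a cohort of subjects
#'
#' One scan path per (subject, image) pair, mirroring a design with one trial
#' per image, flattened to a fixation table.
#'
#' @param maps named list of [SaliencyMap-class] (names are image ids).
#' @param paramsList list of [ModelParams-class], one per subject (names are
#'   subject ids; a single [ModelParams-class] is recycled).
#' @param nFix fixations per path.
#' @param seed integer master seed.
#' @param recordTags record latent tags (returned in the `tags` attribute).
#' @return fixation table (data.frame); per-fixation latent tags, when
#'   recorded, in `attr(, "tags")`.
#' @export
sampleCohort <- function(maps, paramsList, nFix = 35L, seed = NULL,
                         recordTags = FALSE) {
  if (is(paramsList, "ModelParams")) paramsList <- list(paramsList)
  nS <- length(paramsList); nI <- length(maps)
  image_ids <- names(maps) %||% sprintf("img%02d", seq_len(nI))
  subject_ids <- names(paramsList) %||% sprintf("subj%02d", seq_len(nS))
  seeds <- spawn_seeds(seed, nS * nI)
  rows <- vector("list", nS * nI)
  tag_col <- vector("list", nS * nI)
  k <- 0L
  for (s in seq_len(nS)) for (i in seq_len(nI)) {
    k <- k + 1L
    p <- sampleScanpath(maps[[i]], paramsList[[s]], nFix = nFix,
                        seed = seeds[[k]], recordTags = recordTags)
    loc <- locations(p)
    rows[[k]] <- data.frame(
      subject_id = subject_ids[s], image_id = image_ids[i], trial_id = 1L,
      fixation_index = seq_len(nrow(loc)), x = loc[, "x"], y = loc[, "y"])
    tag_col[[k]] <- if (length(pathTags(p))) pathTags(p)
                    else rep(NA_character_, nrow(loc))
  }
  out <- do.call(rbind, rows)
  if (recordTags) attr(out, "tags") <- unlist(tag_col, use.names = FALSE)
  out
}
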