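#' k-fold cross-validated predictive scores
#'
#' Splits the images into k seeded folds; for every subject and fold, the
#' model is fitted on the training-fold images and AUC-Borji, NSS and
#' information gain are computed on the held-out test-fold images
#' (teacher-forced scoring at the posterior mean, optionally averaged over
#' posterior draws). A separate model is fitted per subject.
#'
#' @param fixations fixation table (all subjects).
#' @param maps named list of [SaliencyMap-class] keyed by image_id.
#' @param variant model variant to fit and score.
#' @param hyper a [Hyperparams-class] or NULL for defaults.
#' @param k number of folds (>= 2; k = number of images gives
#'   leave-one-image-out).
#' @param control sampler settings for the per-fold fits.
#' @param nNegatives AUC negatives per positive.
#' @param posteriorDraws 0 scores at the posterior mean; a positive number
#'   scores that many posterior draws per fold and averages the scores.
#' @param seed integer master seed (fold assignment, fits, scoring).
#' @return data.frame with one row per (subject, fold): `variant`,
#'   `subject_id`, `fold`, `auc`, `nss`, `ig`, `nTest`, `converged`; pooled
#'   means are in `attr(, "pooled")` and the fold assignment in
#'   `attr(, "folds")`.
#' @export
crossValidate <- function(fixations, maps, variant = "full", hyper = NULL,
                          k = 5L, control = gibbsControl(), nNegatives = 10L,
                          posteriorDraws = 0L, seed = NULL) {
  fixations <- validateFixationTable(fixations)
  images <- unique(fixations$image_id)
  if (k < 2L || k > length(images))
    stop("'k' must be between 2 and the number of images")
  seeds <- spawn_seeds(seed, 2L)
  foldOf <- with_seed(seeds[[1]],
    setNames(rep_len(seq_len(k), length(images))[sample.int(length(images))],
             images))
  subjects <- unique(fixations$subject_id)
  fitSeeds <- spawn_seeds(seeds[[2]], length(subjects) * k * 2L)
  rows <- list()
  si <- 0L
  for (subj in subjects) {
    fsub <- fixations[fixations$subject_id == subj, , drop = FALSE]
    for (fold in seq_len(k)) {
      si <- si + 1L
      testImgs <- names(foldOf)[foldOf == fold]
      if (!length(testImgs)) stop("fold ", fold, " has no test images")
      train <- fsub[!fsub$image_id %in% testImgs, , drop = FALSE]
      test <- fsub[fsub$image_id %in% testImgs, , drop = FALSE]
      if (variant == "saliency_baseline") {
        # nothing to infer: every step is scored under the saliency map
        fit <- NULL
        scoreSets <- list(modelParams(epsX = 1, epsY = 1,
                                      variant = "saliency_baseline"))
      } else {
        fit <- suppressWarnings(
          runGibbs(train, maps, variant = variant, hyper = hyper,
                   control = control, seed = fitSeeds[[2L * si - 1L]]))
        scoreSets <- if (posteriorDraws > 0L)
          posteriorDrawParams(fit, posteriorDraws, seed = fitSeeds[[2L * si]])
        else list(posteriorMeanParams(fit))
      }
      sc <- lapply(seq_along(scoreSets), function(j)
        scoreScanpaths(test, maps, scoreSets[[j]], nNegatives = nNegatives,
                       seed = fitSeeds[[2L * si]]))
      rows[[si]] <- data.frame(
        variant = variant, subject_id = subj, fold = fold,
        auc = mean(vapply(sc, `[[`, numeric(1), "auc")),
        nss = mean(vapply(sc, `[[`, numeric(1), "nss")),
        ig = mean(vapply(sc, `[[`, numeric(1), "ig")),
        nTest = sc[[1]]$n,
        converged = if (is.null(fit)) TRUE else isConverged(fit))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "pooled") <- c(auc = mean(out$auc), nss = mean(out$nss),
                           ig = mean(out$ig))
  attr(out, "folds") <- foldOf
  out
}
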