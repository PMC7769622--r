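# Predictive scores and saccade-statistics analyses against hand oracles.

test_that("AUC-Borji equals exhaustive pair counting", {
  pos <- c(0.9, 0.8, 0.4); neg <- c(0.7, 0.3, 0.1)
  expect_equal(aucBorji(pos, neg), 8 / 9, tolerance = 1e-14)
  expect_equal(aucBorji(pos, neg), oracle_auc_paircount(pos, neg))
  # perfect separation and random instances with ties
  expect_equal(aucBorji(c(5, 6), c(1, 2, 3)), 1)
  set.seed(8)
  for (i in 1:15) {
    p <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)
    q <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)
    expect_equal(aucBorji(p, q), oracle_auc_paircount(p, q),
                 tolerance = 1e-12)
  }
  expect_warning(a <- aucBorji(rep(2, 5), rep(2, 7)), "identical")
  expect_equal(a, 0.5)
})

test_that("uniform prediction maps score at chance", {
  set.seed(11)
  pos <- runif(5000); neg <- runif(5000)
  expect_lt(abs(aucBorji(pos, neg) - 0.5), 0.02)
})

test_that("NSS is the z-scored map value, with the stated conventions", {
  # indicator map on N = 4 pixels: value (1 - 1/N) / sd
  m <- c(1, 0, 0, 0)
  mu <- mean(m); sdv <- sqrt(mean((m - mu)^2))
  expect_equal(nssScore(1, mu, sdv), (1 - 1 / 4) / sdv, tolerance = 1e-12)
  # constant maps contribute zero, with a warning
  expect_warning(z <- nssScore(c(0.5, 1), c(0.5, 0.8), c(0, 0.1)),
                 "constant")
  expect_equal(z, mean(c(0, 2)))
  # affine invariance: z-scores are unchanged under a * map + c
  v <- 0.37; mp <- runif(16)
  a <- 3.2; cc <- 0.7
  z1 <- (v - mean(mp)) / sqrt(mean((mp - mean(mp))^2))
  mp2 <- a * mp + cc; v2 <- a * v + cc
  z2 <- (v2 - mean(mp2)) / sqrt(mean((mp2 - mean(mp2))^2))
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("information gain matches hand arithmetic", {
  # uniform model on any grid gains nothing
  expect_equal(informationGain(rep(log(1 / 256), 9), 256), 0)
  # probability 1/2 on a 128 x 128 grid: 14 - 1 bits
  expect_equal(informationGain(log(0.5), 128 * 128), 13)
  # 3-step toy on 16 pixels: mean(4-2, 4-3, 4-1)
  expect_equal(informationGain(log(c(1 / 4, 1 / 8, 1 / 2)), 16),
               mean(c(2, 1, 3)), tolerance = 1e-12)
  # order invariance, and exact additive decomposition over two paths
  lp <- log(c(0.1, 0.02, 0.3, 0.05))
  expect_equal(informationGain(lp, 64), informationGain(rev(lp), 64))
  expect_equal(informationGain(lp, 64),
               (2 * informationGain(lp[1:2], 64) +
                2 * informationGain(lp[3:4], 64)) / 4)
})

test_that("saccade geometry follows hand trigonometry", {
  sp <- scanPath(rbind(c(0, 0), c(3, 4), c(6, 8), c(3, 4)))
  st <- saccadeStatistics(sp)
  expect_equal(st$amplitude, c(5, 5, 5))
  expect_equal(st$direction[1], atan2(4, 3) * 180 / pi, tolerance = 1e-12)
  # two identical consecutive vectors: no direction change
  expect_equal(st$directionChange[2], 0)
  # exact return saccade: +-180
  expect_equal(abs(st$directionChange[3]), 180)
  expect_true(is.na(st$directionChange[1]))
})

test_that("direction-change wrapping stays in (-180, 180]", {
  set.seed(14)
  loc <- cbind(cumsum(rnorm(40)), cumsum(rnorm(40))) + 50
  st <- saccadeStatistics(scanPath(loc))
  dch <- st$directionChange[-1]
  expect_true(all(dch > -180 & dch <= 180))
})

test_that("amplitude autocorrelation has the stated exact values", {
  # alternating sequence: lag-1 autocorrelation is the closed-form value of
  # the biased sample estimator on a finite alternating series
  amp <- rep(c(2, 8), 10)
  loc <- matrix(10, nrow = 21, ncol = 2)
  loc[, 1] <- cumsum(c(10, amp))  # saccades along x with those amplitudes
  ac <- amplitudeAutocorrelation(list(scanPath(loc)), maxLag = 2)
  expect_equal(ac$acf[ac$lag == 0], 1)
  expected_lag1 <- drop(acf(amp, lag.max = 1, plot = FALSE)$acf)[2]
  expect_equal(ac$acf[ac$lag == 1], expected_lag1, tolerance = 1e-12)
  expect_lt(ac$acf[ac$lag == 1], -0.9)
  # i.i.d. amplitudes: mean lag-1 autocorrelation near zero
  set.seed(15)
  paths <- replicate(400, {
    a <- rexp(20, 1 / 5)
    l <- matrix(40, 21, 2)
    l[, 1] <- 100 + cumsum(c(0, a * rep(c(1, -1), 10)))  # amplitudes = a
    scanPath(l)
  }, simplify = FALSE)
  acn <- amplitudeAutocorrelation(paths, maxLag = 1)
  se <- 1 / sqrt(20 * 400)
  expect_lt(abs(acn$acf[acn$lag == 1]), 5 * se)
})

test_that("subject moments and R-squared follow their definitions", {
  tab <- rbind(
    data.frame(subject_id = "a", image_id = "i", trial_id = 1L,
               fixation_index = 1:3, x = c(0, 3, 3), y = c(0, 4, 8)),
    data.frame(subject_id = "b", image_id = "i", trial_id = 1L,
               fixation_index = 1:3, x = c(0, 6, 6), y = c(0, 8, 16)))
  mom <- subjectMoments(tab)
  expect_equal(mom$meanAmplitude[mom$subject_id == "a"], mean(c(5, 4)))
  expect_equal(mom$meanAmplitude[mom$subject_id == "b"], mean(c(10, 8)))
  # identity prediction: R^2 = 1; hand-set 3-subject toy; constant <= 0
  expect_equal(coefficientOfDetermination(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(2, 4, 9); sim <- c(3, 5, 7)
  expect_equal(coefficientOfDetermination(obs, sim),
               1 - sum((obs - sim)^2) / sum((obs - mean(obs))^2))
  expect_lte(coefficientOfDetermination(obs, rep(5, 3)), 0)
})

test_that("teacher-forced scoring rewards the generating model", {
  p <- defaultTrueParams(2)
  ds <- syntheticDataset(p, nSubjects = 1, nImages = 4, nFix = 20,
                         grid = c(32, 32), pxPerDegree = 2, seed = 19)
  scTrue <- scoreScanpaths(ds$fixations, ds$maps, p, seed = 1)
  expect_true(scTrue$auc > 0.5 && scTrue$auc <= 1)
  expect_gt(scTrue$nss, 0)
  expect_gt(scTrue$ig, 0)
  expect_equal(scTrue$n, 4 * 20)
  # identical seeds give identical reports
  scTrue2 <- scoreScanpaths(ds$fixations, ds$maps, p, seed = 1)
  expect_identical(scTrue, scTrue2)
  # a mis-scaled model scores lower in IG
  bad <- modelParams(epsX = 100, epsY = 100, xiX = 900, xiY = 900,
                     b = 0, sO = 0)
  scBad <- scoreScanpaths(ds$fixations, ds$maps, bad, seed = 1)
  expect_gt(scTrue$ig, scBad$ig)
})

test_that("amplitude-density bands bracket the point density", {
  p <- defaultTrueParams(2)
  ds <- syntheticDataset(p, nSubjects = 1, nImages = 4, nFix = 15,
                         grid = c(32, 32), pxPerDegree = 2, seed = 41)
  fit <- suppressWarnings(
    runGibbs(ds$fixations, ds$maps, variant = "full",
             control = gibbsControl(nChains = 1, nIter = 150, burnIn = 60,
                                    leapfrog = 3), seed = 6))
  bands <- amplitudeDensityBands(fit, ds$maps, nFix = 15, nDraws = 8,
                                 seed = 9)
  expect_true(all(bands$lower <= bands$upper + 1e-12))
  expect_true(all(bands$mean >= 0))
  expect_gt(max(bands$mean), 0)
  expect_identical(bands,
                   amplitudeDensityBands(fit, ds$maps, nFix = 15,
                                         nDraws = 8, seed = 9))
})

test_that("cross-validation folds partition the images", {
  p <- defaultTrueParams(2)
  ds <- syntheticDataset(p, nSubjects = 1, nImages = 6, nFix = 8,
                         grid = c(24, 24), pxPerDegree = 2, seed = 23)
  cv <- crossValidate(ds$fixations, ds$maps, variant = "saliency_baseline",
                      k = 6,
                      control = gibbsControl(nChains = 1, nIter = 30,
                                             burnIn = 10, leapfrog = 2),
                      seed = 4)
  folds <- attr(cv, "folds")
  expect_setequal(names(folds), names(ds$maps))   # covers all images
  expect_true(all(table(folds) == 1L))            # leave-one-out
  expect_equal(nrow(cv), 6L)
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
})
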