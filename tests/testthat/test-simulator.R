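# Generative sampling of scan paths: seeded determinism, distributional
# checks against the maps that generated them, and cohort plumbing.

test_that("scan paths are reproducible and carry well-formed tags", {
  m <- syntheticSaliency(c(24, 24), nModes = 2, seed = 5)
  p <- defaultTrueParams(2)
  s1 <- sampleScanpath(m, p, nFix = 12, seed = 42)
  s2 <- sampleScanpath(m, p, nFix = 12, seed = 42)
  expect_identical(locations(s1), locations(s2))
  expect_identical(pathTags(s1), pathTags(s2))
  expect_equal(nFixations(s1), 12L)
  expect_identical(pathTags(s1)[1:2], c("initial", "initial"))
  expect_true(all(pathTags(s1)[-(1:2)] %in% c("local", "global")))
  s3 <- sampleScanpath(m, p, nFix = 12, seed = 43)
  expect_false(identical(locations(s1), locations(s3)))
  expect_error(sampleScanpath(m, p, nFix = 1), "nFix")
})

test_that("the first two fixations are distributed as the saliency map", {
  # multinomial frequency check over many T = 2 paths on a coarse map
  m <- syntheticSaliency(c(8, 8), nModes = 2, seed = 1)
  s <- mapValues(m)
  n <- 2e4
  counts <- matrix(0, 8, 8)
  set.seed(3)
  for (i in seq_len(n)) {
    loc <- locations(sampleScanpath(m, defaultTrueParams(2), nFix = 2))
    for (t in 1:2)
      counts[loc[t, 2] + 1, loc[t, 1] + 1] <-
        counts[loc[t, 2] + 1, loc[t, 1] + 1] + 1
  }
  freq <- counts / (2 * n)
  se <- sqrt(s * (1 - s) / (2 * n))
  expect_true(all(abs(freq - s) < 5 * se + 1e-4))
})

test_that("pure-local simulation reproduces the discrete truncated-Gaussian amplitude", {
  # fixed choice with rho = 1 steps only from the local map; the mean
  # simulated amplitude must match the exact expectation over the grid
  H <- W <- 41
  uni <- SaliencyMap(matrix(1, H, W))
  p <- modelParams(epsX = 4, epsY = 4, xiX = 100, xiY = 100,
                   variant = "fixed_choice", rhoFixed = 1)
  zc <- c(20, 20)
  m <- localMap(zc, p, uni)
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  # exact expectation and variance of the step length from an interior pixel
  expAmp <- sum(m * sqrt((xs - zc[1])^2 + (ys - zc[2])^2))
  varAmp <- sum(m * ((xs - zc[1])^2 + (ys - zc[2])^2)) - expAmp^2
  # simulate full paths and keep saccades launched well inside the grid
  # (sigma = 2 px, so truncation is negligible > 10 px from the border)
  set.seed(9)
  amps <- numeric(0)
  while (length(amps) < 1500) {
    loc <- locations(sampleScanpath(uni, p, nFix = 12))
    d <- diff(loc)[-1, , drop = FALSE]           # modeled steps t >= 3
    from <- loc[2:(nrow(loc) - 1), , drop = FALSE]
    interior <- from[, 1] >= 10 & from[, 1] <= W - 11 &
                from[, 2] >= 10 & from[, 2] <= H - 11
    amps <- c(amps, sqrt(rowSums(d[interior, , drop = FALSE]^2)))
  }
  expect_lt(abs(mean(amps) - expAmp), 4 * sqrt(varAmp / length(amps)))
})

test_that("cohorts flatten to valid fixation tables and order amplitudes by eps", {
  maps <- list(imgA = syntheticSaliency(c(36, 36), 2, seed = 2),
               imgB = syntheticSaliency(c(36, 36), 2, seed = 3),
               imgC = syntheticSaliency(c(36, 36), 2, seed = 4))
  small <- modelParams(epsX = 2, epsY = 2, xiX = 200, xiY = 200,
                       variant = "fixed_choice", rhoFixed = 0.7)
  large <- modelParams(epsX = 10, epsY = 10, xiX = 200, xiY = 200,
                       variant = "fixed_choice", rhoFixed = 0.7)
  tab <- sampleCohort(maps, list(s1 = small, s2 = large), nFix = 4, seed = 1)
  expect_equal(nrow(tab), 2 * 3 * 4)
  expect_silent(validateFixationTable(tab, grid = c(36, 36)))
  expect_identical(tab, sampleCohort(maps, list(s1 = small, s2 = large),
                                     nFix = 4, seed = 1))
  # subject with larger eps produces larger mean amplitude (Monte Carlo)
  tabMC <- sampleCohort(maps, list(s1 = small, s2 = large), nFix = 30,
                        seed = 12)
  mom <- subjectMoments(tabMC)
  expect_lt(mom$meanAmplitude[mom$subject_id == "s1"],
            mom$meanAmplitude[mom$subject_id == "s2"])
})

test_that("local-tag fraction converges to the mean gating probability", {
  m <- syntheticSaliency(c(32, 32), nModes = 3, seed = 8, pxPerDegree = 2)
  s <- mapValues(m)
  p <- modelParams(epsX = 6, epsY = 6, xiX = 150, xiY = 150, b = 2, sO = 1)
  nLocal <- 0; rhoTot <- 0; nStep <- 0
  set.seed(5)
  while (nStep < 1e4) {
    sp <- sampleScanpath(m, p, nFix = 35)
    loc <- locations(sp)
    sv <- s[cbind(loc[, 2] + 1, loc[, 1] + 1)]
    rho <- rhoLink(sv[2:34], sv[1:33], p)
    nLocal <- nLocal + sum(pathTags(sp)[3:35] == "local")
    rhoTot <- rhoTot + sum(rho)
    nStep <- nStep + 33
  }
  # binomial CI around the path-averaged gate
  expect_lt(abs(nLocal - rhoTot) / nStep, 4 * sqrt(0.25 / nStep))
})

test_that("amplitudes are a two-scale mixture split by the latent tags", {
  m <- syntheticSaliency(c(64, 64), nModes = 3, seed = 6, pxPerDegree = 2)
  p <- defaultTrueParams(2)  # eps well separated from xi
  ampL <- ampG <- numeric(0)
  set.seed(31)
  while (length(ampL) < 400 || length(ampG) < 400) {
    sp <- sampleScanpath(m, p, nFix = 35)
    loc <- locations(sp)
    amp <- sqrt(rowSums(diff(loc)^2))
    tg <- pathTags(sp)[-1]          # tag of the landing fixation
    ampL <- c(ampL, amp[tg == "local"])
    ampG <- c(ampG, amp[tg == "global"])
  }
  wt <- wilcox.test(ampL, ampG, alternative = "less")
  expect_lt(wt$p.value, 1e-6)
})

test_that("saliency-baseline simulations recover the input map", {
  # chi-square goodness of fit of aggregated fixations against the map
  m <- syntheticSaliency(c(16, 16), nModes = 2, seed = 14)
  p <- modelParams(epsX = 1, epsY = 1, variant = "saliency_baseline")
  set.seed(21)
  counts <- matrix(0, 16, 16)
  nFix <- 40
  for (i in 1:250) {
    loc <- locations(sampleScanpath(m, p, nFix = nFix))
    for (t in seq_len(nFix))
      counts[loc[t, 2] + 1, loc[t, 1] + 1] <-
        counts[loc[t, 2] + 1, loc[t, 1] + 1] + 1
  }
  n <- sum(counts)
  expected <- mapValues(m) * n
  keep <- expected >= 5
  chi <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  pval <- pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})
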