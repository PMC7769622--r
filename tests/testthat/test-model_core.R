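# Step distributions and scan-path likelihoods against brute-force oracles.

test_that("local map matches the per-pixel oracle and its contracts", {
  # 3x3 grid, unit variances: all 9 probabilities against direct evaluation
  p <- modelParams(epsX = 1, epsY = 1, xiX = 9, xiY = 9)
  m <- localMap(c(1, 1), p, grid = c(3, 3))
  expect_equal(m, oracle_local_map(3, 3, c(1, 1), 1, 1), tolerance = 1e-12)
  expect_equal(sum(m), 1, tolerance = 1e-12)

  # peak at the conditioning fixation; lateral symmetry
  p2 <- modelParams(epsX = 2, epsY = 3, xiX = 50, xiY = 50)
  m2 <- localMap(c(5, 4), p2, grid = c(9, 11))
  expect_equal(map_at(m2, c(5, 4)), max(m2))
  expect_equal(map_at(m2, c(3, 4)), map_at(m2, c(7, 4)), tolerance = 1e-14)
  expect_error(localMap(c(11, 4), p2, grid = c(9, 11)), "outside")
})

test_that("global map matches the brute-force evaluation on a 5x5 toy", {
  sal <- rand_saliency(5, 5, seed = 42)
  p <- modelParams(epsX = 0.5, epsY = 0.5, xiX = 4, xiY = 4)
  m <- globalMap(c(2, 2), p, sal)
  expect_equal(m, oracle_global_map(mapValues(sal), c(2, 2), 0.5, 0.5, 4, 4),
               tolerance = 1e-12)
  expect_equal(sum(m), 1, tolerance = 1e-9)
  expect_true(all(m >= 0))
})

test_that("the repulsion clamp zeroes the current location for uniform saliency", {
  # with uniform saliency, s * n_xi < n_eps at the center pixel, so the
  # probability there is exactly zero
  sal <- SaliencyMap(matrix(1, 9, 9))
  p <- modelParams(epsX = 1, epsY = 1, xiX = 16, xiY = 16)
  m <- globalMap(c(4, 4), p, sal)
  expect_identical(map_at(m, c(4, 4)), 0)
  expect_equal(sum(m), 1, tolerance = 1e-9)
})

test_that("degenerate global maps raise a typed error", {
  # tiny grid, saliency scaled so s * n_xi never exceeds n_eps anywhere
  sal <- SaliencyMap(matrix(1, 4, 4))
  p <- modelParams(epsX = 100, epsY = 100, xiX = 101, xiY = 101)
  expect_error(globalMap(c(1, 1), p, sal), class = "lga_degenerate_map")
})

test_that("the gating link is a logistic in the saliency ratio", {
  p0 <- modelParams(epsX = 1, epsY = 1, b = 0, sO = 3)
  expect_equal(rhoLink(0.9, 0.1, p0), 0.5)             # b = 0
  p1 <- modelParams(epsX = 1, epsY = 1, b = 2.7, sO = 4)
  expect_equal(rhoLink(0.8, 0.2, p1), 0.5)             # ratio equals s_o
  p2 <- modelParams(epsX = 1, epsY = 1, b = 2, sO = 1)
  expect_equal(rhoLink(0.4, 0.2, p2), 1 / (1 + exp(-2)))  # b(ratio - s_o) = 2
  # denominator guard: zero saliency at z_{t-2} stays finite
  expect_true(is.finite(rhoLink(0.5, 0, p2)) && rhoLink(0.5, 0, p2) <= 1)
})

test_that("the local-choice link uses the saliency value, monotonically", {
  p <- modelParams(epsX = 1, epsY = 1, b = 0, sO = 0.3,
                   variant = "local_choice")
  expect_equal(rhoLink(0.9, params = p), 0.5)
  p2 <- modelParams(epsX = 1, epsY = 1, b = 3, sO = 0.3,
                    variant = "local_choice")
  expect_equal(rhoLink(0.3, params = p2), 0.5)  # s = s_o
  vals <- rhoLink(seq(0, 1, by = 0.02), params = p2)
  expect_true(all(diff(vals) > 0))              # monotone in s for b > 0
})

test_that("step probability is the stated mixture of its own components", {
  sal <- rand_saliency(5, 5, seed = 7)
  # fixed-choice endpoints collapse onto the component maps
  pL <- modelParams(epsX = 0.3, epsY = 0.3, xiX = 4, xiY = 4,
                    variant = "fixed_choice", rhoFixed = 1)
  pG <- modelParams(epsX = 0.3, epsY = 0.3, xiX = 4, xiY = 4,
                    variant = "fixed_choice", rhoFixed = 0)
  z <- c(3, 1); zp <- c(2, 2); zp2 <- c(1, 3)
  expect_equal(stepProbability(z, zp, zp2, pL, sal)$prob,
               map_at(localMap(zp, pL, sal), z), tolerance = 1e-14)
  expect_equal(stepProbability(z, zp, zp2, pG, sal)$prob,
               map_at(globalMap(zp, pG, sal), z), tolerance = 1e-14)
  # full variant recomposed from its own breakdown by an independent formula
  pF <- modelParams(epsX = 0.3, epsY = 0.3, xiX = 4, xiY = 4, b = 1.2,
                    sO = 0.8)
  st <- stepProbability(z, zp, zp2, pF, sal)
  rho <- 1 / (1 + exp(-1.2 * (map_at(mapValues(sal), zp) /
                                map_at(mapValues(sal), zp2) - 0.8)))
  expect_equal(st$prob, rho * st$pLocal + (1 - rho) * st$pGlobal,
               tolerance = 1e-14)
  expect_equal(st$rho, rho, tolerance = 1e-14)
})

test_that("local-saliency map matches its oracle and reduces to a Gaussian on uniform saliency", {
  sal <- rand_saliency(4, 4, seed = 13)
  p <- modelParams(epsX = 1, epsY = 1, xiX = 3, xiY = 5,
                   variant = "local_saliency")
  m <- localSaliencyMap(c(1, 2), p, sal)
  expect_equal(m, oracle_local_saliency_map(mapValues(sal), c(1, 2), 3, 5),
               tolerance = 1e-12)
  expect_equal(sum(m), 1, tolerance = 1e-12)
  # uniform saliency: the constant cancels, leaving the xi-Gaussian
  uni <- SaliencyMap(matrix(1, 7, 7))
  m2 <- localSaliencyMap(c(3, 3), p, uni)
  expect_equal(m2, oracle_local_map(7, 7, c(3, 3), 3, 5), tolerance = 1e-12)
})

test_that("the saliency baseline is the identity and ignores history", {
  sal <- rand_saliency(6, 6, seed = 3)
  expect_identical(saliencyBaselineMap(sal), mapValues(sal))
  p <- modelParams(epsX = 1, epsY = 1, variant = "saliency_baseline")
  expect_equal(stepMap(c(1, 1), c(2, 2), p, sal),
               stepMap(c(5, 5), c(0, 0), p, sal))
})

test_that("scan-path log-likelihood composes per-step oracles", {
  sal <- rand_saliency(5, 5, seed = 21)
  s <- mapValues(sal)
  p <- modelParams(epsX = 0.3, epsY = 0.3, xiX = 4, xiY = 4, b = 1, sO = 1)
  loc <- rbind(c(1, 1), c(3, 2), c(2, 4), c(0, 2))
  ll <- scanpathLogLik(loc, p, sal)
  steps <- attr(ll, "steps")
  expect_equal(steps[1], log(map_at(s, loc[1, ])))
  expect_equal(steps[2], log(map_at(s, loc[2, ])))
  for (t in 3:4) {
    om <- oracle_global_map(s, loc[t - 1, ], 0.3, 0.3, 4, 4)
    ol <- oracle_local_map(5, 5, loc[t - 1, ], 0.3, 0.3)
    rho <- 1 / (1 + exp(-(map_at(s, loc[t - 1, ]) / map_at(s, loc[t - 2, ]) - 1)))
    expect_equal(steps[t],
                 log(rho * map_at(ol, loc[t, ]) + (1 - rho) * map_at(om, loc[t, ])),
                 tolerance = 1e-12)
  }
  expect_equal(as.numeric(ll), sum(steps))
  # T = 2: just the two initial factors
  ll2 <- scanpathLogLik(loc[1:2, ], p, sal)
  expect_equal(as.numeric(ll2), steps[1] + steps[2])
  # additivity: extending a path only adds step terms
  expect_equal(attr(scanpathLogLik(loc[1:3, ], p, sal), "steps"), steps[1:3])
  # each factor is a probability <= 1, so the log-likelihood never increases
  expect_lte(as.numeric(ll), as.numeric(ll2))
  # base-2 scaling
  expect_equal(as.numeric(scanpathLogLik(loc, p, sal, base = "bits")),
               as.numeric(ll) / log(2))
})

test_that("probability maps stay normalized across random parameter draws", {
  set.seed(99)
  for (i in 1:20) {
    H <- sample(4:12, 1); W <- sample(4:12, 1)
    sal <- rand_saliency(H, W, seed = i)
    ex <- runif(1, 0.3, 2); ey <- runif(1, 0.3, 2)
    p <- modelParams(epsX = ex, epsY = ey, xiX = ex * runif(1, 3, 20),
                     xiY = ey * runif(1, 3, 20), b = rnorm(1), sO = rnorm(1))
    zp <- c(sample(0:(W - 1), 1), sample(0:(H - 1), 1))
    expect_equal(sum(localMap(zp, p, sal)), 1, tolerance = 1e-9)
    expect_equal(sum(globalMap(zp, p, sal)), 1, tolerance = 1e-9)
    expect_equal(sum(localSaliencyMap(zp, p, sal)), 1, tolerance = 1e-9)
  }
})

test_that("model parameter validity enforces the scale ordering", {
  expect_error(modelParams(epsX = 4, epsY = 4, xiX = 3, xiY = 9), "dominate")
  expect_error(modelParams(epsX = -1, epsY = 1), "positive")
  expect_error(modelParams(epsX = 1, epsY = 1, variant = "fixed_choice",
                           rhoFixed = 1.4), "probability")
  # one-mode variants need no eps/xi ordering
  expect_s4_class(modelParams(epsX = 5, epsY = 5, xiX = 2, xiY = 2,
                              variant = "local_saliency"), "ModelParams")
})
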