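# Correctness of the augmented Gibbs sampler's building blocks: Polya-Gamma
# moments, the Bernoulli and Gaussian full conditionals, the HMC scale update
# in its conjugate limit, and prior reproduction on an empty dataset.

test_that("Polya-Gamma draws match the tanh moment identity", {
  n <- 1e5
  set.seed(1)
  for (c0 in c(0, 0.5, 2, 5)) {
    x <- rpolyagamma(n, c0)
    expect_true(all(x > 0))
    target <- if (c0 == 0) 0.25 else tanh(c0 / 2) / (2 * c0)
    expect_lt(abs(mean(x) - target), 4 * sd(x) / sqrt(n))
    # symmetry of the tilt
    y <- rpolyagamma(n, -c0)
    expect_lt(abs(mean(y) - target), 4 * sd(y) / sqrt(n))
  }
})

test_that("the mode indicator follows its Bernoulli full conditional", {
  # closed-form posterior: rho p_l / (rho p_l + (1 - rho) p_g)
  pr <- attr(sampleGamma(0.5, log(0.02), log(0.01)), "prob")
  expect_equal(pr, 2 / 3, tolerance = 1e-12)
  # endpoints
  expect_equal(attr(sampleGamma(1, log(0.1), log(0.9)), "prob"), 1)
  expect_equal(attr(sampleGamma(0.4, -Inf, log(0.9)), "prob"), 0)
  expect_error(sampleGamma(0.5, -Inf, -Inf), "inconsistency")
  # the log-space path agrees with the direct one away from saturation
  f <- c(-3, 0.2, 4)
  a <- attr(sampleGamma(plogis(f), log(c(0.1, 0.5, 0.2)),
                        log(c(0.3, 0.1, 0.2))), "prob")
  b <- attr(sampleGamma(plogis(f), log(c(0.1, 0.5, 0.2)),
                        log(c(0.3, 0.1, 0.2)), logitRho = f), "prob")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("link conditionals match a completion-of-squares oracle", {
  # single saccade, hand-set (gamma, w, x): the conditional mean/variance
  # must equal the quadratic-form solution computed symbolically here
  x <- 0.7; w <- 0.9; kappa <- 0.5; muB <- -0.3; sigB <- 2
  precOracle <- 1 / sigB^2 + w * x^2
  meanOracle <- (muB / sigB^2 + kappa * x) / precOracle
  set.seed(2)
  d <- sampleB(x, kappa, w, muB, sigB)
  expect_equal(attr(d, "mean"), meanOracle, tolerance = 1e-10)
  expect_equal(attr(d, "sd"), 1 / sqrt(precOracle), tolerance = 1e-10)

  r <- 1.4; b <- 1.1; muS <- 0.2; sigS <- 3
  precS <- 1 / sigS^2 + b^2 * w
  meanS <- (muS / sigS^2 + w * b^2 * r - b * kappa) / precS
  d2 <- sampleSO(r, kappa, w, b, muS, sigS)
  expect_equal(attr(d2, "mean"), meanS, tolerance = 1e-10)
  expect_equal(attr(d2, "sd"), 1 / sqrt(precS), tolerance = 1e-10)

  # no data: both reduce to the prior
  expect_equal(attr(sampleB(numeric(0), numeric(0), numeric(0), 1.5, 2),
                    "mean"), 1.5)
  expect_equal(attr(sampleSO(numeric(0), numeric(0), numeric(0), 2, -1, 3),
                    "sd"), 3)
  # b = 0 makes the s_o likelihood vanish
  expect_equal(attr(sampleSO(1.7, 0.5, 0.8, 0, -1, 3), "mean"), -1)

  # symmetric toy: sum(kappa) = 0 and ratios symmetric about s_o keep the
  # conditional mean at the prior-weighted center
  rr <- c(0.5, 1.5); kk <- c(-0.5, 0.5); ww <- c(0.4, 0.4); b2 <- 1
  d3 <- sampleSO(rr, kk, ww, b2, 1, 2)
  expect_equal(attr(d3, "mean"),
               (1 / 4 + sum(ww * b2^2 * rr - b2 * kk)) / (1 / 4 + b2^2 * sum(ww)),
               tolerance = 1e-12)
})

test_that("the w-marginalized Gibbs kernel reproduces the exact logistic posterior", {
  # 1-saccade toy: alternate w | b and b | w; the stationary marginal of b
  # must match the numerically normalized logistic-likelihood x prior
  # density (total variation on a binned grid)
  x <- 1.2; gam <- 1L; muB <- 0; sigB <- 2
  set.seed(33)
  b <- 0; keep <- numeric(4e4)
  for (i in seq_along(keep)) {
    w <- rpolyagamma(1, b * x)
    b <- as.numeric(sampleB(x, gam - 0.5, w, muB, sigB))
    keep[i] <- b
  }
  grid <- seq(-8, 10, length.out = 481)
  dens <- plogis(grid * x)^gam * (1 - plogis(grid * x))^(1 - gam) *
          dnorm(grid, muB, sigB)
  dens <- dens / sum(dens)
  edges <- seq(-8, 10, length.out = 61)
  hcount <- hist(keep[keep > -8 & keep < 10], breaks = edges, plot = FALSE)
  emp <- hcount$counts / length(keep)
  theo <- vapply(seq_len(60), function(k)
    sum(dens[grid >= edges[k] & grid < edges[k + 1]]), numeric(1))
  expect_lt(0.5 * sum(abs(emp - theo)), 0.02)
})

test_that("beta conditional of the fixed-choice probability is conjugate", {
  set.seed(4)
  g <- c(rep(1L, 7), rep(0L, 3))
  draws <- replicate(4e4, sampleRhoFixed(g, 1, 1))
  expect_lt(abs(mean(draws) - 8 / 12), 4 * sd(draws) / sqrt(4e4))
  # no data: the prior
  d0 <- replicate(2e4, sampleRhoFixed(integer(0), 3, 1))
  expect_lt(abs(mean(d0) - 0.75), 4 * sd(d0) / sqrt(2e4))
  # overwhelming data pins the draw
  expect_gt(sampleRhoFixed(rep(1L, 5000), 1, 1), 0.99)
})

test_that("HMC scale updates preserve support and hit the exact-flow limit", {
  set.seed(6)
  maps <- list(syntheticSaliency(c(32, 32), 2, seed = 3))
  p <- defaultTrueParams(2)
  sp <- sampleScanpath(maps[[1]], p, nFix = 20, seed = 8)
  loc <- locations(sp)
  prev <- loc[2:19, ]; cur <- loc[3:20, ]
  gamma <- as.integer(pathTags(sp)[3:20] == "local")
  hyper <- defaultHyperparams(2)
  # step size -> 0: acceptance probability -> 1
  res <- hmcUpdateScales(prev, cur, gamma, maps, rep(1L, 18), c(9, 7),
                         c(225, 169), hyper, stepSize = 1e-6, leapfrog = 3)
  expect_gt(res$alpha, 1 - 1e-6)
  # constraint preservation over repeated updates
  eps <- c(9, 7); xi <- c(225, 169)
  for (i in 1:30) {
    res <- hmcUpdateScales(prev, cur, gamma, maps, rep(1L, 18), eps, xi,
                           hyper, stepSize = 0.1, leapfrog = 5)
    eps <- res$eps; xi <- res$xi
    expect_true(xi[1] > eps[1] && xi[2] > eps[2])
  }
})


test_that("two chains on the same data agree", {
  p <- defaultTrueParams(2)
  ds <- syntheticDataset(p, nSubjects = 1, nImages = 6, nFix = 25,
                         grid = c(32, 32), pxPerDegree = 2, seed = 55)
  fit <- suppressWarnings(
    runGibbs(ds$fixations, ds$maps, variant = "full",
             control = gibbsControl(nChains = 2, nIter = 900, burnIn = 400,
                                    leapfrog = 5), seed = 7))
  expect_true(all(gelmanRhat(fit) < 1.2))
  expect_true(all(fit@acceptRate > 0.2 & fit@acceptRate < 0.99))
})

test_that("the local-saliency variant updates only xi", {
  p <- modelParams(epsX = 1, epsY = 1, xiX = 30, xiY = 30,
                   variant = "local_saliency")
  ds <- syntheticDataset(p, nSubjects = 1, nImages = 10, nFix = 25,
                         grid = c(24, 24), pxPerDegree = 2, seed = 12)
  fit <- suppressWarnings(
    runGibbs(ds$fixations, ds$maps, variant = "local_saliency",
             hyper = hyperparams(alphaXi = 2, betaXi = 300),
             control = gibbsControl(nChains = 2, nIter = 400, burnIn = 150,
                                    leapfrog = 5), seed = 3))
  d <- as.matrix(fit)
  expect_setequal(colnames(d), c("iteration", "xi_x", "xi_y",
                                 "log_posterior"))
  sm <- posteriorSummary(fit)
  # the generating scale is recovered to the right order
  expect_gt(sm$mean[sm$parameter == "xi_x"], 10)
  expect_lt(sm$mean[sm$parameter == "xi_x"], 150)
})
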