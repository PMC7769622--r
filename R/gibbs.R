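# The Gibbs sampler: gamma -> w -> b -> s_o -> (eps, xi) by HMC, with
# dispersed chain initializations and split-R-hat / ESS diagnostics.

#' Sampler settings
#'
#' @param nChains number of independent chains from dispersed starts.
#' @param nIter sweeps per chain.
#' @param burnIn sweeps discarded (and used for step-size adaptation).
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param leapfrog leapfrog steps per HMC transition.
#' @param linkSweeps repetitions of the (gamma, w, b, s_o) link block per
#'   sweep; extra repetitions are nearly free (no map evaluations) and
#'   decorrelate the link slope from the latent labels.
#' @param targetAccept dual-averaging target acceptance rate.
#' @param initStepSize initial leapfrog step size (log-scale coordinates).
#' @param rhatThreshold convergence threshold on split R-hat.
#' @param verbose print per-chain progress.
#' @return list of settings for [runGibbs()].
#' @export
gibbsControl <- function(nChains = 4L, nIter = 5000L, burnIn = 2000L,
                         thin = 1L, leapfrog = 10L, linkSweeps = 5L,
                         targetAccept = 0.65, initStepSize = 0.1,
                         rhatThreshold = 1.1, verbose = FALSE) {
  stopifnot(nIter > burnIn, burnIn >= 0, thin >= 1, nChains >= 1,
            linkSweeps >= 1)
  list(nChains = as.integer(nChains), nIter = as.integer(nIter),
       burnIn = as.integer(burnIn), thin = as.integer(thin),
       leapfrog = as.integer(leapfrog), linkSweeps = as.integer(linkSweeps),
       targetAccept = targetAccept, initStepSize = initStepSize,
       rhatThreshold = rhatThreshold, verbose = isTRUE(verbose))
}

# Flatten a fixation table + per-image maps into per-saccade arrays.
.prepare_gibbs_data <- function(fixations, maps, variant) {
  if (is(maps, "SaliencyMap")) maps <- list(maps)
  sList <- lapply(maps, mapValues)
  dims <- vapply(sList, dim, integer(2))
  if (length(sList) && !all(dims == dims[, 1]))
    stop("all saliency maps in one fit must share the same grid")
  H <- if (length(sList)) nrow(sList[[1]]) else 2L
  W <- if (length(sList)) ncol(sList[[1]]) else 2L
  empty <- list(sList = sList, img = integer(0),
                prev = matrix(0, 0, 2), cur = matrix(0, 0, 2),
                H = H, W = W, n = 0L, ratio = numeric(0),
                sPrev = numeric(0), pathId = integer(0), logS12 = 0)
  if (is.null(fixations) || !nrow(fixations)) return(empty)
  fixations <- validateFixationTable(fixations, grid = c(H, W))
  if (is.null(names(maps))) {
    ids <- unique(fixations$image_id)
    if (length(ids) != length(maps))
      stop("'maps' must be named by image_id when several images are present")
    names(maps) <- names(sList) <- ids
  }
  unknown <- setdiff(unique(fixations$image_id), names(maps))
  if (length(unknown))
    stop("no saliency map for image(s): ", paste(unknown, collapse = ", "))
  paths <- fixationsToPaths(fixations)
  prev <- cur <- NULL
  img <- pathId <- integer(0)
  sPrev <- sPrev2 <- numeric(0)
  logS12 <- 0
  for (k in seq_along(paths)) {
    loc <- locations(paths[[k]])
    s <- sList[[attr(paths[[k]], "image_id")]]
    iimg <- match(attr(paths[[k]], "image_id"), names(maps))
    sv <- s[cbind(floor(loc[, 2]) + 1L, floor(loc[, 1]) + 1L)]
    logS12 <- logS12 + sum(log(pmax(sv[1:2], .PROB_FLOOR)))
    T_ <- nrow(loc)
    if (T_ < 3L) next
    tt <- 3:T_
    prev <- rbind(prev, loc[tt - 1L, , drop = FALSE])
    cur <- rbind(cur, loc[tt, , drop = FALSE])
    sPrev <- c(sPrev, sv[tt - 1L])
    sPrev2 <- c(sPrev2, sv[tt - 2L])
    img <- c(img, rep(iimg, length(tt)))
    pathId <- c(pathId, rep(k, length(tt)))
  }
  n <- length(img)
  if (!n) {
    if (variant != "saliency_baseline")
      warning("no path has 3 or more fixations; sampling from the prior")
    return(empty)
  }
  list(sList = unname(sList), img = img - 1L, prev = unname(prev),
       cur = unname(cur), H = H, W = W, n = n,
       ratio = sPrev / pmax(sPrev2, .RATIO_FLOOR), sPrev = sPrev,
       pathId = pathId, logS12 = logS12)
}

.theta_log_prior <- function(eps, xi, b, sO, rho, hyper, variant) {
  out <- 0
  if (variant != "local_saliency")
    out <- out + sum(dinvgamma_log(eps, hyper@alphaEps, hyper@betaEps))
  out <- out + sum(dinvgamma_log(xi, hyper@alphaXi, hyper@betaXi))
  if (variant %in% c("full", "local_choice"))
    out <- out + dnorm(b, hyper@muB, hyper@sigmaB, log = TRUE) +
           dnorm(sO, hyper@muSo, hyper@sigmaSo, log = TRUE)
  if (variant == "fixed_choice")
    out <- out + stats::dbeta(rho, hyper@betaA, hyper@betaB, log = TRUE)
  out
}

# dispersed initialization; retried until the global map is non-degenerate
# Dispersed initialization; retried until the global map is non-degenerate.
# The scales are prior draws conditioned into data-bracketed windows: eps
# below the median squared step (but above a quarter of it, so that short
# saccades can register as local at all), xi above the median and below
# three upper deciles. Chains stay dispersed within the regime the mixture
# has to separate instead of starting in degenerate territory (eps
# comparable to xi, or eps so small no saccade can be tagged local).
.init_chain <- function(dat, hyper, variant) {
  qs <- function(d, p) if (dat$n) max(quantile(d^2, p, names = FALSE), 0.25)
                       else NA_real_
  dxs <- dat$cur[, 1] - dat$prev[, 1]
  dys <- dat$cur[, 2] - dat$prev[, 2]
  mx <- qs(dxs, 0.5); my <- qs(dys, 0.5)
  qx <- 3 * qs(dxs, 0.9); qy <- 3 * qs(dys, 0.9)
  draw_window <- function(a, b, lo, hi) {
    if (is.na(lo)) return(rinvgamma(1, a, b))
    for (i in 1:200) {
      v <- rinvgamma(1, a, b)
      if (v > lo && v < hi) return(v)
    }
    exp(runif(1, log(lo), log(hi)))
  }
  # The marginal surface has metastable basins (e.g. eps far below the
  # short-saccade scale, with every saccade absorbed by the global mode).
  # Each chain therefore starts its scales at the best of several window
  # draws under the label-agnostic (gate = 1/2) marginal likelihood: a
  # cheap screen that keeps starts out of basins hundreds of nats below
  # the dominant mode while chains stay dispersed through the draws.
  draw_scales <- function() {
    eps <- c(draw_window(hyper@alphaEps[1], hyper@betaEps[1], mx / 4, mx),
             draw_window(hyper@alphaEps[2], hyper@betaEps[2], my / 4, my))
    xi <- c(draw_window(hyper@alphaXi[1], hyper@betaXi[1],
                        if (is.na(mx)) NA_real_ else max(mx, eps[1]), qx),
            draw_window(hyper@alphaXi[2], hyper@betaXi[2],
                        if (is.na(my)) NA_real_ else max(my, eps[2]), qy))
    list(eps = eps, xi = pmax(xi, 1.05 * eps))
  }
  pick_scales <- function() {
    if (!dat$n || variant == "local_saliency") return(draw_scales())
    lhalf <- rep(log(0.5), dat$n)
    best <- NULL; bestVal <- -Inf
    for (k in 1:10) {
      cand <- draw_scales()
      lp <- .scales_logpost_marginal(log(c(cand$eps, cand$xi)), dat,
                                     lhalf, lhalf, hyper, wantGrad = FALSE)
      if (is.finite(lp$value) && lp$value > bestVal) {
        best <- cand; bestVal <- lp$value
      }
    }
    best %||% draw_scales()
  }
  for (try in 1:50) {
    sc <- pick_scales()
    eps <- sc$eps
    xi <- sc$xi
    # link parameters from their priors, but re-drawn if the initial gate
    # values are already deep in the saturated logistic regime for most
    # saccades (such starts let the mode assignment decouple from the data
    # and can strand a chain in a spurious all-local mode)
    xlin <- if (variant == "local_choice") dat$sPrev else dat$ratio
    b <- sO <- 0
    for (i in 1:200) {
      b <- rnorm(1, hyper@muB, hyper@sigmaB)
      sO <- rnorm(1, hyper@muSo, hyper@sigmaSo)
      if (!dat$n || !variant %in% c("full", "local_choice")) break
      if (median(abs(b * (xlin - sO))) <= 10) break
    }
    st <- list(eps = eps, xi = xi, b = b, sO = sO,
               rho = rbeta(1, hyper@betaA, hyper@betaB))
    if (!dat$n || variant == "local_saliency") return(st)
    u <- log(c(st$eps, st$xi))
    lp <- .scales_logpost(u, dat, rep(0L, dat$n), hyper, variant,
                          wantGrad = FALSE)
    if (is.finite(lp$value)) return(st)
  }
  stop("could not find a non-degenerate initialization")
}

.gibbs_chain <- function(dat, variant, hyper, control, seed) {
  with_seed(seed, {
    st <- .init_chain(dat, hyper, variant)
    n <- dat$n
    hasLink <- variant %in% c("full", "local_choice")
    mixture <- hasLink || variant == "fixed_choice"
    xlin <- if (variant == "local_choice") dat$sPrev else dat$ratio
    cols <- switch(variant,
      full = , local_choice = c("eps_x", "eps_y", "xi_x", "xi_y", "b", "s_o"),
      fixed_choice = c("eps_x", "eps_y", "xi_x", "xi_y", "rho"),
      local_saliency = c("xi_x", "xi_y"))
    keep <- seq(control$burnIn + 1L, control$nIter, by = control$thin)
    out <- matrix(NA_real_, length(keep), length(cols) + 2L,
                  dimnames = list(NULL, c("iteration", cols, "log_posterior")))
    da <- .da_init(control$initStepSize, control$targetAccept)
    stepSize <- control$initStepSize
    nAcc <- 0L; nPost <- 0L
    row <- 0L
    gamma <- rep(1L, n)
    cache <- NULL  # per-saccade component values/gradients at current scales
    # diagonal-metric adaptation (Welford moments over mid-burn-in sweeps)
    d_u <- if (variant == "local_saliency") 2L else 4L
    hmcScale <- rep(1, d_u)
    wf <- list(n = 0, mean = rep(0, d_u), m2 = rep(0, d_u))
    adaptAt <- if (control$burnIn >= 100L) floor(0.6 * control$burnIn) else NA
    state_row <- function(lik) {
      prior <- .theta_log_prior(st$eps, st$xi, st$b, st$sO, st$rho, hyper,
                                variant)
      vals <- switch(variant,
        full = , local_choice = c(st$eps, st$xi, st$b, st$sO),
        fixed_choice = c(st$eps, st$xi, st$rho),
        local_saliency = st$xi)
      c(vals, lik + dat$logS12 + prior)
    }
    for (it in seq_len(control$nIter + 1L)) {
      # marginal likelihood pieces at the *current* state (used both for the
      # draw recorded for sweep it-1 and for the gamma update of sweep it)
      if (mixture && n) {
        f <- if (hasLink) st$b * (xlin - st$sO)
             else rep(stats::qlogis(st$rho), n)
        lr1 <- plogis(f, log.p = TRUE)        # log rho_t, saturation-safe
        lr0 <- plogis(-f, log.p = TRUE)       # log(1 - rho_t)
        if (is.null(cache)) {                 # first sweep: one full pass
          cache <- cpp_scales_marginal_grad(
            dat$sList, dat$img, dat$prev, dat$cur, lr1, lr0,
            st$eps[1], st$eps[2], st$xi[1], st$xi[2], TRUE)
          if (cache$degenerate)
            stop("global map degenerate at the initial state")
        }
        aa <- lr1 + cache$llo; bb <- lr0 + cache$glo
        mm <- pmax(aa, bb)
        lik <- sum(mm + log(exp(aa - mm) + exp(bb - mm)))
      } else if (variant == "local_saliency" && n) {
        lik <- cpp_localsal_loglik_grad(dat$sList, dat$img, dat$prev,
                                        dat$cur, st$xi[1], st$xi[2],
                                        FALSE)$value
      } else lik <- 0
      if (it > control$burnIn + 1L &&
          (it - control$burnIn - 2L) %% control$thin == 0L && row < nrow(out)) {
        row <- row + 1L
        out[row, ] <- c(it - 1L, state_row(lik))
      }
      if (it > control$nIter) break

      # Label warm-up: in the first burn-in sweeps the gate is held at 1/2 so
      # the mode tags follow the likelihood while the scales self-organize;
      # full conditional updates resume afterwards (warm-up is discarded).
      # The link block (gamma -> w -> b -> s_o) is iterated several times
      # per sweep: it needs no map evaluations (the component log-densities
      # are cached), and the extra sub-sweeps decorrelate b from the labels.
      warmup <- it <= min(50L, control$burnIn %/% 2L)
      nsub <- if (hasLink && n) control$linkSweeps else 1L
      for (sub in seq_len(nsub)) {
        if (mixture && n) {
          fcur <- if (hasLink) st$b * (xlin - st$sO)
                  else rep(stats::qlogis(st$rho), n)
          fg <- if (warmup) rep(0, n) else fcur
          gamma <- sampleGamma(plogis(fg), cache$llo, cache$glo,
                               logitRho = fg)
        }
        if (hasLink) {
          w <- rpolyagamma(n, if (n) fcur else numeric(0))
          st$b <- as.numeric(sampleB(xlin - st$sO, gamma - 0.5, w,
                                     hyper@muB, hyper@sigmaB))
          st$sO <- as.numeric(sampleSO(xlin, gamma - 0.5, w, st$b,
                                       hyper@muSo, hyper@sigmaSo))
        } else if (variant == "fixed_choice") {
          st$rho <- sampleRhoFixed(if (n) gamma else integer(0),
                                   hyper@betaA, hyper@betaB)
          # keep the gate logit finite (a Beta draw can round to 0 or 1)
          st$rho <- min(max(st$rho, 1e-12), 1 - 1e-12)
        }
      }
      u0 <- if (variant == "local_saliency") log(st$xi)
            else log(c(st$eps, st$xi))
      if (mixture && n) {
        # collapsed scale update: condition on the *updated* link parameters
        f2 <- if (hasLink) st$b * (xlin - st$sO)
              else rep(stats::qlogis(st$rho), n)
        l1 <- plogis(f2, log.p = TRUE)
        l0 <- plogis(-f2, log.p = TRUE)
        lpfun <- function(u) .scales_logpost_marginal(u, dat, l1, l0, hyper)
        lp0 <- .marginal_from_cache(cache, l1, l0, u0, hyper)
      } else {
        lpfun <- function(u) .scales_logpost(u, dat, gamma, hyper, variant)
        lp0 <- lpfun(u0)
      }
      if (it == 1L) {  # order-of-magnitude step search seeds the adaptation
        stepSize <- .find_step(u0, lp0, lpfun, control$initStepSize)
        da <- .da_init(stepSize, control$targetAccept)
      }
      if (!is.na(adaptAt) && it == adaptAt && wf$n >= 20) {
        # switch to the estimated per-coordinate metric; restart the step
        # size at the new scaling
        hmcScale <- pmax(sqrt(wf$m2 / (wf$n - 1)), 1e-4)
        stepSize <- .find_step(u0, lp0, lpfun, 1, scale = hmcScale)
        da <- .da_init(stepSize, control$targetAccept)
      }
      res <- .hmc_transition(u0, lp0, lpfun, stepSize, control$leapfrog,
                             scale = hmcScale)
      if (variant == "local_saliency") st$xi <- exp(res$u)
      else { st$eps <- exp(res$u[1:2]); st$xi <- exp(res$u[3:4]) }
      if (mixture && n && res$accepted) cache <- res$lp
      if (it <= control$burnIn) {
        if (it > min(50L, control$burnIn %/% 4L) &&
            (is.na(adaptAt) || it < adaptAt)) {
          wf$n <- wf$n + 1
          dlt <- res$u - wf$mean
          wf$mean <- wf$mean + dlt / wf$n
          wf$m2 <- wf$m2 + dlt * (res$u - wf$mean)
        }
        da <- .da_update(da, res$alpha)
        stepSize <- exp(da$logEps)
      } else {
        if (it == control$burnIn + 1L && control$burnIn > 0)
          stepSize <- exp(da$logEpsBar)
        nPost <- nPost + 1L
        nAcc <- nAcc + res$accepted
      }
    }
    list(draws = out, acceptRate = if (nPost) nAcc / nPost else NA_real_)
  })
}

#' Run the Gibbs sampler
#'
#' Fits one model (for one subject's data) by cycling
#' \eqn{\gamma \to w \to b \to s_o \to (\epsilon, \xi)} for `nIter` sweeps in
#' each of `nChains` chains started from dispersed initializations (local
#' scales initialized below the data's median squared step, global scales
#' above it, link parameters from their priors). With an empty dataset the
#' sweep reduces to prior sampling, which is a useful correctness check.
#' Variant reductions: the fixed-choice variant replaces the link updates by
#' a conjugate Beta draw; the local-saliency variant updates only
#' \eqn{\xi}; the saliency baseline has nothing to infer.
#'
#' @param fixations fixation table (may be `NULL`/empty for prior sampling).
#' @param maps named list of [SaliencyMap-class] keyed by `image_id` (or a
#'   single map).
#' @param variant model variant to fit.
#' @param hyper a [Hyperparams-class]; default [defaultHyperparams()] scaled
#'   by the maps' `pxPerDegree` and the observed saliency ratios.
#' @param control sampler settings from [gibbsControl()].
#' @param seed integer master seed (chains get reproducible sub-seeds).
#' @return a [PosteriorSamples-class]. Non-convergence (split R-hat above the
#'   control threshold) is flagged in `diagnostics(x)$converged` with a
#'   warning, not an error.
#' @export
runGibbs <- function(fixations, maps, variant = c("full", "local_choice",
                     "fixed_choice", "local_saliency"), hyper = NULL,
                     control = gibbsControl(), seed = NULL) {
  variant <- match.arg(variant)
  dat <- .prepare_gibbs_data(fixations, maps, variant)
  if (is.null(hyper)) {
    if (is(maps, "SaliencyMap")) maps <- list(maps)
    ppd <- vapply(maps, pxPerDegree, numeric(1))
    ppd <- if (length(ppd) && any(!is.na(ppd))) ppd[!is.na(ppd)][1]
           else dat$W / 32
    hyper <- defaultHyperparams(pxPerDegree = ppd, ratios = dat$ratio)
  }
  stopifnot(is(hyper, "Hyperparams"))
  seeds <- spawn_seeds(seed, control$nChains)
  chains <- lapply(seq_len(control$nChains), function(k) {
    if (control$verbose) message("chain ", k, "/", control$nChains)
    .gibbs_chain(dat, variant, hyper, control, seeds[[k]])
  })
  draws <- lapply(chains, `[[`, "draws")
  pars <- setdiff(colnames(draws[[1]]), c("iteration", "log_posterior"))
  rhat <- vapply(pars, function(p)
    .split_rhat(lapply(draws, function(d) d[, p])), numeric(1))
  ess <- vapply(pars, function(p)
    .ess_chains(lapply(draws, function(d) d[, p])), numeric(1))
  converged <- all(is.finite(rhat)) && all(rhat < control$rhatThreshold)
  if (!converged)
    warning("chains did not converge (max split R-hat = ",
            sprintf("%.3f", max(rhat)), ")")
  new("PosteriorSamples", draws = draws, variant = variant,
      acceptRate = vapply(chains, `[[`, numeric(1), "acceptRate"),
      diagnostics = list(rhat = rhat, ess = ess, converged = converged),
      control = control,
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

# ---- diagnostics ------------------------------------------------------------

# split R-hat: each chain halved, between/within variance ratio
.split_rhat <- function(chains) {
  n2 <- floor(min(lengths(chains)) / 2)
  if (n2 < 2L) return(NA_real_)
  halves <- list()
  for (x in chains) {
    x <- x[seq_len(2L * n2)]
    halves <- c(halves, list(x[1:n2], x[(n2 + 1):(2 * n2)]))
  }
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n2 * var(means)
  if (W <= 0) return(if (B <= 1e-12) 1 else Inf)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

# effective sample size, Geyer initial-monotone sequence on pooled
# chain-averaged autocorrelations
.ess_chains <- function(chains) {
  n <- min(lengths(chains))
  m <- length(chains)
  if (n < 4L) return(NA_real_)
  acovs <- vapply(chains, function(x)
    drop(acf(x[seq_len(n)], lag.max = n - 2L, type = "covariance",
             plot = FALSE, demean = TRUE)$acf), numeric(n - 1L))
  acovs <- matrix(acovs, ncol = m)
  chain_vars <- vapply(chains, function(x) var(x[seq_len(n)]), numeric(1))
  means <- vapply(chains, function(x) mean(x[seq_len(n)]), numeric(1))
  W <- mean(chain_vars)
  varPlus <- (n - 1) / n * W + (if (m > 1) var(means) else 0)
  if (varPlus <= 0) return(m * n)
  rho <- 1 - (W - rowMeans(acovs)) / varPlus  # lag 0 .. n-2
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 0
  prevPair <- Inf
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair < 0) break
    pair <- min(pair, prevPair)
    tau <- tau + pair
    prevPair <- pair
    k <- k + 2L
  }
  ess <- m * n / (1 + 2 * tau - 2 * rho[1])
  # rho[1] is lag-0 (=~1): the pair sums above start at lag 0
  max(min(ess, m * n), 1)
}

# ---- PosteriorSamples methods ----------------------------------------------

#' @rdname lgattention-generics
#' @export
setMethod("draws", "PosteriorSamples", function(x) x@draws)

#' @rdname lgattention-generics
#' @export
setMethod("variantName", "PosteriorSamples", function(x) x@variant)

#' Combined draw matrix
#'
#' @param x a [PosteriorSamples-class].
#' @param ... unused.
#' @return all chains row-bound into one matrix.
#' @export
setMethod("as.matrix", "PosteriorSamples", function(x, ...)
  do.call(rbind, x@draws))

#' Convergence diagnostics of a posterior sample
#'
#' @param x a [PosteriorSamples-class].
#' @return `gelmanRhat`: named vector of split R-hat values;
#'   `effectiveSize`: named vector of effective sample sizes;
#'   `isConverged`: logical.
#' @export
gelmanRhat <- function(x) x@diagnostics$rhat

#' @rdname gelmanRhat
#' @export
effectiveSize <- function(x) x@diagnostics$ess

#' @rdname gelmanRhat
#' @export
isConverged <- function(x) isTRUE(x@diagnostics$converged)

#' Posterior summary table
#'
#' @param x a [PosteriorSamples-class].
#' @param prob central credible-interval mass (default 0.9).
#' @return data.frame with one row per parameter: posterior mean, sd, kernel
#'   density mode, central interval bounds, split R-hat and ESS.
#' @export
posteriorSummary <- function(x, prob = 0.9) {
  d <- as.matrix(x)
  pars <- setdiff(colnames(d), c("iteration", "log_posterior"))
  a <- (1 - prob) / 2
  rows <- lapply(pars, function(p) {
    v <- d[, p]
    dens <- density(v)
    data.frame(parameter = p, mean = mean(v), sd = sd(v),
               mode = dens$x[which.max(dens$y)],
               lower = quantile(v, a, names = FALSE),
               upper = quantile(v, 1 - a, names = FALSE),
               rhat = x@diagnostics$rhat[[p]],
               ess = x@diagnostics$ess[[p]])
  })
  do.call(rbind, rows)
}

#' Posterior-mean parameter set
#'
#' Collapses a posterior sample to a [ModelParams-class] at the posterior
#' mean (used e.g. for predictive scoring).
#'
#' @param x a [PosteriorSamples-class].
#' @return a [ModelParams-class].
#' @export
posteriorMeanParams <- function(x) {
  m <- colMeans(as.matrix(x))
  v <- x@variant
  switch(v,
    full = , local_choice = modelParams(
      epsX = m[["eps_x"]], epsY = m[["eps_y"]],
      xiX = m[["xi_x"]], xiY = m[["xi_y"]],
      b = m[["b"]], sO = m[["s_o"]], variant = v),
    fixed_choice = modelParams(
      epsX = m[["eps_x"]], epsY = m[["eps_y"]],
      xiX = m[["xi_x"]], xiY = m[["xi_y"]],
      variant = v, rhoFixed = m[["rho"]]),
    local_saliency = modelParams(
      epsX = m[["xi_x"]] / 100, epsY = m[["xi_y"]] / 100,
      xiX = m[["xi_x"]], xiY = m[["xi_y"]], variant = v))
}

#' Draw parameter sets from a posterior sample
#'
#' @param x a [PosteriorSamples-class].
#' @param n number of parameter sets.
#' @param seed integer seed.
#' @return list of [ModelParams-class], each built from one stored draw.
#' @export
posteriorDrawParams <- function(x, n, seed = NULL) {
  d <- as.matrix(x)
  ix <- with_seed(seed, sample.int(nrow(d), n, replace = n > nrow(d)))
  v <- x@variant
  lapply(ix, function(i) {
    m <- d[i, ]
    switch(v,
      full = , local_choice = modelParams(
        epsX = m[["eps_x"]], epsY = m[["eps_y"]],
        xiX = m[["xi_x"]], xiY = m[["xi_y"]],
        b = m[["b"]], sO = m[["s_o"]], variant = v),
      fixed_choice = modelParams(
        epsX = m[["eps_x"]], epsY = m[["eps_y"]],
        xiX = m[["xi_x"]], xiY = m[["xi_y"]],
        variant = v, rhoFixed = m[["rho"]]),
      local_saliency = modelParams(
        epsX = m[["xi_x"]] / 100, epsY = m[["xi_y"]] / 100,
        xiX = m[["xi_x"]], xiY = m[["xi_y"]], variant = v))
  })
}

setMethod("show", "PosteriorSamples", function(object) {
  nd <- sum(vapply(object@draws, nrow, integer(1)))
  cat(sprintf("PosteriorSamples: variant '%s', %d chains, %d draws\n",
              object@variant, length(object@draws), nd))
  cat(sprintf("  mean HMC acceptance %.2f; converged: %s (max R-hat %.3f)\n",
              mean(object@acceptRate), object@diagnostics$converged,
              suppressWarnings(max(object@diagnostics$rhat))))
})
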