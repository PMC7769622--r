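# Full conditional distributions of the Gibbs sampler.
#
# The augmented model attaches to every modeled saccade t a Bernoulli mode
# indicator gamma_t (1 = local, 0 = global) with success probability
# rho_t = sigma(f_t), and a Polya-Gamma variable w_t ~ PG(1, f_t) that makes
# the logistic factor Gaussian in the link parameters:
#   sigma(f)^g (1-sigma(f))^(1-g) propto exp((g - 1/2) f - w f^2 / 2).
# With f_t = b (x_t - s_o) (x_t the saliency ratio, or the saliency value for
# the local-choice variant), f is linear in b given s_o and linear in s_o
# given b, so both full conditionals are Gaussian by completion of squares.

#' Sample the latent mode indicators
#'
#' Draws each saccade's mode indicator from its Bernoulli full conditional
#' \deqn{P(\gamma_t = 1 | \cdot) = \frac{\rho_t p_{local}(z_t)}
#'   {\rho_t p_{local}(z_t) + (1 - \rho_t) p_{global}(z_t)}.}
#'
#' @param rho gating probabilities \eqn{\rho_t} (vector).
#' @param logLocal,logGlobal log step probabilities of the observed fixation
#'   under the local and global maps (vectors; `-Inf` encodes a zero).
#' @param logitRho optional logit of `rho` (the link value \eqn{f_t}); when
#'   supplied, the conditional logit \eqn{f_t + \log p_{local} - \log
#'   p_{global}} is formed directly in log space, which stays exact where
#'   `rho` itself would round to 0 or 1 in double precision.
#' @return integer vector of 0/1 draws, with the success probabilities in
#'   the `prob` attribute.
#' @export
sampleGamma <- function(rho, logLocal, logGlobal, logitRho = NULL) {
  if (is.null(logitRho)) {
    a <- log(rho) + logLocal
    b <- log1p(-rho) + logGlobal
    if (any(a == -Inf & b == -Inf))
      stop("both mixture components have probability zero at an observed ",
           "fixation: data/parameter inconsistency")
    p <- plogis(a - b)  # 1 / (1 + exp(b - a))
  } else {
    p <- plogis(logitRho + logLocal - logGlobal)
    p[logGlobal == -Inf] <- 1  # clamped global zero: local with certainty
  }
  structure(as.integer(runif(length(p)) < p), prob = p)
}

#' Gaussian full conditionals of the link parameters
#'
#' `sampleB` draws the logistic slope b from its Gaussian full conditional
#' given the design values `x` (\eqn{x_t = s_{t-1}/s_{t-2} - s_o}, so that
#' \eqn{f_t = b x_t}), the centered indicators `kappa`
#' (\eqn{\gamma_t - 1/2}) and the Polya-Gamma draws `w`:
#' precision \eqn{1/\sigma_b^2 + \sum_t w_t x_t^2}, mean
#' \eqn{(\mu_b/\sigma_b^2 + \sum_t \kappa_t x_t) / precision}.
#' `sampleSO` is the mirror image for the offset, with
#' \eqn{f_t = b r_t - b s_o} linear in \eqn{s_o} with coefficient \eqn{-b}:
#' precision \eqn{1/\sigma_{s_o}^2 + b^2 \sum_t w_t}, mean
#' \eqn{(\mu_{s_o}/\sigma_{s_o}^2 + \sum_t (w_t b^2 r_t - b \kappa_t)) /
#' precision}. With no saccades both reduce to the prior.
#'
#' @param x design values per saccade (for `sampleB`).
#' @param r raw covariate values per saccade (saliency ratio, or saliency
#'   value for the local-choice variant; for `sampleSO`).
#' @param kappa centered indicators \eqn{\gamma_t - 1/2}.
#' @param w Polya-Gamma auxiliary draws.
#' @param b current slope (for `sampleSO`).
#' @param muB,sigmaB,muSo,sigmaSo Gaussian prior mean/sd.
#' @return one draw, with the conditional `mean` and `sd` as attributes.
#' @export
sampleB <- function(x, kappa, w, muB, sigmaB) {
  prec <- 1 / sigmaB^2 + sum(w * x^2)
  m <- (muB / sigmaB^2 + sum(kappa * x)) / prec
  structure(rnorm(1, m, 1 / sqrt(prec)), mean = m, sd = 1 / sqrt(prec))
}

#' @rdname sampleB
#' @export
sampleSO <- function(r, kappa, w, b, muSo, sigmaSo) {
  prec <- 1 / sigmaSo^2 + b^2 * sum(w)
  m <- (muSo / sigmaSo^2 + sum(w * b^2 * r - b * kappa)) / prec
  structure(rnorm(1, m, 1 / sqrt(prec)), mean = m, sd = 1 / sqrt(prec))
}

#' Beta full conditional of the fixed-choice mixing probability
#'
#' @param gamma 0/1 mode indicators.
#' @param betaA,betaB Beta prior parameters.
#' @return one draw from Beta(betaA + #\{gamma=1\}, betaB + #\{gamma=0\}).
#' @export
sampleRhoFixed <- function(gamma, betaA, betaB) {
  rbeta(1, betaA + sum(gamma == 1L), betaB + sum(gamma == 0L))
}

# ---- HMC for the length scales ---------------------------------------------
#
# The conditional of (eps, xi) given the mode tags has no closed form because
# of the clamped global map, so one Hamiltonian Monte Carlo transition targets
#   sum_{gamma=1} log p_local(z_t) + sum_{gamma=0} log p_global(z_t)
#   + IG log-priors,
# in unconstrained coordinates u = log(eps_x, eps_y, xi_x, xi_y) with the
# change-of-variables Jacobian. Proposals violating xi > eps componentwise or
# producing an all-zero global map get log-density -Inf and are rejected,
# which preserves detailed balance on the constrained support.

# log conditional density and gradient in u = log scales
.scales_logpost <- function(u, dat, gamma, hyper, variant, wantGrad = TRUE) {
  if (variant == "local_saliency") {
    xi <- exp(u)
    lik <- cpp_localsal_loglik_grad(dat$sList, dat$img, dat$prev, dat$cur,
                                    xi[1], xi[2], wantGrad)
    if (lik$degenerate || !is.finite(lik$value))
      return(list(value = -Inf, grad = rep(NA_real_, 2)))
    pv <- sum(dinvgamma_log(xi, hyper@alphaXi, hyper@betaXi)) + sum(u)
    pg <- hyper@betaXi / xi - hyper@alphaXi
    return(list(value = lik$value + pv,
                grad = if (wantGrad) lik$grad + pg else NULL))
  }
  if (u[3] <= u[1] || u[4] <= u[2])  # support constraint xi > eps
    return(list(value = -Inf, grad = rep(NA_real_, 4)))
  eps <- exp(u[1:2]); xi <- exp(u[3:4])
  lik <- cpp_scales_loglik_grad(dat$sList, dat$img, dat$prev, dat$cur,
                                as.integer(gamma), dat$H, dat$W,
                                eps[1], eps[2], xi[1], xi[2], wantGrad)
  if (lik$degenerate || !is.finite(lik$value))
    return(list(value = -Inf, grad = rep(NA_real_, 4)))
  pv <- sum(dinvgamma_log(eps, hyper@alphaEps, hyper@betaEps)) +
        sum(dinvgamma_log(xi, hyper@alphaXi, hyper@betaXi)) + sum(u)
  pg <- c(hyper@betaEps / eps - hyper@alphaEps,
          hyper@betaXi / xi - hyper@alphaXi)
  list(value = lik$value + pv, grad = if (wantGrad) lik$grad + pg else NULL)
}

# Marginal (label-collapsed) variant of the scale conditional: targets
# p(eps, xi | b, s_o, Z) with the mode indicators summed out. Used inside the
# Gibbs sweep (a partially collapsed update): hard labels are only needed for
# the Polya-Gamma link updates, and collapsing them out of the scale move
# removes the sticky label-trap modes of the hard-conditioned update.
.scales_prior <- function(u, hyper) {
  eps <- exp(u[1:2]); xi <- exp(u[3:4])
  list(value = sum(dinvgamma_log(eps, hyper@alphaEps, hyper@betaEps)) +
         sum(dinvgamma_log(xi, hyper@alphaXi, hyper@betaXi)) + sum(u),
       grad = c(hyper@betaEps / eps - hyper@alphaEps,
                hyper@betaXi / xi - hyper@alphaXi))
}

.scales_logpost_marginal <- function(u, dat, lr1, lr0, hyper,
                                     wantGrad = TRUE) {
  if (u[3] <= u[1] || u[4] <= u[2])
    return(list(value = -Inf, grad = rep(NA_real_, 4)))
  eps <- exp(u[1:2]); xi <- exp(u[3:4])
  lik <- cpp_scales_marginal_grad(dat$sList, dat$img, dat$prev, dat$cur,
                                  lr1, lr0, eps[1], eps[2], xi[1], xi[2],
                                  wantGrad)
  if (lik$degenerate || !is.finite(lik$value))
    return(list(value = -Inf, grad = rep(NA_real_, 4)))
  pr <- .scales_prior(u, hyper)
  list(value = lik$value + pr$value,
       grad = if (wantGrad) lik$grad + pr$grad else NULL,
       llo = lik$llo, glo = lik$glo, dllo = lik$dllo, dglo = lik$dglo)
}

# recombine a cached per-saccade component evaluation (valid at the current
# scales) with new gate values: the component values and gradients do not
# depend on the gate, so no grid pass is needed
.marginal_from_cache <- function(cache, lr1, lr0, u, hyper) {
  aa <- lr1 + cache$llo
  bb <- lr0 + cache$glo
  m <- pmax(aa, bb)
  lmix <- m + log(exp(aa - m) + exp(bb - m))
  q <- exp(aa - lmix)
  q1 <- 1 - q   # clamped saccades have zeroed dglo rows, so q1 * 0 is safe
  g <- c(colSums(q * cache$dllo), 0, 0) + colSums(q1 * cache$dglo)
  pr <- .scales_prior(u, hyper)
  list(value = sum(lmix) + pr$value, grad = g + pr$grad,
       llo = cache$llo, glo = cache$glo, dllo = cache$dllo,
       dglo = cache$dglo)
}

# One leapfrog HMC transition. `scale` is the per-coordinate metric (an
# estimate of the target's marginal sd, adapted during burn-in): the
# trajectory runs in coordinates u / scale with unit mass, which equalizes
# the very different stiffness of the local and global log-scales.
.hmc_transition <- function(u0, lp0, lpfun, stepSize, L,
                            scale = rep(1, length(u0))) {
  d <- length(u0)
  # jitter the trajectory length: fixed (step, L) on a near-Gaussian target
  # resonates (trajectories return to their start), freezing the chain
  if (L > 1L) {
    lo <- max(1L, (L + 1L) %/% 2L)
    L <- lo + sample.int(L - lo + 1L, 1L) - 1L
  }
  stepSize <- stepSize * runif(1, 0.9, 1.1)
  p <- rnorm(d)
  H0 <- -lp0$value + 0.5 * sum(p^2)
  u <- u0
  lp <- lp0
  ok <- TRUE
  p <- p + 0.5 * stepSize * scale * lp$grad
  for (l in seq_len(L)) {
    u <- u + stepSize * scale * p
    if (any(!is.finite(u))) { ok <- FALSE; break }
    lp <- lpfun(u)
    if (!is.finite(lp$value)) { ok <- FALSE; break }
    if (any(!is.finite(lp$grad))) {
      warning("non-finite gradient in HMC step; transition rejected")
      ok <- FALSE; break
    }
    if (l < L) p <- p + stepSize * scale * lp$grad
  }
  alpha <- 0
  if (ok) {
    p <- p + 0.5 * stepSize * scale * lp$grad
    H1 <- -lp$value + 0.5 * sum(p^2)
    alpha <- min(1, exp(H0 - H1))
  }
  if (is.finite(alpha) && alpha > 0 && runif(1) < alpha)
    list(u = u, lp = lp, accepted = TRUE, alpha = alpha)
  else
    list(u = u0, lp = lp0, accepted = FALSE, alpha = alpha)
}

# find an order-of-magnitude step size before adaptation starts: double or
# halve until a single leapfrog step crosses 50% acceptance
.find_step <- function(u0, lp0, lpfun, eps0 = 0.1,
                       scale = rep(1, length(u0))) {
  alpha_of <- function(s) {
    p <- rnorm(length(u0))
    H0 <- -lp0$value + 0.5 * sum(p^2)
    p1 <- p + 0.5 * s * scale * lp0$grad
    u1 <- u0 + s * scale * p1
    if (any(!is.finite(u1))) return(0)
    lp1 <- lpfun(u1)
    if (!is.finite(lp1$value) || any(!is.finite(lp1$grad))) return(0)
    p1 <- p1 + 0.5 * s * scale * lp1$grad
    H1 <- -lp1$value + 0.5 * sum(p1^2)
    min(1, exp(H0 - H1))
  }
  s <- eps0
  dir <- if (alpha_of(s) > 0.5) 1 else -1
  for (i in 1:40) {
    s2 <- s * 2^dir
    al <- alpha_of(s2)
    if ((dir == 1 && al <= 0.5) || (dir == -1 && al > 0.5)) {
      if (dir == -1) s <- s2
      break
    }
    s <- s2
  }
  min(max(s, 1e-8), exp(1))
}

# dual-averaging step-size adaptation (used during burn-in)
.da_init <- function(eps0, target = 0.65) {
  list(mu = log(10 * eps0), logEps = log(eps0), logEpsBar = log(eps0),
       hBar = 0, t = 0, gamma = 0.05, t0 = 10, kappa = 0.75, target = target)
}

.da_update <- function(da, alpha) {
  da$t <- da$t + 1
  frac <- 1 / (da$t + da$t0)
  da$hBar <- (1 - frac) * da$hBar + frac * (da$target - alpha)
  # cap the log step size: steps beyond ~e in log-scale coordinates are
  # never useful and an early streak of alpha = 1 would otherwise let the
  # shadow iterate run away
  da$logEps <- min(da$mu - sqrt(da$t) / da$gamma * da$hBar, 1)
  wgt <- da$t^(-da$kappa)
  da$logEpsBar <- wgt * da$logEps + (1 - wgt) * da$logEpsBar
  da
}

#' One HMC transition for the Gaussian length scales
#'
#' Performs a single Hamiltonian Monte Carlo transition targeting the full
#' conditional of \eqn{(\epsilon_x, \epsilon_y, \xi_x, \xi_y)} given the mode
#' tags (or of \eqn{(\xi_x, \xi_y)} for the local-saliency variant), in
#' log-scale coordinates with the Inverse-Gamma priors and the
#' \eqn{\xi > \epsilon} support constraint.
#'
#' @param prev,cur n x 2 matrices of (x, y) saccade start and landing
#'   coordinates (the modeled saccades, t >= 3).
#' @param gamma 0/1 mode tags per saccade (1 = local); ignored by the
#'   local-saliency variant.
#' @param maps list of [SaliencyMap-class] (shared grid geometry).
#' @param imageIndex 1-based index into `maps` per saccade.
#' @param eps,xi current variances, length-2 (x, y) each.
#' @param hyper a [Hyperparams-class].
#' @param stepSize leapfrog step size in log-scale coordinates.
#' @param leapfrog number of leapfrog steps.
#' @param variant model variant.
#' @return list with `eps`, `xi` (new values), `accepted`, `alpha` (the
#'   acceptance probability) and `logDensity` (conditional log density at the
#'   returned state, including priors and Jacobian).
#' @export
hmcUpdateScales <- function(prev, cur, gamma, maps, imageIndex, eps, xi,
                            hyper, stepSize = 0.05, leapfrog = 10,
                            variant = "full") {
  prev <- as.matrix(prev); cur <- as.matrix(cur)
  sList <- lapply(maps, mapValues)
  dat <- list(sList = sList, img = as.integer(imageIndex) - 1L,
              prev = prev, cur = cur,
              H = nrow(sList[[1]]), W = ncol(sList[[1]]))
  u0 <- if (variant == "local_saliency") log(xi) else log(c(eps, xi))
  lpfun <- function(u) .scales_logpost(u, dat, gamma, hyper, variant)
  lp0 <- lpfun(u0)
  if (!is.finite(lp0$value))
    stop("current length scales have zero conditional density")
  res <- .hmc_transition(u0, lp0, lpfun, stepSize, leapfrog)
  if (variant == "local_saliency")
    list(eps = eps, xi = exp(res$u), accepted = res$accepted,
         alpha = res$alpha, logDensity = res$lp$value)
  else
    list(eps = exp(res$u[1:2]), xi = exp(res$u[3:4]), accepted = res$accepted,
         alpha = res$alpha, logDensity = res$lp$value)
}
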