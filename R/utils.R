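# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards so seeded helpers do not perturb the session stream.
# seed = NULL runs on the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive k reproducible sub-seeds (< 2^31) from a master seed.
spawn_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, k)))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# floor for probabilities before taking logs (keeps HMC/optimization finite
# while genuine zeros are still flagged upstream)
.PROB_FLOOR <- 1e-300

# saliency-value floor used in the ratio s_{t-1}/s_{t-2} (the map has unit
# total mass, so this is 1e-12 of the map mass)
.RATIO_FLOOR <- 1e-12

# Inverse-Gamma(shape a, scale b) log-density
dinvgamma_log <- function(x, a, b) {
  a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
}

rinvgamma <- function(n, a, b) 1 / rgamma(n, shape = a, rate = b)

qinvgamma <- function(p, a, b) 1 / qgamma(1 - p, shape = a, rate = b)

pinvgamma <- function(q, a, b) 1 - pgamma(1 / q, shape = a, rate = b)

`%||%` <- function(a, b) if (is.null(a)) b else a
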