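# Independent brute-force oracles used across the test files. These evaluate
# the model's defining expressions directly, pixel by pixel, with plain R
# arithmetic, so they share no code path with the package internals.

# discrete Gaussian step map: n(z; zprev, eps) over pixel centers, normalized
oracle_local_map <- function(H, W, zprev, ex, ey) {
  m <- matrix(0, H, W)
  for (x in 0:(W - 1)) for (y in 0:(H - 1))
    m[y + 1, x + 1] <- dnorm(x, zprev[1], sqrt(ex)) *
                       dnorm(y, zprev[2], sqrt(ey))
  m / sum(m)
}

# global map: max(s * n_xi - n_eps, 0), normalized
oracle_global_map <- function(s, zprev, ex, ey, xx, xy) {
  H <- nrow(s); W <- ncol(s)
  m <- matrix(0, H, W)
  for (x in 0:(W - 1)) for (y in 0:(H - 1)) {
    v <- s[y + 1, x + 1] *
           dnorm(x, zprev[1], sqrt(xx)) * dnorm(y, zprev[2], sqrt(xy)) -
         dnorm(x, zprev[1], sqrt(ex)) * dnorm(y, zprev[2], sqrt(ey))
    m[y + 1, x + 1] <- max(v, 0)
  }
  m / sum(m)
}

# one-mode local-saliency map: s * n_xi, normalized
oracle_local_saliency_map <- function(s, zprev, xx, xy) {
  H <- nrow(s); W <- ncol(s)
  m <- matrix(0, H, W)
  for (x in 0:(W - 1)) for (y in 0:(H - 1))
    m[y + 1, x + 1] <- s[y + 1, x + 1] *
      dnorm(x, zprev[1], sqrt(xx)) * dnorm(y, zprev[2], sqrt(xy))
  m / sum(m)
}

# kernel-density estimate by direct summation over fixations
oracle_kde_map <- function(H, W, fx, fy, bw) {
  m <- matrix(0, H, W)
  for (i in seq_along(fx))
    for (x in 0:(W - 1)) for (y in 0:(H - 1))
      m[y + 1, x + 1] <- m[y + 1, x + 1] +
        dnorm(x, fx[i], bw) * dnorm(y, fy[i], bw)
  m / sum(m)
}

# AUC by exhaustive pair counting (ties count one half)
oracle_auc_paircount <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# interior local maxima of a matrix (8-neighbourhood, strict)
oracle_local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- 0L
  for (i in 2:(H - 1)) for (j in 2:(W - 1)) {
    nb <- m[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (m[i, j] == max(nb) && sum(nb == m[i, j]) == 1L) out <- out + 1L
  }
  out
}

map_at <- function(m, z) m[floor(z[2]) + 1L, floor(z[1]) + 1L]

# Inverse-Gamma CDF through the reciprocal Gamma (for KS comparisons)
pinvgamma_test <- function(q, a, b) {
  1 - pgamma(1 / q, shape = a, rate = b)
}

# small random test fixtures
rand_saliency <- function(H, W, seed) {
  set.seed(seed)
  SaliencyMap(matrix(rexp(H * W), H, W))
}
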