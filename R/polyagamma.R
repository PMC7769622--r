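#' Draw from the Polya-Gamma distribution PG(1, c)
#'
#' Exact draws via the Devroye-type alternating-series rejection sampler.
#' PG(1, c) is the augmentation law that makes a Bernoulli-logistic
#' likelihood conditionally Gaussian in its linear parameters; it is
#' symmetric in the tilt, PG(1, c) = PG(1, -c), and has mean
#' \eqn{\tanh(c/2)/(2c)} (1/4 at c = 0).
#'
#' @param n number of draws.
#' @param c tilt parameter(s); recycled to length `n`.
#' @return numeric vector of `n` positive draws.
#' @examples
#' mean(rpolyagamma(1e4, 2))    # ~ tanh(1) / 4
#' @export
rpolyagamma <- function(n, c = 0) {
  c <- rep_len(as.numeric(c), n)
  if (anyNA(c) || any(!is.finite(c))) stop("'c' must be finite")
  cpp_rpg(c)
}
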