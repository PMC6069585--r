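#' Construct a linear congruential generator
#'
#' Creates an [LCG-class] generator with recurrence
#' \eqn{x_n = (\alpha x_{n-1} + c) \bmod M}, emitting uniforms
#' \eqn{\lambda_n = x_n / M}.  The default constants
#' \code{alpha = 1664525}, \code{inc = 1013904223}, \code{modulus = 2^32}
#' (the Numerical Recipes choice) satisfy the Hull-Dobell conditions and so
#' have full period \eqn{M}.
#'
#' @param seed nonnegative integer initial state \eqn{x_0} (reduced mod M).
#' @param alpha nonnegative integer multiplier.
#' @param inc nonnegative integer increment.
#' @param modulus positive integer modulus.
#' @return an \code{LCG} object.
#' @examples
#' gen <- LCG(seed = 0)
#' lcgNext(gen)        # 1013904223 / 2^32
#' @export
LCG <- function(seed = 42, alpha = 1664525, inc = 1013904223, modulus = 2^32) {
  if (length(modulus) != 1L || !is.finite(modulus) || modulus < 1)
    stop("invalid LCG constants: modulus M must be a positive integer")
  if (length(seed) != 1L || !is.finite(seed) || seed < 0 || seed != floor(seed))
    stop("seed x_0 must be a nonnegative integer")
  st <- new.env(parent = emptyenv())
  st$x <- seed %% modulus
  new("LCG", state = st, alpha = alpha, inc = inc, modulus = modulus)
}

#' Advance the generator and emit uniforms in [0, 1)
#'
#' Applies the recurrence \code{n} times and returns the emitted values
#' \eqn{\lambda = x/M}.  The generator is advanced in place.
#'
#' @param gen an [LCG-class] generator.
#' @param n number of values to draw.
#' @return numeric vector of length \code{n}, all values in [0, 1).
#' @export
lcgNext <- function(gen, n = 1L) {
  stopifnot(is(gen, "LCG"), n >= 0)
  a <- gen@alpha; cc <- gen@inc; M <- gen@modulus
  x <- gen@state$x
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (a * x + cc) %% M
    out[i] <- x / M
  }
  gen@state$x <- x
  out
}

#' Uniform draws on an arbitrary interval
#'
#' Affine map of the generator output: \code{lo + lambda * (hi - lo)},
#' giving values in \code{[lo, hi)} (degenerate \code{lo == hi} returns
#' \code{lo}).
#'
#' @inheritParams lcgNext
#' @param lo,hi interval bounds, \code{lo <= hi}.
#' @return numeric vector of length \code{n}.
#' @export
lcgUniform <- function(gen, n = 1L, lo = 0, hi = 1) {
  if (lo > hi) stop("range error: lo > hi")
  lo + lcgNext(gen, n) * (hi - lo)
}

#' Pseudo-Gaussian draws from the generator
#'
#' Sums of 12 uniforms minus 6 (Irwin-Hall approximation), so all fixture
#' noise stays on the package's own generator and remains reproducible from
#' one seed.
#'
#' @inheritParams lcgNext
#' @param mean,sd location and scale of the approximate normal.
#' @return numeric vector of length \code{n}.
#' @export
lcgNormal <- function(gen, n = 1L, mean = 0, sd = 1) {
  if (n == 0L) return(numeric(0))
  u <- matrix(lcgNext(gen, 12L * n), nrow = 12L)
  mean + sd * (colSums(u) - 6)
}

#' Uniform integer draws on 1..k
#'
#' Used for sampling source images with replacement.
#'
#' @inheritParams lcgNext
#' @param k upper bound (inclusive).
#' @return integer vector with values in \code{1..k}.
#' @export
lcgInteger <- function(gen, n = 1L, k) {
  stopifnot(k >= 1)
  pmin(floor(lcgNext(gen, n) * k) + 1L, k)
}

#' Derive an independent generator for a disjoint stream
#'
#' Produces a new generator with the same constants whose seed is a mix of
#' the parent's current state and a stream index, so e.g. test-set fixtures
#' use a stream disjoint from training fixtures.
#'
#' @param gen an [LCG-class] generator.
#' @param stream nonnegative integer stream index.
#' @return a new \code{LCG}.
#' @export
lcgSpawn <- function(gen, stream = 1L) {
  # golden-ratio multiplicative mix, reduced mod M
  mix <- (gen@state$x + (stream + 1) * 2654435761) %% gen@modulus
  LCG(seed = mix, alpha = gen@alpha, inc = gen@inc, modulus = gen@modulus)
}
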