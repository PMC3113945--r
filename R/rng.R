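# Explicit counter-based random source for the fixture generator.
# Park-Miller minstd LCG (a = 16807, m = 2^31 - 1): 31-bit arithmetic is exact
# in doubles, so streams are reproducible across platforms. State is threaded
# through an environment; nothing touches R's global .Random.seed.

lcgNew <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  s <- floor(abs(seed)) %% 2147483646 + 1  # state in 1 .. m-1
  env <- new.env(parent = emptyenv())
  env$state <- s
  env$count <- 0
  class(env) <- "lcg"
  env
}

lcgNext <- function(rng) {
  rng$state <- (16807 * rng$state) %% 2147483647
  rng$count <- rng$count + 1
  rng$state
}

# uniforms in (0, 1)
lcgUnif <- function(rng, n = 1) vapply(seq_len(n), function(i) lcgNext(rng) / 2147483647, 0)

# integer in 1..k
lcgInt <- function(rng, k) 1L + as.integer(floor(lcgUnif(rng) * k) %% k)

lcgPick <- function(rng, x) x[[lcgInt(rng, length(x))]]

# standard normal via Box-Muller (one value per call; deterministic pair use)
lcgNorm <- function(rng, n = 1) {
  vapply(seq_len(n), function(i) {
    u1 <- lcgUnif(rng); u2 <- lcgUnif(rng)
    sqrt(-2 * log(u1)) * cos(2 * pi * u2)
  }, 0)
}
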