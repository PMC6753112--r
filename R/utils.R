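# Internal helpers: seeding, validation.

#' Derive a named-substream seed from a master seed
#'
#' Every stochastic component of the package draws from its own substream,
#' keyed by a short name, so that adding one simulated trait never perturbs
#' the draws of another. The substream seed is a deterministic 31-bit hash of
#' (seed, stream name).
#'
#' @param seed Master integer seed.
#' @param stream Character stream name, e.g. `"pedigree"`, `"trait/height"`.
#' @return An integer seed below 2^31.
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

set_stream_seed <- function(seed, stream) {
  set.seed(stream_seed(seed, stream))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix-free message built via sprintf
abort_famh2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# truncated normal draw by resampling (bounds far in the tail, so cheap)
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

# 2x2 central finite-difference Hessian of f at x (used for observed
# information of variance-component likelihoods)
fd_hessian2 <- function(f, x, rel_h = 1e-4) {
  h <- pmax(abs(x), 1e-3) * rel_h
  H <- matrix(NA_real_, 2L, 2L)
  for (i in 1:2) {
    ei <- c(0, 0); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f(x) + f(x - ei)) / h[i]^2
  }
  e1 <- c(h[1], 0); e2 <- c(0, h[2])
  H[1, 2] <- H[2, 1] <-
    (f(x + e1 + e2) - f(x + e1 - e2) - f(x - e1 + e2) + f(x - e1 - e2)) /
    (4 * h[1] * h[2])
  H
}
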