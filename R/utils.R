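# Internal helpers: scoped RNG, child-seed derivation, multivariate-normal
# log-density (chol based; only the sampler is available from MASS).

# evaluate code under a fixed seed without disturbing the caller's RNG
withr_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer")
  withr::with_seed(as.integer(seed), code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic substream scheme: stage `k` of a run with master seed
#' `s` uses seed `(s * 1000 + k) mod 2^31 - 1`, so individual pipeline
#' stages can be rerun independently yet reproducibly.
#'
#' @param master Master seed (integer).
#' @param index Substream index (non-negative integer).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(master, index) {
  stopifnot(is.numeric(master), is.numeric(index), index >= 0)
  as.integer((abs(as.numeric(master)) * 1000 + as.numeric(index)) %% (2^31 - 1))
}

# log density of MVN(mean, sigma) at rows of x (matrix n x d)
.dmvnorm_log <- function(x, mean, sigma) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  d <- ncol(x)
  ch <- chol(sigma)
  z <- backsolve(ch, t(x) - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# nearest symmetric part, guarding tiny asymmetries from finite differences
.symm <- function(m) (m + t(m)) / 2
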