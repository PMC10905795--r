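# Internal helpers shared across modules.

# Run code under a local RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Splittable counter scheme: derive a child seed from a parent seed and an
# index, staying below 2^31 (exact in double arithmetic).
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 69069 + as.numeric(index) * 10007 + 1) %% 2147483647)
}

# Pearson kurtosis (m4 / m2^2); 3 for a Gaussian.
kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(NA_real_)
  mean(x^4) / m2^2
}

# Robust z-scores with a floored MAD scale so that near-degenerate inputs
# (identical channels / epochs) do not explode into spurious flags.
robust_z <- function(x, floor) {
  ctr <- stats::median(x)
  sc <- max(1.4826 * stats::mad(x, center = ctr, constant = 1), floor)
  (x - ctr) / sc
}

is_symmetric_matrix <- function(m, tol = 1e-10) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
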