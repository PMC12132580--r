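# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed and restore the caller's RNG state after.
with_seed <- function(seed, expr) {
  force(seed) # must be forced before the RNG state is saved
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one integer seed, staying below 2^31.
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model corrected agreement between two labelings of the same
#' items; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 1)
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Quadratic (parabolic) interpolation of an extremum location around index i0.
# Returns fractional index; falls back to i0 at array edges.
parabolic_peak <- function(y, i0) {
  n <- length(y)
  if (i0 <= 1 || i0 >= n) return(as.numeric(i0))
  denom <- y[i0 - 1] - 2 * y[i0] + y[i0 + 1]
  if (abs(denom) < .Machine$double.eps) return(as.numeric(i0))
  i0 + 0.5 * (y[i0 - 1] - y[i0 + 1]) / denom
}

# Gaussian smoothing of a uniformly sampled series with edge renormalization,
# so that total mass is conserved away from the boundaries.
gauss_smooth <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(seq(-half, half), sd = sigma_bins)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  sm <- stats::filter(xp, k / sum(k), sides = 2)
  sm <- as.numeric(sm[(half + 1):(half + n)])
  # renormalize near edges where the kernel is truncated
  w <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k / sum(k), sides = 2)
  w <- as.numeric(w[(half + 1):(half + n)])
  sm / w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
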