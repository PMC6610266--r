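# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483629 + 1
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# Discrete Gaussian kernel, sigma in voxels, truncated at 4 sigma, unit sum.
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Shift a 3-D array by `by` voxels along `axis`, zero-filling exposed planes.
shift3d <- function(a, by, axis) {
  d <- dim(a)
  if (by == 0L) return(a)
  out <- array(0, d)
  src <- dst <- lapply(d, seq_len)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  if (by > 0) {
    dst[[axis]] <- (by + 1L):n
    src[[axis]] <- 1L:(n - by)
  } else {
    dst[[axis]] <- 1L:(n + by)
    src[[axis]] <- (1L - by):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# Separable Gaussian smoothing with zero padding outside the grid.
# sigma_vox: scalar or length-3 sigma in voxel units per axis.
gaussian_smooth3d <- function(a, sigma_vox) {
  stopifnot(length(dim(a)) == 3L)
  sigma_vox <- rep(sigma_vox, length.out = 3L)
  out <- a
  for (axis in 1:3) {
    k <- gauss_kernel(sigma_vox[axis])
    if (length(k) == 1L) next
    h <- (length(k) - 1L) %/% 2L
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift3d(out, j - h - 1L, axis)
    }
    out <- acc
  }
  out
}
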