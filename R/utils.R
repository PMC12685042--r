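# Internal numerical helpers: boundary-aware 1D filters applied along array
# axes, separable 3D Gaussian blur, local maxima and connected components.

# Reflect an out-of-range 1-based index into 1..n ("reflect" convention with
# edge repetition: d c b a | a b c d | d c b a).
reflect_index <- function(i, n) {
  j <- (i - 1L) %% (2L * n)
  ifelse(j < n, j + 1L, 2L * n - j)
}

# n x n smoothing matrix for a set of taps at integer offsets, reflect boundary.
smoothing_matrix <- function(n, weights, offsets) {
  stopifnot(length(weights) == length(offsets))
  idx <- seq_len(n)
  ii <- rep(idx, times = length(offsets))
  jj <- reflect_index(rep(idx, times = length(offsets)) +
                        rep(offsets, each = n), n)
  xx <- rep(weights, each = n)
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# Centered uniform filter taps; for even sizes the window is [-k/2, k/2 - 1],
# matching the common image-processing origin convention.
uniform_offsets <- function(size) {
  seq.int(-(size %/% 2), size - 1L - size %/% 2)
}

uniform_filter_matrix <- function(n, size) {
  smoothing_matrix(n, rep(1 / size, size), uniform_offsets(size))
}

# Apply a size-`size` uniform filter along a numeric vector (reflect boundary).
uniform_filter1 <- function(x, size) {
  as.numeric(uniform_filter_matrix(length(x), size) %*% x)
}

gaussian_taps <- function(sigma) {
  if (sigma <= 0) return(list(w = 1, o = 0L))
  r <- as.integer(ceiling(3 * sigma))
  o <- seq.int(-r, r)
  w <- exp(-0.5 * (o / sigma)^2)
  list(w = w / sum(w), o = o)
}

gaussian_filter_matrix <- function(n, sigma) {
  g <- gaussian_taps(sigma)
  smoothing_matrix(n, g$w, g$o)
}

# Separable Gaussian blur of a 3D array; sigma is a scalar or length-3 vector
# of per-axis standard deviations in voxel units (y, x, z order).
gauss_blur_3d <- function(a, sigma) {
  d <- dim(a)
  stopifnot(length(d) == 3L)
  sigma <- rep_len(sigma, 3L)
  m <- a
  if (sigma[1] > 0) {
    m <- array(as.numeric(gaussian_filter_matrix(d[1], sigma[1]) %*%
                            matrix(m, d[1], d[2] * d[3])), d)
  }
  if (sigma[2] > 0) {
    p <- aperm(m, c(2, 1, 3))
    p <- array(as.numeric(gaussian_filter_matrix(d[2], sigma[2]) %*%
                            matrix(p, d[2], d[1] * d[3])), dim(p))
    m <- aperm(p, c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    p <- aperm(m, c(3, 1, 2))
    p <- array(as.numeric(gaussian_filter_matrix(d[3], sigma[3]) %*%
                            matrix(p, d[3], d[1] * d[2])), dim(p))
    m <- aperm(p, c(2, 3, 1))
  }
  m
}

# 2D separable Gaussian blur of a matrix (reflect boundary).
gauss_blur_2d <- function(m, sigma) {
  sigma <- rep_len(sigma, 2L)
  d <- dim(m)
  out <- m
  if (sigma[1] > 0) out <- as.matrix(gaussian_filter_matrix(d[1], sigma[1]) %*% out)
  if (sigma[2] > 0) out <- t(as.matrix(gaussian_filter_matrix(d[2], sigma[2]) %*% t(out)))
  out
}

# Shift a 3D array by integer offsets, filling vacated entries.
shift3 <- function(a, dy, dx, dz, fill) {
  d <- dim(a)
  out <- array(fill, d)
  ys <- max(1, 1 + dy):min(d[1], d[1] + dy)
  xs <- max(1, 1 + dx):min(d[2], d[2] + dx)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (dy > d[1] || dy < -d[1] || dx > d[2] || dx < -d[2] || dz > d[3] || dz < -d[3])
    return(out)
  out[ys, xs, zs] <- a[ys - dy, xs - dx, zs - dz]
  out
}

neighbor_offsets <- function(connectivity = 26L) {
  g <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  g <- g[!(g$dy == 0 & g$dx == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dy) + abs(g$dx) + abs(g$dz) == 1, ]
  g
}

# Logical array of voxels that are >= all neighbors under the given
# connectivity (plateaus included; collapse them separately).
local_maxima_3d <- function(a, connectivity = 26L) {
  offs <- neighbor_offsets(connectivity)
  ok <- array(TRUE, dim(a))
  for (r in seq_len(nrow(offs))) {
    ok <- ok & (a >= shift3(a, offs$dy[r], offs$dx[r], offs$dz[r], -Inf))
  }
  ok
}

# Connected components of a logical mask by iterative minimum-label
# propagation. If `values` is given, two neighboring voxels connect only when
# their values are equal (used to collapse plateaus of local maxima).
connected_components_3d <- function(mask, connectivity = 6L, values = NULL) {
  d <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  comp <- array(Inf, d)
  comp[mask] <- which(mask)
  repeat {
    prev <- comp
    for (r in seq_len(nrow(offs))) {
      cand <- shift3(comp, offs$dy[r], offs$dx[r], offs$dz[r], Inf)
      if (!is.null(values)) {
        vn <- shift3(values, offs$dy[r], offs$dx[r], offs$dz[r], NA_real_)
        cand[is.na(vn) | vn != values] <- Inf
      }
      comp <- pmin(comp, cand)
    }
    comp[!mask] <- Inf
    if (identical(prev, comp)) break
  }
  lab <- array(0L, d)
  if (any(mask)) {
    ids <- sort(unique(comp[mask]))
    lab[mask] <- match(comp[mask], ids)
  }
  lab
}

# Deterministic child-seed derivation from one master seed (kept < 2^31).
derive_seed <- function(master, k) {
  as.integer((abs(as.numeric(master)) %% 65011 * 31907 + k * 2713 + 17) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
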