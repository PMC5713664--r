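# Internal array primitives shared by every module: separable Gaussian
# smoothing with replicate padding, finite-difference gradients, and the
# linear (bi-/trilinear) sampler together with the analytic derivative of the
# interpolant.  Everything operates on plain numeric arrays of rank 2 or 3;
# the public classes (scalar_image, displacement_field) wrap these.

.gauss_kernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along dimension `along`; `pad` is "replicate" or "zero".
.conv1d_along <- function(arr, kernel, along, pad = "replicate") {
  d <- dim(arr)
  nd <- length(d)
  if (length(kernel) == 1L) return(arr * kernel)
  perm <- c(along, seq_len(nd)[-along])
  x <- aperm(arr, perm)
  m <- d[along]
  x <- matrix(x, nrow = m)
  r <- (length(kernel) - 1L) %/% 2L
  if (pad == "replicate") {
    xp <- x[c(rep(1L, r), seq_len(m), rep(m, r)), , drop = FALSE]
  } else {
    xp <- rbind(matrix(0, r, ncol(x)), x, matrix(0, r, ncol(x)))
  }
  out <- matrix(0, nrow = m, ncol = ncol(x))
  for (t in seq_along(kernel)) {
    out <- out + kernel[t] * xp[(t - 1L) + seq_len(m), , drop = FALSE]
  }
  out <- array(out, dim = d[perm])
  aperm(out, order(perm))
}

.gaussian_smooth_array <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- .gauss_kernel1d(sigma)
  for (ax in seq_along(dim(arr))) arr <- .conv1d_along(arr, k, ax)
  arr
}

# Per-axis finite differences: central in the interior, one-sided at the two
# boundary slices.  Units: intensity per voxel.
.diff_along <- function(arr, along) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(along, seq_len(nd)[-along])
  x <- aperm(arr, perm)
  m <- d[along]
  x <- matrix(x, nrow = m)
  out <- matrix(0, nrow = m, ncol = ncol(x))
  if (m >= 3L) {
    out[2:(m - 1L), ] <- (x[3:m, , drop = FALSE] - x[1:(m - 2L), , drop = FALSE]) / 2
  }
  out[1L, ] <- x[2L, ] - x[1L, ]
  out[m, ] <- x[m, ] - x[m - 1L, ]
  out <- array(out, dim = d[perm])
  aperm(out, order(perm))
}

# Column-major grid of 1-based voxel indices, one row per voxel, matching the
# storage order of `array()`.
.grid_coords <- function(shape) {
  nd <- length(shape)
  n <- prod(shape)
  out <- matrix(0, nrow = n, ncol = nd)
  rep_each <- 1L
  for (ax in seq_len(nd)) {
    out[, ax] <- rep(rep(seq_len(shape[ax]), each = rep_each),
                     length.out = n)
    rep_each <- rep_each * shape[ax]
  }
  out
}

# Linear interpolation of `arr` at fractional 1-based coordinates (one row
# per sample).  pad = "replicate" clamps; pad = "constant" returns pad_value
# for any coordinate strictly outside [1, dim].
.sample_linear <- function(arr, coords, pad = "replicate", pad_value = 0) {
  d <- dim(arr)
  nd <- length(d)
  stopifnot(ncol(coords) == nd)
  outside <- rep(FALSE, nrow(coords))
  if (pad == "constant") {
    for (ax in seq_len(nd)) {
      outside <- outside | coords[, ax] < 1 | coords[, ax] > d[ax]
    }
  }
  cl <- coords
  for (ax in seq_len(nd)) cl[, ax] <- pmin(pmax(cl[, ax], 1), d[ax])
  i0 <- floor(cl)
  for (ax in seq_len(nd)) i0[, ax] <- pmin(i0[, ax], d[ax] - 1L)
  w <- cl - i0
  if (nd == 2L) {
    f00 <- arr[cbind(i0[, 1], i0[, 2])]
    f10 <- arr[cbind(i0[, 1] + 1, i0[, 2])]
    f01 <- arr[cbind(i0[, 1], i0[, 2] + 1)]
    f11 <- arr[cbind(i0[, 1] + 1, i0[, 2] + 1)]
    wx <- w[, 1]; wy <- w[, 2]
    val <- (1 - wx) * (1 - wy) * f00 + wx * (1 - wy) * f10 +
      (1 - wx) * wy * f01 + wx * wy * f11
  } else {
    f000 <- arr[cbind(i0[, 1], i0[, 2], i0[, 3])]
    f100 <- arr[cbind(i0[, 1] + 1, i0[, 2], i0[, 3])]
    f010 <- arr[cbind(i0[, 1], i0[, 2] + 1, i0[, 3])]
    f110 <- arr[cbind(i0[, 1] + 1, i0[, 2] + 1, i0[, 3])]
    f001 <- arr[cbind(i0[, 1], i0[, 2], i0[, 3] + 1)]
    f101 <- arr[cbind(i0[, 1] + 1, i0[, 2], i0[, 3] + 1)]
    f011 <- arr[cbind(i0[, 1], i0[, 2] + 1, i0[, 3] + 1)]
    f111 <- arr[cbind(i0[, 1] + 1, i0[, 2] + 1, i0[, 3] + 1)]
    wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
    c00 <- f000 * (1 - wx) + f100 * wx
    c10 <- f010 * (1 - wx) + f110 * wx
    c01 <- f001 * (1 - wx) + f101 * wx
    c11 <- f011 * (1 - wx) + f111 * wx
    c0 <- c00 * (1 - wy) + c10 * wy
    c1 <- c01 * (1 - wy) + c11 * wy
    val <- c0 * (1 - wz) + c1 * wz
  }
  if (any(outside)) val[outside] <- pad_value
  val
}

# Analytic partial derivatives of the linear interpolant of `arr` at the
# given coordinates (one row per sample, one column per axis).  Outside the
# valid domain the interpolant is constant along the clamped axis, so the
# corresponding derivative is zero.
.sample_linear_grad <- function(arr, coords) {
  d <- dim(arr)
  nd <- length(d)
  cl <- coords
  for (ax in seq_len(nd)) cl[, ax] <- pmin(pmax(cl[, ax], 1), d[ax])
  i0 <- floor(cl)
  for (ax in seq_len(nd)) i0[, ax] <- pmin(i0[, ax], d[ax] - 1L)
  w <- cl - i0
  g <- matrix(0, nrow = nrow(coords), ncol = nd)
  if (nd == 2L) {
    f00 <- arr[cbind(i0[, 1], i0[, 2])]
    f10 <- arr[cbind(i0[, 1] + 1, i0[, 2])]
    f01 <- arr[cbind(i0[, 1], i0[, 2] + 1)]
    f11 <- arr[cbind(i0[, 1] + 1, i0[, 2] + 1)]
    wx <- w[, 1]; wy <- w[, 2]
    g[, 1] <- (1 - wy) * (f10 - f00) + wy * (f11 - f01)
    g[, 2] <- (1 - wx) * (f01 - f00) + wx * (f11 - f10)
  } else {
    f000 <- arr[cbind(i0[, 1], i0[, 2], i0[, 3])]
    f100 <- arr[cbind(i0[, 1] + 1, i0[, 2], i0[, 3])]
    f010 <- arr[cbind(i0[, 1], i0[, 2] + 1, i0[, 3])]
    f110 <- arr[cbind(i0[, 1] + 1, i0[, 2] + 1, i0[, 3])]
    f001 <- arr[cbind(i0[, 1], i0[, 2], i0[, 3] + 1)]
    f101 <- arr[cbind(i0[, 1] + 1, i0[, 2], i0[, 3] + 1)]
    f011 <- arr[cbind(i0[, 1], i0[, 2] + 1, i0[, 3] + 1)]
    f111 <- arr[cbind(i0[, 1] + 1, i0[, 2] + 1, i0[, 3] + 1)]
    wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
    g[, 1] <- (1 - wy) * (1 - wz) * (f100 - f000) + wy * (1 - wz) * (f110 - f010) +
      (1 - wy) * wz * (f101 - f001) + wy * wz * (f111 - f011)
    g[, 2] <- (1 - wx) * (1 - wz) * (f010 - f000) + wx * (1 - wz) * (f110 - f100) +
      (1 - wx) * wz * (f011 - f001) + wx * wz * (f111 - f101)
    g[, 3] <- (1 - wx) * (1 - wy) * (f001 - f000) + wx * (1 - wy) * (f101 - f100) +
      (1 - wx) * wy * (f011 - f010) + wx * wy * (f111 - f110)
  }
  for (ax in seq_len(nd)) {
    bad <- coords[, ax] < 1 | coords[, ax] > d[ax]
    if (any(bad)) g[bad, ax] <- 0
  }
  g
}
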