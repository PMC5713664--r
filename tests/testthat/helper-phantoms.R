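# Shared fixtures, built in code: smooth textured images, random smooth
# displacement fields, and brute-force oracles kept deliberately independent
# of the package implementations they check.

smooth_textured_image <- function(shape, lo = 0.25, hi = 0.75, smooth = 2) {
  a <- gmidemons:::.gaussian_smooth_array(array(runif(prod(shape)),
                                                dim = shape), smooth)
  a <- (a - min(a)) / (max(a) - min(a))
  scalar_image(lo + (hi - lo) * a)
}

random_smooth_field <- function(shape, rms = 0.6, smooth = 2) {
  nd <- length(shape)
  fv <- array(rnorm(prod(shape) * nd), dim = c(shape, nd))
  fv <- gmidemons:::.smooth_field_array(fv, smooth)
  displacement_field(fv * (rms / sqrt(mean(fv^2))))
}

# O(n * m) double-loop Hausdorff oracles.  Squared components are added one
# by one in double precision (R's sum() accumulates in long double, which
# would differ from any double-precision implementation in the last bits).
oracle_pair_dist <- function(a, b) {
  s <- 0
  for (t in a - b) s <- s + t * t
  sqrt(s)
}

oracle_directed_hausdorff <- function(A, B) {
  worst <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      best <- min(best, oracle_pair_dist(A[i, ], B[j, ]))
    }
    worst <- max(worst, best)
  }
  worst
}

oracle_directed_mhd <- function(A, B) {
  acc <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B))) {
      best <- min(best, oracle_pair_dist(A[i, ], B[j, ]))
    }
    acc <- acc + best
  }
  acc / nrow(A)
}

# index-shift warp oracle for integer-valued fields (in-bounds pixels only)
oracle_integer_warp <- function(arr, vx, vy) {
  d <- dim(arr)
  out <- array(NA_real_, dim = d)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      si <- i + vx[i, j]
      sj <- j + vy[i, j]
      if (si >= 1 && si <= d[1] && sj >= 1 && sj <= d[2]) {
        out[i, j] <- arr[si, sj]
      }
    }
  }
  out
}
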