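# Parzen-window joint density, mutual information, and the
# gradient-of-mutual-information force field.
#
# The joint intensity density of the reference image R and the warped
# floating image F(P + v) is estimated on a regular lattice over [0,1]^2:
#   p(i, j) = (1/N) sum_P K_delta(R(P) - i) K_delta(F(P+v) - j)
# with K_delta a Gaussian kernel of width delta.  All integrals over the
# lattice use trapezoidal quadrature, and the density is renormalized so its
# lattice integral is exactly 1 (the Gaussian tails that fall outside [0,1]
# would otherwise lose a small amount of mass near the intensity extremes).

.check_unit_interval <- function(x, what) {
  if (any(x < -1e-6) || any(x > 1 + 1e-6)) {
    stop(what, " intensities must be normalized to [0, 1]; see normalize_image()")
  }
  pmin(pmax(x, 0), 1)
}

# Core density estimator on intensity vectors.
.joint_density_core <- function(r_vec, f_vec, delta, lattice_size) {
  n <- length(r_vec)
  if (n == 0L) stop("empty overlap: no voxels contribute to the joint density")
  L <- as.integer(lattice_size)
  lattice <- seq(0, 1, length.out = L)
  h <- lattice[2] - lattice[1]
  w <- rep(h, L); w[c(1L, L)] <- h / 2  # trapezoid weights
  kr <- stats::dnorm(outer(r_vec, lattice, "-"), sd = delta)  # n x L
  kf <- stats::dnorm(outer(f_vec, lattice, "-"), sd = delta)
  grid <- crossprod(kr, kf) / n                               # L x L
  z <- as.numeric(w %*% grid %*% w)
  if (z <= 0) stop("degenerate joint density (zero total mass)")
  grid <- grid / z
  marginal_r <- as.vector(grid %*% w)
  marginal_f <- as.vector(w %*% grid)
  structure(list(grid = grid, lattice = lattice, step = h, quad_w = w,
                 delta = delta, n_samples = n,
                 marginal_r = marginal_r, marginal_f = marginal_f),
            class = "joint_density")
}

#' Parzen-window joint intensity density
#'
#' Estimates the joint density `p(i, j)` of reference / warped-floating
#' intensity pairs with a separable Gaussian Parzen kernel of width `delta`,
#' evaluated on a `lattice_size` x `lattice_size` lattice over the unit
#' intensity square.  The density is renormalized to integrate to 1 over the
#' lattice (trapezoidal quadrature) and carries its marginals.
#'
#' @param r_img reference image with intensities in [0, 1].
#' @param warped_f floating image resampled onto the reference grid,
#'   intensities in [0, 1].
#' @param delta Parzen kernel width in normalized intensity units.
#' @param lattice_size lattice points per intensity axis (>= 8).
#' @return An object of class `joint_density` with fields `grid` (the L x L
#'   density, reference intensity on rows), `lattice`, `step`, `quad_w`,
#'   `delta`, `n_samples`, `marginal_r`, `marginal_f`.
#' @examples
#' r <- scalar_image(matrix(runif(64), 8, 8))
#' jd <- estimate_joint_density(r, r, delta = 0.05, lattice_size = 32)
#' sum(outer(jd$quad_w, jd$quad_w) * jd$grid)  # integrates to 1
#' @export
estimate_joint_density <- function(r_img, warped_f, delta = 0.05,
                                   lattice_size = 64L) {
  if (!is.numeric(delta) || delta <= 0) stop("`delta` must be > 0")
  if (lattice_size < 8) stop("`lattice_size` must be >= 8")
  r <- .as_image(r_img)$data
  f <- .as_image(warped_f)$data
  if (!identical(dim(r), dim(f))) {
    stop("images must share a grid for joint-density estimation")
  }
  rv <- .check_unit_interval(as.vector(r), "reference")
  fv <- .check_unit_interval(as.vector(f), "floating")
  .joint_density_core(rv, fv, delta, lattice_size)
}

#' @export
print.joint_density <- function(x, ...) {
  cat("<joint_density> ", length(x$lattice), "^2 lattice | delta ", x$delta,
      " | N ", x$n_samples, " | MI ", signif(mutual_information(x), 5),
      " nats\n", sep = "")
  invisible(x)
}

#' Mutual information of a joint density
#'
#' Computes `MI = integral p(i,j) log( p(i,j) / (p_R(i) p_F(j)) ) di dj` by
#' trapezoidal lattice quadrature, in nats (natural logarithm).  Lattice
#' cells with `p(i,j) = 0` contribute zero.
#'
#' @param jd a `joint_density` from [estimate_joint_density()].
#' @return Mutual information in nats (non-negative up to quadrature error).
#' @export
mutual_information <- function(jd) {
  stopifnot(inherits(jd, "joint_density"))
  p <- jd$grid
  ratio_log <- log(p) - outer(log(jd$marginal_r), log(jd$marginal_f), "+")
  integrand <- p * ratio_log
  integrand[p == 0] <- 0
  as.numeric(jd$quad_w %*% integrand %*% jd$quad_w)
}

# Core of the MI force.  Takes flattened intensities of the reference and the
# already-warped floating image plus the floating gradient sampled at the
# displaced points (n x d), and returns the per-voxel gradient of mutual
# information with respect to the displacement of each voxel:
#   (1/N) [Psi_delta (x) dL/dj](R(P), F(P+v)) * gradF(P+v)
# where L(i,j) = 1 + log(p(i,j) / (p_R(i) p_F(j))).  dL/dj is taken by
# central differences on the intensity lattice, the 2D convolution with
# Psi_delta is separable with zero extension (the density has no mass beyond
# the lattice), and the bracket is evaluated at each voxel's intensity pair
# by bilinear interpolation.
.mi_force_core <- function(r_vec, f_vec, gradF, delta, lattice_size, shape,
                           need_force = TRUE) {
  jd <- .joint_density_core(.check_unit_interval(r_vec, "reference"),
                            .check_unit_interval(f_vec, "floating"),
                            delta, lattice_size)
  mi_value <- mutual_information(jd)
  if (!need_force) {
    return(list(mi_value = mi_value, jd = jd, force_mat = NULL))
  }
  h <- jd$step
  Lmat <- 1 + log(jd$grid) -
    outer(log(jd$marginal_r), log(jd$marginal_f), "+")
  dLdj <- .diff_along(Lmat, 2L) / h
  m <- max(1L, as.integer(ceiling(4 * delta / h)))
  taps <- stats::dnorm((-m:m) * h, sd = delta) * h
  G <- .conv1d_along(dLdj, taps, 1L, pad = "zero")
  G <- .conv1d_along(G, taps, 2L, pad = "zero")
  # lattice coordinates of each voxel's intensity pair
  ic <- cbind(pmin(pmax(r_vec, 0), 1) / h + 1,
              pmin(pmax(f_vec, 0), 1) / h + 1)
  bracket <- .sample_linear(G, ic)
  force_mat <- gradF * (bracket / jd$n_samples)
  list(mi_value = mi_value, jd = jd, force_mat = force_mat,
       n_samples = jd$n_samples)
}

#' Gradient-of-mutual-information force field
#'
#' The derivative of the Parzen-window mutual information with respect to the
#' per-voxel displacement: at each reference voxel `P`,
#' \deqn{\nabla MI(P) = \frac{1}{N}\,[\Psi_\delta \otimes \partial L/\partial j]
#'   \bigl(R(P), F(P+v)\bigr)\; \nabla F(P+v)}
#' with `L(i,j) = 1 + log( p(i,j) / (p_R(i) p_F(j)) )`.  The spatial factor
#' `\nabla F(P+v)` is the exact derivative of the linear warp interpolant, so
#' the returned field is the analytic gradient of the discrete MI objective
#' computed by [mutual_information()] (up to lattice discretization).
#'
#' @param r_img reference image, intensities in [0, 1].
#' @param f_img floating image (unwarped), intensities in [0, 1].
#' @param field current `displacement_field` on the reference grid.
#' @param delta Parzen width.
#' @param lattice_size intensity lattice resolution.
#' @param pad,pad_value out-of-bounds policy for the warp.
#' @return An object of class `mi_force_field`: a list with `vectors` (array
#'   `c(shape, d)` of per-voxel MI gradients) and `mi_value` (MI of the
#'   current configuration, in nats).
#' @export
mi_gradient_field <- function(r_img, f_img, field, delta = 0.05,
                              lattice_size = 64L,
                              pad = c("replicate", "constant"),
                              pad_value = 0) {
  pad <- match.arg(pad)
  r <- .as_image(r_img)
  f <- .as_image(f_img)
  shape <- field_shape(field)
  if (!identical(shape, dim(r$data))) {
    stop("field grid does not match the reference grid")
  }
  coords <- .grid_coords(shape) + .field_matrix(field)
  wf_vec <- .sample_linear(f$data, coords, pad = pad, pad_value = pad_value)
  gradF <- .sample_linear_grad(f$data, coords)
  res <- .mi_force_core(as.vector(r$data), wf_vec, gradF, delta,
                        lattice_size, shape)
  structure(list(vectors = array(res$force_mat,
                                 dim = c(shape, length(shape))),
                 mi_value = res$mi_value),
            class = "mi_force_field")
}
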