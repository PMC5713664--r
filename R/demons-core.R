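#' Classic demons force field
#'
#' At every voxel `P` the optical-flow ("demons") force is
#' \deqn{v = \frac{(r - f)\,\nabla r}{\|\nabla r\|^2 + (r - f)^2 / k^2}}
#' where `r` is the reference intensity, `f` the floating intensity already
#' resampled onto the reference grid, and `k` a normalization factor that
#' compensates for the intensity mismatch between the images.  Where the
#' denominator is exactly zero (`f = r` and `\nabla r = 0`) the force is the
#' zero vector.  The per-voxel magnitude is analytically bounded by `k / 2`.
#'
#' Sign convention: under the pull composition used throughout (`o(P) =
#' F(P + v)`), the intensity difference must enter as `r - f` for the force
#' to reduce the local mismatch (it is the negative gradient of
#' `(F(P+v) - r)^2 / 2` under the demons approximation
#' `\nabla F(P+v) \approx \nabla r`); writing the same force with `f - r`
#' corresponds to the push convention for `v`.
#'
#' @param r_img reference `scalar_image` (or array).
#' @param warped_f floating image already warped onto the reference grid.
#' @param grad_r reference gradient as returned by [image_gradient()];
#'   computed on the fly when `NULL`.
#' @param k positive normalization factor.
#' @return Numeric array of dimension `c(shape, d)`: one force vector per
#'   voxel.
#' @export
demons_force <- function(r_img, warped_f, grad_r = NULL, k = 1) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("`k` must be > 0")
  r <- .as_image(r_img)$data
  f <- .as_image(warped_f)$data
  if (!identical(dim(r), dim(f))) {
    stop("reference and warped floating images must share a grid")
  }
  if (is.null(grad_r)) grad_r <- image_gradient(r)
  d <- dim(r)
  nd <- length(d)
  n <- prod(d)
  diff <- r - f
  g <- matrix(grad_r, ncol = nd)
  denom <- rowSums(g^2) + as.vector(diff)^2 / k^2
  scale <- ifelse(denom == 0, 0, as.vector(diff) / denom)
  force <- g * scale
  array(force, dim = c(d, nd))
}

# Scale down any per-voxel update whose magnitude exceeds max_step.
.cap_step <- function(inc_mat, max_step) {
  mag <- sqrt(rowSums(inc_mat^2))
  over <- mag > max_step
  if (any(over)) inc_mat[over, ] <- inc_mat[over, ] * (max_step / mag[over])
  inc_mat
}

# Smooth every component of a field array c(shape, nd) with a Gaussian.
.smooth_field_array <- function(vec_arr, sigma) {
  if (sigma <= 0) return(vec_arr)
  dv <- dim(vec_arr)
  nd <- length(dv) - 1L
  n <- prod(dv[-length(dv)])
  for (ax in seq_len(nd)) {
    sel <- seq.int((ax - 1L) * n + 1L, ax * n)
    comp <- array(vec_arr[sel], dim = dv[-length(dv)])
    vec_arr[sel] <- .gaussian_smooth_array(comp, sigma)
  }
  vec_arr
}

# Shared update body of the classic and MI-augmented iterations.  The
# floating image is sampled through the current field, forces are computed,
# capped, added to the field, and the summed field is Gaussian-regularized
# (diffusion-like smoothing of the total field).  With alpha = 0 the MI term
# is skipped entirely, so the classic iteration is bit-identical to the
# MI-augmented iteration at alpha = 0.
.reg_step <- function(field, r_img, f_img, cfg, grad_r = NULL,
                      grad_f = NULL, alpha = cfg$alpha, with_mi = alpha > 0,
                      need_mi_value = FALSE) {
  r <- .as_image(r_img)
  f <- .as_image(f_img)
  shape <- field_shape(field)
  if (!identical(shape, dim(r$data))) {
    stop("field grid does not match the reference grid")
  }
  if (is.null(grad_r)) grad_r <- image_gradient(r)
  coords <- .grid_coords(shape) + .field_matrix(field)
  wf_vec <- .sample_linear(f$data, coords, pad = cfg$pad,
                           pad_value = cfg$pad_value)
  wf <- array(wf_vec, dim = shape)
  inc <- matrix(demons_force(r$data, wf, grad_r, cfg$k), ncol = length(shape))
  mi_value <- NA_real_
  if (with_mi || need_mi_value) {
    gradF <- .sample_linear_grad(f$data, coords)
    mi <- .mi_force_core(as.vector(r$data), wf_vec, gradF,
                         delta = cfg$parzen_delta,
                         lattice_size = cfg$lattice_size,
                         shape = shape,
                         need_force = with_mi)
    mi_value <- mi$mi_value
    # The MI step is scaled by the overlap count N so the per-voxel update is
    # resolution-independent across pyramid levels (grad MI itself carries a
    # 1/N factor); alpha is therefore a per-sample step size.
    if (with_mi) inc <- inc + alpha * mi$n_samples * mi$force_mat
  }
  inc <- .cap_step(inc, cfg$max_step)
  new_vec <- .field_matrix(field) + inc
  new_arr <- array(new_vec, dim = dim(field$vectors))
  new_arr <- .smooth_field_array(new_arr, cfg$sigma)
  list(field = displacement_field(new_arr, level = field$level),
       mi_value = mi_value,
       max_update = if (nrow(inc)) max(sqrt(rowSums(inc^2))) else 0,
       msd = mean((wf_vec - as.vector(r$data))^2))
}

#' One classic demons iteration
#'
#' Computes `G_sigma * (v^n + force)`: the floating image is sampled through
#' the current field, the demons force is evaluated, added to the field, and
#' the summed field is smoothed component-wise with a Gaussian of standard
#' deviation `cfg$sigma` (sigma = 0 means no smoothing).  Per-voxel updates
#' are capped at `cfg$max_step` voxels before smoothing.
#'
#' @param field current `displacement_field` (iterate `v^n`).
#' @param r_img reference `scalar_image`.
#' @param f_img floating `scalar_image` (unwarped; it is sampled through the
#'   field internally).
#' @param cfg a [registration_config()].
#' @return The updated `displacement_field` `v^(n+1)`.
#' @seealso [gmi_demons_iteration()] for the mutual-information-augmented
#'   update.
#' @export
demons_iteration <- function(field, r_img, f_img, cfg = registration_config()) {
  .reg_step(field, r_img, f_img, cfg, alpha = 0)$field
}
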