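# Synthetic multimodal phantom pairs with known ground-truth misalignment.
# The generator emulates the PET/CT scenario the registration is built for:
# one anatomy rendered under two different intensity mappings, a bright
# "lesion" blob (emulating focal FDG uptake) present only in the reference
# channel, a smooth random ground-truth deformation, a rigid offset, and
# additive Gaussian noise on both channels.

#' Phantom specification
#'
#' Defaults encode the standard study conditions used throughout the test
#' suite: 64 x 64 grids, deformations of up to 5 voxels with a ~10-voxel
#' smoothness scale, a rigid offset of (5, -3) voxels plus a 5 degree
#' rotation, additive noise with standard deviation 0.01 on unit-normalized
#' intensities, and a non-monotone ("tent") intensity remap under which
#' intensity differences alone misdirect a monomodal registration.
#'
#' @param shape grid dimensions (length 2 or 3).
#' @param deform_amplitude maximum ground-truth displacement magnitude in
#'   voxels (>= 0).
#' @param deform_scale Gaussian smoothness length of the deformation, voxels.
#' @param rigid_rotation rotation of the rigid offset, radians (scalar for
#'   2D, length-3 for 3D).
#' @param rigid_translation translation of the rigid offset, voxels.
#' @param noise_sigma additive Gaussian noise standard deviation (>= 0).
#' @param remap intensity transfer producing the "CT-like" channel from the
#'   "PET-like" anatomy: `"nonmonotone"` (tent map `1 - |2x - 1|`),
#'   `"monotone"` (`sqrt(x)`) or `"identity"`.
#' @param lesion add the reference-only bright lesion blob.
#' @param seed RNG seed; a fixed seed makes the pair fully reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L),
                         deform_amplitude = 5,
                         deform_scale = 10,
                         rigid_rotation = 5 * pi / 180,
                         rigid_translation = c(5, -3),
                         noise_sigma = 0.01,
                         remap = c("nonmonotone", "monotone", "identity"),
                         lesion = TRUE,
                         seed = 1L) {
  remap <- match.arg(remap)
  nd <- length(shape)
  stopifnot(nd %in% c(2L, 3L), all(shape >= 12),
            deform_amplitude >= 0, deform_scale > 0, noise_sigma >= 0,
            length(rigid_translation) == nd)
  if (nd == 3L && length(rigid_rotation) == 1L && rigid_rotation[1] == 0) {
    rigid_rotation <- c(0, 0, 0)
  }
  structure(list(shape = as.integer(shape),
                 deform_amplitude = deform_amplitude,
                 deform_scale = deform_scale,
                 rigid_rotation = rigid_rotation,
                 rigid_translation = rigid_translation,
                 noise_sigma = noise_sigma, remap = remap,
                 lesion = isTRUE(lesion), seed = as.integer(seed)),
            class = "phantom_spec")
}

.remap_fun <- function(kind) {
  switch(kind,
         nonmonotone = function(x) 1 - abs(2 * x - 1),
         monotone = function(x) sqrt(x),
         identity = identity)
}

# Nested-ellipse anatomy on [0,1] intensities: background 0.05, body 0.30,
# inner organ 0.55, ring 0.80.  Rendered binary and smoothed (sigma = 1
# voxel) to give the contours a finite, resolvable width.
.render_anatomy <- function(shape) {
  nd <- length(shape)
  g <- .grid_coords(shape)
  ctr <- (1 + shape) / 2
  u <- sweep(g, 2, ctr, "-")
  u <- sweep(u, 2, shape / 2, "/")   # normalized [-1, 1] coordinates
  r_body <- c(0.78, 0.62, 0.70)[seq_len(nd)]
  q_body <- rowSums(sweep(u, 2, r_body, "/")^2)
  organ_ctr <- c(-0.18, 0.12, 0)[seq_len(nd)]
  r_organ <- c(0.3, 0.26, 0.3)[seq_len(nd)]
  q_organ <- rowSums(sweep(sweep(u, 2, organ_ctr, "-"), 2, r_organ, "/")^2)
  ring_ctr <- c(0.3, -0.18, 0)[seq_len(nd)]
  r_ring <- c(0.26, 0.3, 0.28)[seq_len(nd)]
  q_ring <- rowSums(sweep(sweep(u, 2, ring_ctr, "-"), 2, r_ring, "/")^2)
  val <- rep(0.05, nrow(g))
  val[q_body <= 1] <- 0.30
  val[q_organ <= 1] <- 0.55
  val[q_ring <= 1 & q_ring >= 0.45] <- 0.80
  arr <- array(val, dim = shape)
  .gaussian_smooth_array(arr, 1)
}

.render_lesion <- function(shape) {
  nd <- length(shape)
  g <- .grid_coords(shape)
  ctr <- (1 + shape) / 2 + shape * c(0.10, 0.16, 0)[seq_len(nd)]
  rad <- pmax(shape * 0.055, 2)
  q <- rowSums(sweep(sweep(g, 2, ctr, "-"), 2, rad, "/")^2)
  array(0.62 * exp(-q / 2), dim = shape)
}

# Smooth random displacement: per-component white noise smoothed at
# deform_scale, tapered to zero over an 8-voxel border (keeps the inverse
# well-defined and the anatomy inside the grid), rescaled so the maximum
# vector magnitude equals `amplitude`.
.random_smooth_field <- function(shape, amplitude, scale) {
  nd <- length(shape)
  if (amplitude == 0) return(zero_field(shape))
  comps <- matrix(0, nrow = prod(shape), ncol = nd)
  taper <- array(1, dim = shape)
  for (ax in seq_len(nd)) {
    ramp <- pmin(1, (seq_len(shape[ax]) - 1) / 8, (shape[ax] - seq_len(shape[ax])) / 8)
    shape_perm <- c(ax, seq_len(nd)[-ax])
    t_ax <- aperm(array(ramp, dim = dim(taper)[shape_perm]), order(shape_perm))
    taper <- taper * t_ax
  }
  for (ax in seq_len(nd)) {
    w <- array(stats::rnorm(prod(shape)), dim = shape)
    comps[, ax] <- as.vector(.gaussian_smooth_array(w, scale) * taper)
  }
  mag <- sqrt(rowSums(comps^2))
  m <- max(mag)
  if (m > 0) comps <- comps * (amplitude / m)
  displacement_field(array(comps, dim = c(shape, nd)))
}

# Fixed-point inversion of a displacement field: returns u with
# u(Q) = -v(Q + u(Q)), so that (id + v)^{-1}(Q) = Q + u(Q).
.invert_field <- function(field, iters = 30L, tol = 1e-3) {
  shape <- field_shape(field)
  nd <- length(shape)
  grid <- .grid_coords(shape)
  comps <- lapply(seq_len(nd), function(ax) {
    n <- prod(shape)
    array(field$vectors[seq.int((ax - 1L) * n + 1L, ax * n)], dim = shape)
  })
  u <- matrix(0, nrow = prod(shape), ncol = nd)
  for (it in seq_len(iters)) {
    pts <- grid + u
    v_at <- vapply(comps, function(cmp) .sample_linear(cmp, pts),
                   numeric(nrow(grid)))
    delta <- max(abs(-v_at - u))
    u <- -v_at
    if (delta < tol) break
  }
  displacement_field(array(u, dim = c(shape, nd)))
}

#' Generate a multimodal phantom pair with known ground truth
#'
#' The reference ("PET-like") channel is the rendered anatomy plus the
#' lesion blob plus noise.  The floating ("CT-like") channel is the
#' remapped anatomy (without the lesion) warped by the inverse of the
#' ground-truth field, displaced by the inverse of the ground-truth rigid
#' transform, plus independent noise.  Under the pull convention used by
#' [warp_image()], `apply_rigid(floating, truth_rigid)` followed by warping
#' with `truth_field` realigns the floating channel with the reference
#' anatomy, so `truth_field` is exactly the field a deformable registration
#' run after a perfect rigid stage should recover.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `reference` and `floating` (`scalar_image`s),
#'   `truth_field` (`displacement_field`), `truth_rigid`
#'   (`rigid_transform`), `body_mask` (logical array: anatomy body region),
#'   and the `spec`.
#' @examples
#' pair <- generate_phantom_pair(phantom_spec(seed = 42))
#' max(sqrt(rowSums(matrix(pair$truth_field$vectors, ncol = 2)^2)))  # <= 5
#' @export
generate_phantom_pair <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    shape <- spec$shape
    nd <- length(shape)
    anatomy <- .render_anatomy(shape)
    ref_clean <- anatomy
    if (spec$lesion) {
      ref_clean <- pmin(ref_clean + .render_lesion(shape), 0.95)
    }
    truth_field <- .random_smooth_field(shape, spec$deform_amplitude,
                                        spec$deform_scale)
    truth_rigid <- rigid_transform(rotation = spec$rigid_rotation,
                                   translation = spec$rigid_translation,
                                   center = (1 + shape) / 2)
    flo_clean <- .remap_fun(spec$remap)(anatomy)
    if (spec$deform_amplitude > 0) {
      inv <- .invert_field(truth_field)
      flo_def <- warp_image(scalar_image(flo_clean), inv)$data
    } else {
      flo_def <- flo_clean
    }
    if (!.is_identity_transform(truth_rigid)) {
      grid <- .grid_coords(shape)
      ctr <- .transform_center(truth_rigid, shape)
      coords <- .rigid_coords_inv(truth_rigid, grid, ctr)
      flo_rig <- array(.sample_linear(flo_def, coords), dim = shape)
    } else {
      flo_rig <- flo_def
    }
    if (spec$noise_sigma > 0) {
      ref_arr <- ref_clean + array(stats::rnorm(prod(shape), sd = spec$noise_sigma),
                                   dim = shape)
      flo_arr <- flo_rig + array(stats::rnorm(prod(shape), sd = spec$noise_sigma),
                                 dim = shape)
      ref_arr <- pmin(pmax(ref_arr, 0), 1)
      flo_arr <- pmin(pmax(flo_arr, 0), 1)
    } else {
      ref_arr <- ref_clean
      flo_arr <- flo_rig
    }
    list(reference = scalar_image(array(ref_arr, dim = shape)),
         floating = scalar_image(array(flo_arr, dim = shape)),
         truth_field = truth_field,
         truth_rigid = truth_rigid,
         body_mask = anatomy > 0.15,
         spec = spec)
  })
}

#' Endpoint error between displacement fields
#'
#' Per-voxel Euclidean norm of the field difference, summarized (mean,
#' median, max) inside an optional mask.
#'
#' @param estimated,truth `displacement_field`s on the same grid.
#' @param mask optional logical array selecting the voxels to summarize
#'   (e.g. the phantom body mask).
#' @return A list with `mean`, `median`, `max` (voxels) and `n`, the number
#'   of voxels summarized.
#' @export
endpoint_error <- function(estimated, truth, mask = NULL) {
  stopifnot(inherits(estimated, "displacement_field"),
            inherits(truth, "displacement_field"))
  if (!identical(field_shape(estimated), field_shape(truth))) {
    stop("fields must share a grid")
  }
  err <- sqrt(rowSums((.field_matrix(estimated) - .field_matrix(truth))^2))
  if (!is.null(mask)) {
    if (!identical(dim(mask), field_shape(truth))) {
      stop("mask shape must match the field grid")
    }
    err <- err[as.vector(mask)]
  }
  list(mean = mean(err), median = stats::median(err), max = max(err),
       n = length(err))
}
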