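#' Scalar image on a regular grid
#'
#' The unit all registration and evaluation code operates on: a rank-2 or
#' rank-3 array of intensities plus per-axis physical spacing (mm/voxel) and
#' the physical coordinate of the first voxel.
#'
#' @param data numeric array of rank 2 or 3; every dimension must be at
#'   least 2 and all intensities finite.
#' @param spacing positive numeric vector, one entry per axis (mm/voxel).
#' @param origin numeric vector, physical coordinate of voxel `(1, ..., 1)`.
#' @return An object of class `scalar_image` with fields `data`, `spacing`,
#'   `origin`.
#' @examples
#' img <- scalar_image(matrix(runif(64), 8, 8))
#' image_shape(img)
#' @export
scalar_image <- function(data,
                         spacing = rep(1, length(dim(data))),
                         origin = rep(0, length(dim(data)))) {
  if (is.null(dim(data)) || !(length(dim(data)) %in% c(2L, 3L))) {
    stop("`data` must be a rank-2 or rank-3 array")
  }
  if (any(dim(data) < 2L)) stop("every image dimension must be >= 2")
  if (!all(is.finite(data))) stop("image intensities must be finite")
  nd <- length(dim(data))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be ", nd, " strictly positive finite values")
  }
  if (length(origin) != nd || any(!is.finite(origin))) {
    stop("`origin` must be ", nd, " finite values")
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_image")
}

#' @export
print.scalar_image <- function(x, ...) {
  cat("<scalar_image> ", paste(dim(x$data), collapse = " x "),
      " | spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm | intensity range [",
      signif(min(x$data), 4), ", ", signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

.as_image <- function(x) {
  if (inherits(x, "scalar_image")) return(x)
  if (is.array(x) || is.matrix(x)) return(scalar_image(x))
  stop("expected a scalar_image or a numeric array")
}

#' @rdname scalar_image
#' @param img a `scalar_image`.
#' @export
image_shape <- function(img) dim(.as_image(img)$data)

#' Rescale intensities linearly onto [0, 1]
#'
#' Min-max normalization. The demons force normalization `k` and the Parzen
#' intensity lattice are both defined on the unit intensity interval, so the
#' registration entry points normalize their inputs with this function.
#' A constant image maps to all zeros.
#'
#' @param img a `scalar_image` or numeric array.
#' @return A `scalar_image` with intensities in [0, 1].
#' @export
normalize_image <- function(img) {
  img <- .as_image(img)
  rng <- range(img$data)
  d <- if (rng[2] > rng[1]) (img$data - rng[1]) / (rng[2] - rng[1]) else img$data * 0
  scalar_image(d, img$spacing, img$origin)
}

#' Displacement field over a reference grid
#'
#' Stores one offset vector per voxel of the reference image.  The field
#' follows the pull convention: the registered floating image at reference
#' voxel `P` samples the floating image at `P + v(P)`, with components in
#' voxel units.
#'
#' @param vectors numeric array of rank `d + 1` for a `d`-dimensional grid;
#'   the last dimension indexes the vector components and must have extent
#'   `d`.
#' @param level pyramid level the field belongs to (1 = coarsest).
#' @return An object of class `displacement_field` with fields `vectors` and
#'   `level`.
#' @seealso [warp_image()], [zero_field()]
#' @export
displacement_field <- function(vectors, level = 1L) {
  dv <- dim(vectors)
  if (is.null(dv) || !(length(dv) %in% c(3L, 4L))) {
    stop("`vectors` must be an array of rank 3 (2D grid) or 4 (3D grid)")
  }
  nd <- length(dv) - 1L
  if (dv[length(dv)] != nd) {
    stop("last dimension of `vectors` must equal the grid rank (", nd, ")")
  }
  if (!all(is.finite(vectors))) stop("field components must be finite")
  structure(list(vectors = vectors, level = as.integer(level)),
            class = "displacement_field")
}

#' @rdname displacement_field
#' @param shape grid dimensions of the reference image.
#' @export
zero_field <- function(shape, level = 1L) {
  nd <- length(shape)
  displacement_field(array(0, dim = c(shape, nd)), level = level)
}

#' @rdname displacement_field
#' @param field a `displacement_field`.
#' @export
field_shape <- function(field) {
  dv <- dim(field$vectors)
  dv[-length(dv)]
}

# n x d matrix view of the field components, row-per-voxel in column-major
# voxel order.
.field_matrix <- function(field) {
  dv <- dim(field$vectors)
  nd <- length(dv) - 1L
  matrix(field$vectors, ncol = nd)
}

#' @export
print.displacement_field <- function(x, ...) {
  m <- .field_matrix(x)
  mag <- sqrt(rowSums(m^2))
  cat("<displacement_field> grid ", paste(field_shape(x), collapse = " x "),
      " | level ", x$level, " | max |v| ", signif(max(mag), 4), " voxels\n",
      sep = "")
  invisible(x)
}

#' Registration configuration
#'
#' Collects every tunable parameter of the demons + mutual-information
#' pipeline.  All values have literature-conventional defaults and are
#' validated here.
#'
#' @param k demons force normalization factor (> 0) on unit-normalized
#'   intensities.  Beyond normalizing the force, `k` gates the
#'   intensity-difference force out of regions where the two modalities
#'   disagree by much more than `k`; the small default suits multimodal
#'   pairs, monomodal registrations conventionally use `k = 1`.
#' @param sigma standard deviation, in voxels, of the Gaussian regularizer
#'   applied to the summed displacement field after every iteration; 0
#'   disables smoothing.
#' @param alpha per-sample step size of the mutual-information external
#'   force (the per-voxel MI step is `alpha * N * grad MI`, independent of
#'   resolution; see the methods vignette).
#' @param parzen_delta Parzen kernel width (normalized intensity units).
#' @param lattice_size number of lattice points per intensity axis used to
#'   discretize the joint density (>= 8).
#' @param n_levels pyramid depth (>= 1).
#' @param pyramid_factor integer downsampling factor between levels.
#' @param max_iters_per_level iteration cap N per pyramid level.
#' @param mi_stop_threshold minimum MI increment (nats) between successive
#'   iterations required to keep iterating at a level.
#' @param max_step cap, in voxels, on the magnitude of a single per-voxel
#'   update before regularization (stabilization safeguard).
#' @param pad out-of-bounds policy for warping, `"replicate"` or
#'   `"constant"`.
#' @param pad_value padding intensity when `pad = "constant"`.
#' @param refine_sigma,refine_delta regularization width and Parzen width of
#'   the full-resolution refinement pass run after the pyramid (see the
#'   methods vignette); set either to `NULL` to disable the pass.
#' @param refine_alpha MI step of the refinement pass.
#' @param refine_iters iteration cap of the refinement pass.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(k = 0.1,
                                sigma = 2,
                                alpha = 0.3,
                                parzen_delta = 0.05,
                                lattice_size = 64L,
                                n_levels = 2L,
                                pyramid_factor = 2L,
                                max_iters_per_level = 100L,
                                mi_stop_threshold = 1e-5,
                                max_step = 1.25,
                                pad = c("replicate", "constant"),
                                pad_value = 0,
                                refine_sigma = 2,
                                refine_delta = 0.025,
                                refine_alpha = 0.15,
                                refine_iters = 60L) {
  pad <- match.arg(pad)
  refine <- !is.null(refine_sigma) && !is.null(refine_delta)
  if (refine) {
    stopifnot("refine_sigma must be >= 0" = refine_sigma >= 0,
              "refine_delta must be > 0" = refine_delta > 0,
              "refine_alpha must be >= 0" = refine_alpha >= 0,
              "refine_iters must be >= 1" = refine_iters >= 1)
  }
  stopifnot(
    "k must be > 0" = is.numeric(k) && length(k) == 1 && k > 0,
    "sigma must be >= 0" = is.numeric(sigma) && length(sigma) == 1 && sigma >= 0,
    "alpha must be >= 0" = is.numeric(alpha) && length(alpha) == 1 && alpha >= 0,
    "parzen_delta must be > 0" = is.numeric(parzen_delta) && parzen_delta > 0,
    "lattice_size must be >= 8" = lattice_size >= 8,
    "n_levels must be >= 1" = n_levels >= 1,
    "pyramid_factor must be >= 2" = pyramid_factor >= 2,
    "max_iters_per_level must be >= 1" = max_iters_per_level >= 1,
    "mi_stop_threshold must be >= 0" = mi_stop_threshold >= 0,
    "max_step must be > 0" = max_step > 0
  )
  structure(list(k = k, sigma = sigma, alpha = alpha,
                 parzen_delta = parzen_delta,
                 lattice_size = as.integer(lattice_size),
                 n_levels = as.integer(n_levels),
                 pyramid_factor = as.integer(pyramid_factor),
                 max_iters_per_level = as.integer(max_iters_per_level),
                 mi_stop_threshold = mi_stop_threshold,
                 max_step = max_step, pad = pad, pad_value = pad_value,
                 refine_sigma = if (refine) refine_sigma else NULL,
                 refine_delta = if (refine) refine_delta else NULL,
                 refine_alpha = refine_alpha,
                 refine_iters = as.integer(refine_iters)),
            class = "registration_config")
}

#' Warp a floating image through a displacement field
#'
#' Produces the image `o(P) = F(P + v(P))` on the field's grid, sampling the
#' floating image with linear interpolation.  This is the pull convention
#' used throughout: the field lives on the reference grid and fetches
#' floating intensities.
#'
#' @param floating a `scalar_image` (or array) to be resampled.
#' @param field a `displacement_field` whose grid defines the output grid.
#' @param pad `"replicate"` (default) clamps samples to the image edge;
#'   `"constant"` uses `pad_value` outside the floating image domain.
#' @param pad_value padding intensity for `pad = "constant"`.
#' @return A `scalar_image` on the field grid.
#' @examples
#' img <- scalar_image(matrix(1:16, 4, 4))
#' f <- zero_field(c(4, 4))
#' identical(warp_image(img, f)$data, img$data)
#' @export
warp_image <- function(floating, field, pad = c("replicate", "constant"),
                       pad_value = 0) {
  pad <- match.arg(pad)
  floating <- .as_image(floating)
  if (!inherits(field, "displacement_field")) {
    stop("`field` must be a displacement_field")
  }
  shape <- field_shape(field)
  if (length(shape) != length(dim(floating$data))) {
    stop("field rank (", length(shape), ") does not match image rank (",
         length(dim(floating$data)), ")")
  }
  v <- .field_matrix(field)
  if (all(v == 0) && identical(shape, dim(floating$data))) {
    return(floating)  # identity warp is bit-exact
  }
  coords <- .grid_coords(shape) + v
  out <- .sample_linear(floating$data, coords, pad = pad,
                        pad_value = pad_value)
  scalar_image(array(out, dim = shape), floating$spacing, floating$origin)
}

#' Spatial intensity gradient of an image
#'
#' Per-axis finite differences: central in the interior, one-sided at the
#' boundary slices.  Units are intensity per voxel.
#'
#' @param img a `scalar_image` or numeric array.
#' @return A numeric array of dimension `c(image_shape, d)` whose last axis
#'   indexes the gradient components.
#' @export
image_gradient <- function(img) {
  img <- .as_image(img)
  d <- dim(img$data)
  nd <- length(d)
  n <- prod(d)
  out <- array(0, dim = c(d, nd))
  for (ax in seq_len(nd)) {
    out[seq.int((ax - 1L) * n + 1L, ax * n)] <- .diff_along(img$data, ax)
  }
  out
}
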