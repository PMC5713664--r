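#' Rigid transform (rotation + translation about a center)
#'
#' Maps reference-grid coordinates onto floating-image coordinates:
#' `T(P) = R (P - c) + c + t`, with `R` the rotation (one angle in 2D, three
#' intrinsic z-y-x angles in 3D), `c` the rotation center and `t` the
#' translation in voxels.  [apply_rigid()] resamples a floating image through
#' `T` so that the result lives on the reference grid.
#'
#' @param rotation rotation angle(s) in radians: length 1 (2D) or 3 (3D).
#'   Angles are canonicalized to `(-pi, pi]`.
#' @param translation per-axis offset in voxels (length 2 or 3).
#' @param center rotation center in voxel coordinates; defaults to the grid
#'   center when applied through [apply_rigid()] with a `center = NULL`
#'   transform.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = 0,
                            translation = c(0, 0),
                            center = NULL) {
  nd <- length(translation)
  if (!nd %in% c(2L, 3L)) stop("`translation` must have length 2 or 3")
  nrot <- if (nd == 2L) 1L else 3L
  if (length(rotation) != nrot) {
    stop("`rotation` must have length ", nrot, " for a ", nd, "D transform")
  }
  if (!all(is.finite(rotation)) || !all(is.finite(translation))) {
    stop("transform parameters must be finite")
  }
  rotation <- ((rotation + pi) %% (2 * pi)) - pi
  rotation[rotation == -pi] <- pi  # canonical range (-pi, pi]
  if (!is.null(center) && (length(center) != nd || !all(is.finite(center)))) {
    stop("`center` must be ", nd, " finite voxel coordinates")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 center = if (is.null(center)) NULL else as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> rotation ",
      paste(signif(x$rotation * 180 / pi, 4), collapse = ", "),
      " deg | translation (", paste(signif(x$translation, 4), collapse = ", "),
      ") voxels\n", sep = "")
  invisible(x)
}

.is_identity_transform <- function(t) {
  all(t$rotation == 0) && all(t$translation == 0)
}

.rotation_matrix <- function(rotation, nd) {
  if (nd == 2L) {
    a <- rotation[1]
    matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  } else {
    cz <- cos(rotation[3]); sz <- sin(rotation[3])
    cy <- cos(rotation[2]); sy <- sin(rotation[2])
    cx <- cos(rotation[1]); sx <- sin(rotation[1])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Rz %*% Ry %*% Rx
  }
}

# Transform coordinates (rows) through t; inverse = TRUE applies T^{-1}.
.rigid_coords <- function(tf, coords, center) {
  nd <- ncol(coords)
  R <- .rotation_matrix(tf$rotation, nd)
  ctr <- matrix(center, nrow = nrow(coords), ncol = nd, byrow = TRUE)
  tr <- matrix(tf$translation, nrow = nrow(coords), ncol = nd, byrow = TRUE)
  (coords - ctr) %*% t(R) + ctr + tr
}

.rigid_coords_inv <- function(tf, coords, center) {
  nd <- ncol(coords)
  R <- .rotation_matrix(tf$rotation, nd)
  ctr <- matrix(center, nrow = nrow(coords), ncol = nd, byrow = TRUE)
  tr <- matrix(tf$translation, nrow = nrow(coords), ncol = nd, byrow = TRUE)
  (coords - ctr - tr) %*% R + ctr
}

.transform_center <- function(t, shape) {
  if (!is.null(t$center)) t$center else (1 + shape) / 2
}

#' Resample an image through a rigid transform
#'
#' Returns `o(P) = F(T(P))` with linear interpolation.  An exactly-identity
#' transform returns the input unchanged (bit-exact).
#'
#' @param floating a `scalar_image` to resample.
#' @param t a [rigid_transform()].
#' @param pad,pad_value out-of-bounds policy (edge replication by default).
#' @return The resampled `scalar_image`.
#' @export
apply_rigid <- function(floating, t, pad = c("replicate", "constant"),
                        pad_value = 0) {
  pad <- match.arg(pad)
  floating <- .as_image(floating)
  stopifnot(inherits(t, "rigid_transform"))
  if (.is_identity_transform(t)) return(floating)
  shape <- dim(floating$data)
  ctr <- .transform_center(t, shape)
  coords <- .rigid_coords(t, .grid_coords(shape), ctr)
  out <- .sample_linear(floating$data, coords, pad = pad, pad_value = pad_value)
  scalar_image(array(out, dim = shape), floating$spacing, floating$origin)
}

#' Inverse of a rigid transform
#'
#' @param tf a [rigid_transform()].
#' @param shape grid shape used to resolve a `NULL` center.
#' @return The `rigid_transform` `t^{-1}` (2D). For 3D transforms with
#'   nonzero rotation the inverse is not representable in the same intrinsic
#'   angle convention in general; only the 2D and rotation-free 3D cases are
#'   supported.
#' @export
rigid_inverse <- function(tf, shape = NULL) {
  stopifnot(inherits(tf, "rigid_transform"))
  nd <- length(tf$translation)
  if (nd == 3L && any(tf$rotation != 0)) {
    stop("3D rigid inverse is only supported for rotation-free transforms")
  }
  R <- .rotation_matrix(tf$rotation, nd)
  rigid_transform(rotation = -tf$rotation,
                  translation = as.vector(-t(R) %*% tf$translation),
                  center = tf$center)
}

# intensity centroid in voxel coordinates
.intensity_centroid <- function(arr) {
  g <- .grid_coords(dim(arr))
  w <- as.vector(arr)
  s <- sum(w)
  if (s <= 0) return(colMeans(g))
  as.vector(crossprod(g, w)) / s
}

#' Rigid pre-registration by mutual-information maximization
#'
#' Searches rotation + translation maximizing the Parzen-window mutual
#' information between the reference image and the rigidly resampled
#' floating image, using derivative-free Nelder-Mead simplex restarts from
#' the identity and from the intensity-centroid offset.  If no candidate
#' beats the identity's MI, the identity transform is returned with a
#' warning flag (attribute `converged = FALSE`).
#'
#' @param reference,floating `scalar_image`s (any intensity range; they are
#'   normalized internally).
#' @param cfg a [registration_config()]; `parzen_delta` is reused, the
#'   density lattice for the rigid objective is fixed at 32 points per axis
#'   for speed.
#' @param max_eval Nelder-Mead iteration cap per start.
#' @return A `rigid_transform` with attributes `mi_before`, `mi_after` and
#'   `converged`.
#' @export
rigid_register <- function(reference, floating, cfg = registration_config(),
                           max_eval = 300L) {
  r <- normalize_image(.as_image(reference))
  f <- normalize_image(.as_image(floating))
  shape <- dim(r$data)
  nd <- length(shape)
  ctr <- (1 + shape) / 2
  nrot <- if (nd == 2L) 1L else 3L
  parscale <- c(rep(0.05, nrot), rep(2, nd))

  make_objective <- function(r_img, f_img, scale) {
    # `scale` converts full-resolution parameters to this level's voxels
    sh <- dim(r_img$data)
    grid <- .grid_coords(sh)
    c_l <- (1 + sh) / 2
    rv <- as.vector(r_img$data)
    function(par) {
      tr <- par[nrot + seq_len(nd)] / scale
      tf <- rigid_transform(par[seq_len(nrot)], tr, center = c_l)
      fv <- .sample_linear(f_img$data, .rigid_coords(tf, grid, c_l))
      -mutual_information(.joint_density_core(rv, fv, cfg$parzen_delta, 32L))
    }
  }

  # coarse level (about 32 voxels per axis) for the global multi-start search
  depth <- max(1L, 1L + as.integer(floor(log2(min(shape) / 32))))
  pyr_r <- suppressWarnings(build_pyramid(r, depth, 2L))
  pyr_f <- suppressWarnings(build_pyramid(f, depth, 2L))
  coarse_scale <- 2^(pyr_r$n_levels - 1L)
  neg_coarse <- make_objective(pyr_r$levels[[1L]], pyr_f$levels[[1L]],
                               coarse_scale)
  neg_fine <- make_objective(r, f, 1)

  centroid_shift <- .intensity_centroid(f$data) - .intensity_centroid(r$data)
  rot_starts <- if (nd == 2L) {
    lapply(c(0, -5, 5, -10, 10) * pi / 180, function(a) a)
  } else {
    list(rep(0, 3))
  }
  trans_starts <- list(rep(0, nd), centroid_shift)
  id_par <- rep(0, nrot + nd)
  best_par <- id_par
  best_val <- neg_coarse(id_par)
  for (rs in rot_starts) {
    for (ts in trans_starts) {
      s <- c(rs, ts)
      fit <- tryCatch(
        stats::optim(s, neg_coarse, method = "Nelder-Mead",
                     control = list(maxit = max_eval, reltol = 1e-9,
                                    parscale = parscale)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$value < best_val) {
        best_par <- fit$par
        best_val <- fit$value
      }
    }
  }
  # full-resolution refinement from the coarse optimum
  mi_identity <- -neg_fine(id_par)
  best_mi <- -neg_fine(best_par)
  fit <- tryCatch(
    stats::optim(best_par, neg_fine, method = "Nelder-Mead",
                 control = list(maxit = max_eval, reltol = 1e-9,
                                parscale = parscale)),
    error = function(e) NULL)
  if (!is.null(fit) && -fit$value > best_mi) {
    best_par <- fit$par
    best_mi <- -fit$value
  }
  converged <- best_mi >= mi_identity
  if (!converged) {
    warning("rigid registration did not improve on the identity transform")
    best_par <- id_par
    best_mi <- mi_identity
  }
  out <- .par_to_transform(best_par, nd, ctr)
  attr(out, "mi_before") <- mi_identity
  attr(out, "mi_after") <- best_mi
  attr(out, "converged") <- converged
  out
}

.par_to_transform <- function(par, nd, center) {
  nrot <- if (nd == 2L) 1L else 3L
  rigid_transform(rotation = par[seq_len(nrot)],
                  translation = par[nrot + seq_len(nd)],
                  center = center)
}
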