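#' One demons iteration augmented with the mutual-information force
#'
#' Performs `G_sigma * ( v^n + demons force + alpha * grad MI(v^n) )`: the
#' classic optical-flow update body plus `alpha` times the gradient of the
#' Parzen-window mutual information, followed by component-wise Gaussian
#' regularization of the summed field.  With `alpha = 0` the MI machinery is
#' skipped entirely and the result is bit-identical to [demons_iteration()].
#'
#' @inheritParams demons_iteration
#' @return The updated `displacement_field`, with attribute `mi_value`
#'   carrying the mutual information of the pre-update configuration when
#'   the MI force was evaluated.
#' @export
gmi_demons_iteration <- function(field, r_img, f_img,
                                 cfg = registration_config()) {
  st <- .reg_step(field, r_img, f_img, cfg, alpha = cfg$alpha)
  out <- st$field
  attr(out, "mi_value") <- st$mi_value
  out
}

#' Multiresolution image pyramid
#'
#' Builds a coarse-to-fine pyramid by repeated anti-alias Gaussian smoothing
#' (sigma = 0.5 * factor voxels) and subsampling by `factor`.  The number of
#' levels is automatically reduced (with a warning) so the coarsest level
#' keeps at least 8 voxels per axis.  Spacing metadata is scaled per level.
#'
#' @param img a `scalar_image`.
#' @param n_levels requested pyramid depth (>= 1).
#' @param factor integer downsampling factor between adjacent levels.
#' @return An object of class `image_pyramid`: list with `levels` (ordered
#'   coarsest to finest) and `factor`.
#' @export
build_pyramid <- function(img, n_levels = 3L, factor = 2L) {
  img <- .as_image(img)
  stopifnot(n_levels >= 1, factor >= 2)
  shape <- dim(img$data)
  max_levels <- 1L
  while (all(ceiling(shape / factor^max_levels) >= 8) &&
         max_levels < n_levels) {
    max_levels <- max_levels + 1L
  }
  if (max_levels < n_levels) {
    warning("pyramid depth reduced from ", n_levels, " to ", max_levels,
            " so the coarsest level keeps >= 8 voxels per axis")
    n_levels <- max_levels
  }
  levels <- vector("list", n_levels)
  levels[[n_levels]] <- img
  cur <- img
  if (n_levels > 1L) {
    for (l in seq.int(n_levels - 1L, 1L)) {
      sm <- .gaussian_smooth_array(cur$data, 0.5 * factor)
      idx <- lapply(dim(sm), function(m) seq.int(1L, m, by = factor))
      sub <- do.call(`[`, c(list(sm), idx, list(drop = FALSE)))
      cur <- scalar_image(sub, cur$spacing * factor, cur$origin)
      levels[[l]] <- cur
    }
  }
  structure(list(levels = levels, factor = as.integer(factor),
                 n_levels = n_levels),
            class = "image_pyramid")
}

#' @export
print.image_pyramid <- function(x, ...) {
  cat("<image_pyramid> ", x$n_levels, " level(s), factor ", x$factor, ":\n",
      sep = "")
  for (l in seq_along(x$levels)) {
    cat("  level ", l, ": ", paste(dim(x$levels[[l]]$data), collapse = " x "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Upsample a displacement field to the next pyramid level
#'
#' Linearly interpolates every component onto the finer grid and multiplies
#' the components by `factor` (offsets are stored in voxel units, and one
#' coarse voxel spans `factor` fine voxels).
#'
#' @param field `displacement_field` at the coarse level.
#' @param target_shape grid dimensions of the finer level; must satisfy
#'   `ceiling(target_shape / factor) == field grid shape`.
#' @param factor integer refinement factor.
#' @return The upsampled `displacement_field` (level incremented).
#' @export
upsample_field <- function(field, target_shape, factor = 2L) {
  stopifnot(inherits(field, "displacement_field"))
  shape <- field_shape(field)
  nd <- length(shape)
  if (length(target_shape) != nd ||
      !all(ceiling(target_shape / factor) == shape)) {
    stop("target shape ", paste(target_shape, collapse = "x"),
         " is not a factor-", factor, " refinement of ",
         paste(shape, collapse = "x"))
  }
  # fine index p maps to coarse coordinate (p - 1) / factor + 1, matching the
  # subsampling grid seq(1, ., by = factor) used in build_pyramid
  fine <- .grid_coords(target_shape)
  coarse_coords <- (fine - 1) / factor + 1
  n <- prod(target_shape)
  out <- matrix(0, nrow = n, ncol = nd)
  vdim <- dim(field$vectors)
  nsrc <- prod(shape)
  for (ax in seq_len(nd)) {
    comp <- array(field$vectors[seq.int((ax - 1L) * nsrc + 1L, ax * nsrc)],
                  dim = shape)
    out[, ax] <- .sample_linear(comp, coarse_coords) * factor
  }
  displacement_field(array(out, dim = c(target_shape, nd)),
                     level = field$level + 1L)
}

# One pyramid-level (or refinement) iteration loop with the MI-increment
# stopping rule: the level ends when the increment between successive MI
# evaluations falls below the threshold (the stopping iteration's update is
# not applied) or at the iteration cap.  Monotone acceptance: a stage whose
# last MI value falls below its starting value is reverted to its starting
# field (it made no net progress; in particular, already-aligned inputs pass
# through unchanged instead of accumulating discretization-noise updates).
.run_level <- function(field, r_l, f_l, cfg, max_iters) {
  grad_r <- image_gradient(r_l)
  field0 <- field
  trace <- numeric(0)
  converged <- FALSE
  for (n in seq_len(max_iters)) {
    st <- .reg_step(field, r_l, f_l, cfg, grad_r = grad_r,
                    alpha = cfg$alpha, need_mi_value = TRUE)
    trace <- c(trace, st$mi_value)
    if (n >= 2 && (trace[n] - trace[n - 1]) < cfg$mi_stop_threshold) {
      converged <- TRUE
      break
    }
    field <- st$field
  }
  if (length(trace) >= 2 && trace[length(trace)] < trace[1]) {
    field <- field0
    trace <- trace[1]
    converged <- TRUE
  }
  list(field = field, trace = trace, iterations = length(trace),
       converged = converged)
}

#' Full multiresolution registration
#'
#' Runs the complete pipeline: (1) rigid mutual-information pre-alignment,
#' (2) pyramid construction for both images with a zero-initialized field at
#' the coarsest level, (3) iterative demons + MI-force updates per level,
#' (4) a level terminates when the MI increment between successive
#' iterations falls below `cfg$mi_stop_threshold` or after
#' `cfg$max_iters_per_level` iterations, (5) the field is upsampled to seed
#' the next finer level, (6) the final full-resolution field is returned
#' together with the rigid transform and per-level MI traces.
#'
#' Both inputs are min-max normalized internally; apply the result to the
#' original floating image with [apply_registration()].
#'
#' @param reference,floating `scalar_image`s (or arrays) of equal rank.
#' @param cfg a [registration_config()].
#' @param skip_global skip the rigid stage (identity transform recorded).
#' @param verbose print per-level progress to stderr.
#' @return An object of class `registration_result`: list with `field`
#'   (final full-resolution `displacement_field`), `global_transform`,
#'   `mi_trace` (list of per-iteration MI values, one entry per pyramid
#'   level plus one for the refinement pass when enabled),
#'   `iterations_used`, `converged` (per-stage logical), and `config`.
#' @export
register <- function(reference, floating, cfg = registration_config(),
                     skip_global = FALSE, verbose = FALSE) {
  r <- normalize_image(.as_image(reference))
  f <- normalize_image(.as_image(floating))
  if (!identical(length(dim(r$data)), length(dim(f$data)))) {
    stop("reference and floating images must have the same rank")
  }
  if (skip_global) {
    tf <- rigid_transform(rotation = rep(0, if (length(dim(r$data)) == 2) 1 else 3),
                          translation = rep(0, length(dim(r$data))))
  } else {
    tf <- rigid_register(r, f, cfg)
  }
  f_aligned <- apply_rigid(f, tf, pad = cfg$pad, pad_value = cfg$pad_value)
  pyr_r <- build_pyramid(r, cfg$n_levels, cfg$pyramid_factor)
  suppressWarnings(pyr_f <- build_pyramid(f_aligned, cfg$n_levels,
                                          cfg$pyramid_factor))
  n_levels <- pyr_r$n_levels
  refine <- !is.null(cfg$refine_sigma)
  n_stages <- n_levels + as.integer(refine)
  mi_trace <- vector("list", n_stages)
  iters <- integer(n_stages)
  converged <- logical(n_stages)
  field <- NULL
  for (l in seq_len(n_stages)) {
    refining <- l > n_levels
    r_l <- pyr_r$levels[[min(l, n_levels)]]
    f_l <- pyr_f$levels[[min(l, n_levels)]]
    shape_l <- dim(r_l$data)
    if (is.null(field)) {
      field <- zero_field(shape_l, level = l)
    } else if (!refining) {
      field <- upsample_field(field, shape_l, cfg$pyramid_factor)
    }
    level_cfg <- cfg
    max_it <- cfg$max_iters_per_level
    if (refining) {
      # full-resolution refinement pass: tighter regularization and Parzen
      # width sharpen the MI equilibrium around the transported solution
      level_cfg$sigma <- cfg$refine_sigma
      level_cfg$parzen_delta <- cfg$refine_delta
      level_cfg$alpha <- cfg$refine_alpha
      max_it <- cfg$refine_iters
    }
    st_level <- .run_level(field, r_l, f_l, level_cfg, max_it)
    field <- st_level$field
    iters[l] <- st_level$iterations
    converged[l] <- st_level$converged
    mi_trace[[l]] <- st_level$trace
    if (verbose) {
      tr <- st_level$trace
      message(sprintf("%s (%s): %d iteration(s), MI %.5f -> %.5f",
                      if (refining) "refinement" else paste0("level ", l),
                      paste(shape_l, collapse = "x"),
                      iters[l], tr[1], tr[length(tr)]))
    }
  }
  structure(list(field = field, global_transform = tf, mi_trace = mi_trace,
                 iterations_used = iters, converged = converged,
                 config = cfg),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("<registration_result>\n  global: ")
  print(x$global_transform)
  n_levels <- x$config$n_levels
  for (l in seq_along(x$mi_trace)) {
    tr <- x$mi_trace[[l]]
    cat("  ", if (l > n_levels) "refinement" else paste0("level ", l), ": ",
        x$iterations_used[l], " iter, MI ",
        signif(tr[1], 5), " -> ", signif(tr[length(tr)], 5),
        if (x$converged[l]) " (converged)" else " (iteration cap)", "\n",
        sep = "")
  }
  invisible(x)
}

#' Apply a registration result to an image
#'
#' Resamples the floating image through the global rigid transform and then
#' through the deformable field, reproducing the mapping estimated by
#' [register()] on arbitrary (e.g. unnormalized) intensities.
#'
#' @param result a `registration_result`.
#' @param floating the floating `scalar_image` to resample.
#' @param pad,pad_value out-of-bounds policy.
#' @return The registered `scalar_image` on the reference grid.
#' @export
apply_registration <- function(result, floating,
                               pad = c("replicate", "constant"),
                               pad_value = 0) {
  pad <- match.arg(pad)
  stopifnot(inherits(result, "registration_result"))
  aligned <- apply_rigid(.as_image(floating), result$global_transform,
                         pad = pad, pad_value = pad_value)
  warp_image(aligned, result$field, pad = pad, pad_value = pad_value)
}

#' Total displacement of a rigid + deformable registration
#'
#' Composes the deformable field with the rigid transform into a single
#' displacement field `u(P) = T(P + v(P)) - P` mapping reference voxels all
#' the way into the original floating image frame.  Useful for endpoint-error
#' evaluation against a ground-truth composition.
#'
#' @param field a `displacement_field` estimated after rigid alignment.
#' @param tf the rigid `rigid_transform` applied before the deformable stage.
#' @return A `displacement_field` of the composed mapping.
#' @export
compose_rigid_field <- function(field, tf) {
  stopifnot(inherits(field, "displacement_field"),
            inherits(tf, "rigid_transform"))
  shape <- field_shape(field)
  grid <- .grid_coords(shape)
  pts <- grid + .field_matrix(field)
  ctr <- .transform_center(tf, shape)
  total <- .rigid_coords(tf, pts, ctr) - grid
  displacement_field(array(total, dim = dim(field$vectors)),
                     level = field$level)
}
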