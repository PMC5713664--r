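# Hausdorff-family point-set metrics and feature-point extraction used to
# evaluate registrations.  Point sets are plain numeric matrices, one row
# per point, in voxel units (multiply by spacing for mm).

.as_point_set <- function(x, what = "point set") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) stop(what, " is empty")
  if (!all(is.finite(x))) stop(what, " contains non-finite coordinates")
  x
}

# Minimum distance from every row of A to the set B.  Squared distances are
# accumulated per dimension from outer differences: numerically stable (no
# a^2 + b^2 - 2ab cancellation) and bit-identical to a direct double loop.
.min_dists <- function(A, B) {
  d2 <- 0
  for (ax in seq_len(ncol(A))) {
    d2 <- d2 + outer(A[, ax], B[, ax], "-")^2
  }
  d2 <- matrix(d2, nrow = nrow(A))
  sqrt(apply(d2, 1, min))
}

#' Hausdorff-family distances between point sets
#'
#' `directed_hausdorff(A, B)` is `max_{a in A} min_{b in B} ||a - b||`;
#' `hausdorff` symmetrizes by the outer max; `modified_hausdorff` replaces
#' the outer max of the directed distance by the mean over `A`
#' (`(1/N_A) sum_a min_b ||a - b||`) and reports the symmetrized
#' `max(directed(A,B), directed(B,A))`, the robust variant of Dubuisson and
#' Jain.  The directed values are attached as attribute `directed`.
#'
#' @param A,B point sets: numeric matrices (or data frames) with one point
#'   per row and matching dimensionality; both must be non-empty.
#' @param spacing optional per-axis physical spacing; when given, distances
#'   are in mm instead of voxels.
#' @return A single non-negative distance.
#' @examples
#' A <- rbind(c(0, 0), c(3, 0)); B <- rbind(c(0, 0))
#' directed_hausdorff(A, B)  # 3
#' directed_hausdorff(B, A)  # 0
#' modified_hausdorff(A, B)  # 1.5
#' @export
directed_hausdorff <- function(A, B, spacing = NULL) {
  A <- .as_point_set(A, "A"); B <- .as_point_set(B, "B")
  if (ncol(A) != ncol(B)) stop("point sets must share dimensionality")
  if (!is.null(spacing)) {
    A <- sweep(A, 2, spacing, "*"); B <- sweep(B, 2, spacing, "*")
  }
  max(.min_dists(A, B))
}

#' @rdname directed_hausdorff
#' @export
hausdorff <- function(A, B, spacing = NULL) {
  max(directed_hausdorff(A, B, spacing), directed_hausdorff(B, A, spacing))
}

#' @rdname directed_hausdorff
#' @export
modified_hausdorff <- function(A, B, spacing = NULL) {
  A <- .as_point_set(A, "A"); B <- .as_point_set(B, "B")
  if (ncol(A) != ncol(B)) stop("point sets must share dimensionality")
  if (!is.null(spacing)) {
    A <- sweep(A, 2, spacing, "*"); B <- sweep(B, 2, spacing, "*")
  }
  ab <- mean(.min_dists(A, B))
  ba <- mean(.min_dists(B, A))
  structure(max(ab, ba), directed = c(ab = ab, ba = ba))
}

# logical neighbor-shift: TRUE where the face-neighbor along axis/offset
# exists and is TRUE; outside voxels count as FALSE.
.shift_mask <- function(mask, ax, by) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  idx_to <- lapply(d, seq_len)
  idx_from <- idx_to
  m <- d[ax]
  if (by > 0) {
    idx_to[[ax]] <- seq_len(m - by); idx_from[[ax]] <- seq_len(m - by) + by
  } else {
    idx_to[[ax]] <- seq_len(m + by) - by; idx_from[[ax]] <- seq_len(m + by)
  }
  do.call(`[<-`, c(list(out), idx_to,
                   list(do.call(`[`, c(list(mask), idx_from, list(drop = FALSE))))))
}

.largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  if (length(dim(mask)) == 2L) {
    lab <- EBImage::bwlabel(mask)
    tab <- tabulate(lab[lab > 0])
    return(array(lab == which.max(tab), dim = dim(mask)))
  }
  # 3D: frontier flood fill with 6-connectivity
  remaining <- mask
  best <- NULL
  best_n <- 0L
  nd <- length(dim(mask))
  while (any(remaining)) {
    seed <- array(FALSE, dim = dim(mask))
    seed[which(remaining)[1L]] <- TRUE
    repeat {
      grown <- seed
      for (ax in seq_len(nd)) {
        grown <- grown | .shift_mask(seed, ax, 1L) | .shift_mask(seed, ax, -1L)
      }
      grown <- grown & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    n <- sum(seed)
    if (n > best_n) {
      best <- seed
      best_n <- n
    }
    remaining <- remaining & !seed
  }
  best
}

.boundary_voxels <- function(mask) {
  nd <- length(dim(mask))
  interior <- mask
  for (ax in seq_len(nd)) {
    interior <- interior & .shift_mask(mask, ax, 1L) & .shift_mask(mask, ax, -1L)
  }
  mask & !interior
}

#' Extract feature points from an image
#'
#' Two extractors for Hausdorff-family evaluation:
#' * `"isocontour"`: threshold the (normalized) image, keep the largest
#'   connected component of the resulting body mask, and return its boundary
#'   voxels (voxels of the mask with at least one face-neighbor outside it).
#' * `"edge"`: voxels whose normalized gradient magnitude exceeds the
#'   threshold and is maximal within the 3x3(x3) neighborhood.
#'
#' @param img a `scalar_image` or array.
#' @param method `"isocontour"` (default) or `"edge"`.
#' @param threshold threshold on normalized intensity (isocontour) or
#'   normalized gradient magnitude (edge); `NULL` uses Otsu's threshold of
#'   the normalized image.
#' @return A numeric matrix of voxel coordinates, one point per row.
#' @export
extract_feature_points <- function(img, method = c("isocontour", "edge"),
                                   threshold = NULL) {
  method <- match.arg(method)
  img <- normalize_image(.as_image(img))
  x <- img$data
  d <- dim(x)
  if (method == "isocontour") {
    if (is.null(threshold)) {
      threshold <- EBImage::otsu(matrix(as.vector(x), nrow = d[1]),
                                 range = c(0, 1))
    }
    mask <- x >= threshold
    if (!any(mask)) {
      stop("no voxel reaches the isocontour threshold (", signif(threshold, 4),
           "); try a lower `threshold`")
    }
    mask <- .largest_component(mask)
    pts <- which(.boundary_voxels(mask), arr.ind = TRUE)
  } else {
    g <- image_gradient(img)
    gm <- sqrt(apply(g^2, seq_along(d), sum))
    if (max(gm) > 0) gm <- gm / max(gm)
    if (is.null(threshold)) {
      threshold <- EBImage::otsu(matrix(as.vector(gm), nrow = d[1]),
                                 range = c(0, 1))
    }
    nb_max <- gm
    for (ax in seq_along(d)) {
      for (by in c(-1L, 1L)) {
        sh <- .shift_numeric(gm, ax, by)
        nb_max <- pmax(nb_max, sh)
      }
    }
    keep <- gm >= threshold & gm >= nb_max
    if (!any(keep)) {
      stop("no gradient maxima above threshold (", signif(threshold, 4),
           "); try a lower `threshold`")
    }
    pts <- which(array(keep, dim = d), arr.ind = TRUE)
  }
  pts <- unname(as.matrix(pts))
  storage.mode(pts) <- "double"
  pts
}

# numeric shift along axis; out-of-range positions filled with -Inf so they
# never win a neighborhood maximum
.shift_numeric <- function(arr, ax, by) {
  d <- dim(arr)
  out <- array(-Inf, dim = d)
  idx_to <- lapply(d, seq_len)
  idx_from <- idx_to
  m <- d[ax]
  if (by > 0) {
    idx_to[[ax]] <- seq_len(m - by); idx_from[[ax]] <- seq_len(m - by) + by
  } else {
    idx_to[[ax]] <- seq_len(m + by) - by; idx_from[[ax]] <- seq_len(m + by)
  }
  do.call(`[<-`, c(list(out), idx_to,
                   list(do.call(`[`, c(list(arr), idx_from, list(drop = FALSE))))))
}

#' Modified Hausdorff distance between two images
#'
#' Extracts feature points from both images (each at its own Otsu threshold
#' unless `threshold` is given) and returns their modified Hausdorff
#' distance.  The staging metric used by [run_pipeline()].
#'
#' @param reference,warped images on a common grid.
#' @param method,threshold forwarded to [extract_feature_points()].
#' @param spacing optional spacing for mm output.
#' @return The modified Hausdorff distance (attribute `directed` carries the
#'   two directed means).
#' @export
image_mhd <- function(reference, warped, method = "isocontour",
                      threshold = NULL, spacing = NULL) {
  A <- extract_feature_points(reference, method, threshold)
  B <- extract_feature_points(warped, method, threshold)
  modified_hausdorff(A, B, spacing = spacing)
}
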