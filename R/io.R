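# Readers and writers: NIfTI (.nii / .nii.gz) through RNifti, plus a
# portable raw little-endian float32 array with a JSON sidecar
# ({shape, spacing, origin}).  The portable format is addressed by its .json
# path; the binary payload lives next to it with extension .bin.

.is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)
.is_portable_path <- function(path) grepl("\\.json$", path)
.portable_bin <- function(path) sub("\\.json$", ".bin", path)

.write_nifti_array <- function(arr, spacing, origin, path) {
  im <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(im) <- spacing
  aff <- diag(c(spacing, rep(1, 4 - nd)))
  aff[seq_len(nd), 4] <- origin
  im <- RNifti::`qform<-`(im, structure(aff, code = 2L))
  RNifti::writeNifti(im, path)
}

.read_nifti_array <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- array(as.numeric(im), dim = dim(im))  # drop NIfTI attributes
  nd <- length(dim(arr))
  spacing <- RNifti::pixdim(im)[seq_len(nd)]
  aff <- tryCatch(RNifti::xform(im), error = function(e) NULL)
  origin <- if (!is.null(aff)) aff[seq_len(nd), 4] else rep(0, nd)
  list(data = arr, spacing = as.numeric(spacing), origin = as.numeric(origin))
}

.write_portable_array <- function(arr, spacing, origin, path, kind = "image") {
  header <- list(format = "gmidemons-raw", kind = kind, dtype = "float32",
                 endian = "little", shape = dim(arr),
                 spacing = spacing, origin = origin)
  jsonlite::write_json(header, path, auto_unbox = TRUE, digits = NA)
  con <- file(.portable_bin(path), "wb")
  on.exit(close(con))
  writeBin(as.numeric(arr), con, size = 4L, endian = "little")
}

.read_portable_array <- function(path, expected_kind = NULL) {
  header <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                     error = function(e) {
                       stop("cannot parse header '", path, "': ",
                            conditionMessage(e))
                     })
  if (!identical(header$format, "gmidemons-raw")) {
    stop("'", path, "' is not a portable raw-array header")
  }
  if (!is.null(expected_kind) && !identical(header$kind, expected_kind)) {
    stop("'", path, "' holds a ", header$kind, ", expected a ", expected_kind)
  }
  bin <- .portable_bin(path)
  if (!file.exists(bin)) stop("missing data file '", bin, "'")
  n <- prod(header$shape)
  con <- file(bin, "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  if (length(vals) != n) {
    stop("'", bin, "' is truncated: expected ", n, " float32 values, found ",
         length(vals))
  }
  list(data = array(vals, dim = header$shape),
       spacing = as.numeric(header$spacing),
       origin = as.numeric(header$origin))
}

#' Read / write scalar images
#'
#' Supported formats, chosen by extension: NIfTI (`.nii`, `.nii.gz`) and the
#' portable raw format (a `.json` header next to a `.bin` little-endian
#' float32 payload).  Data, per-axis spacing and origin round-trip at
#' float32 precision.
#'
#' @param path file path (`.nii`, `.nii.gz`, or `.json`).
#' @return `read_image`: a `scalar_image`. `write_image`: the path,
#'   invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  raw <- if (.is_nifti_path(path)) {
    tryCatch(.read_nifti_array(path),
             error = function(e) stop("cannot read NIfTI '", path, "': ",
                                      conditionMessage(e)))
  } else if (.is_portable_path(path)) {
    .read_portable_array(path, expected_kind = "image")
  } else {
    stop("unknown image format for '", path,
         "' (expected .nii, .nii.gz or .json)")
  }
  scalar_image(raw$data, raw$spacing, raw$origin)
}

#' @rdname read_image
#' @param img a `scalar_image` (or array).
#' @export
write_image <- function(img, path) {
  img <- .as_image(img)
  if (.is_nifti_path(path)) {
    .write_nifti_array(img$data, img$spacing, img$origin, path)
  } else if (.is_portable_path(path)) {
    .write_portable_array(img$data, img$spacing, img$origin, path, "image")
  } else {
    stop("unknown image format for '", path, "'")
  }
  invisible(path)
}

#' Read / write displacement fields
#'
#' A `d`-dimensional field is stored as a rank-`d+1` volume whose last axis
#' holds the vector components (voxel units), either as NIfTI or in the
#' portable raw format.
#'
#' @param path file path (`.nii`, `.nii.gz`, or `.json`).
#' @param level pyramid level to record on the loaded field.
#' @return `read_field`: a `displacement_field`; `write_field`: the path,
#'   invisibly.
#' @export
read_field <- function(path, level = 1L) {
  raw <- if (.is_nifti_path(path)) {
    .read_nifti_array(path)
  } else if (.is_portable_path(path)) {
    .read_portable_array(path, expected_kind = "field")
  } else {
    stop("unknown field format for '", path, "'")
  }
  displacement_field(raw$data, level = level)
}

#' @rdname read_field
#' @param field a `displacement_field`.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  nd <- length(field_shape(field))
  if (.is_nifti_path(path)) {
    .write_nifti_array(field$vectors, rep(1, nd + 1), rep(0, nd + 1), path)
  } else if (.is_portable_path(path)) {
    .write_portable_array(field$vectors, rep(1, nd), rep(0, nd), path, "field")
  } else {
    stop("unknown field format for '", path, "'")
  }
  invisible(path)
}

#' Read / write point sets
#'
#' Plain-text coordinate tables: comma- or whitespace-separated, one point
#' per row, with or without a header line.
#'
#' @param path file path.
#' @return `read_point_set`: a numeric matrix with one point per row.
#' @export
read_point_set <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = header, sep = sep,
                          strip.white = TRUE)
  .as_point_set(df, paste0("point set '", path, "'"))
}

#' @rdname read_point_set
#' @param points numeric matrix of coordinates, one point per row.
#' @export
write_point_set <- function(points, path) {
  points <- .as_point_set(points)
  colnames(points) <- c("x", "y", "z")[seq_len(ncol(points))]
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

#' Read / write rigid transforms as JSON
#'
#' @param path JSON file path.
#' @return `read_rigid_transform`: a `rigid_transform`.
#' @export
read_rigid_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(rotation = x$rotation, translation = x$translation,
                  center = x$center)
}

#' @rdname read_rigid_transform
#' @param tf a `rigid_transform`.
#' @export
write_rigid_transform <- function(tf, path) {
  stopifnot(inherits(tf, "rigid_transform"))
  jsonlite::write_json(list(rotation = tf$rotation,
                            translation = tf$translation,
                            center = tf$center),
                       path, auto_unbox = FALSE, digits = NA, null = "null")
  invisible(path)
}

#' Read a registration configuration from JSON
#'
#' The JSON object may set any subset of the [registration_config()]
#' arguments; unset parameters keep their defaults.
#'
#' @param path JSON file path.
#' @return A `registration_config`.
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(registration_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(registration_config, x)
}
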