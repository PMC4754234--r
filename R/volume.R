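#' 3-D SPECT volume
#'
#' Lightweight container for a 3-D scalar brain volume: a numeric array plus
#' voxel spacing (mm), a voxel-to-world affine and a subject identifier.
#' The affine maps homogeneous 0-based voxel indices `(i, j, k, 1)` to world
#' coordinates in mm. By default the world origin is placed at the volume
#' centre, so rigid rotations during registration pivot about the head.
#'
#' @param data 3-D numeric array (counts or normalized intensity).
#' @param spacing Numeric length-3 vector of strictly positive voxel sizes, mm.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `spacing` with the volume centre at the world origin.
#' @param id Subject identifier string.
#' @return An object of class `spect_volume`.
#' @export
spect_volume <- function(data, spacing = c(1, 1, 1), affine = NULL, id = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive voxel sizes", call. = FALSE)
  storage.mode(data) <- "double"
  if (any(!is.finite(data)))
    stop("volume data must be finite", call. = FALSE)
  if (is.null(affine)) affine <- centered_affine(dim(data), spacing)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix", call. = FALSE)
  structure(list(data = data, spacing = spacing, affine = affine,
                 id = as.character(id)),
            class = "spect_volume")
}

centered_affine <- function(dim, spacing) {
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- -spacing * (dim - 1) / 2
  aff
}

#' @export
print.spect_volume <- function(x, ...) {
  cat(sprintf("<spect_volume> %s  %s voxels @ %s mm  range [%.3g, %.3g]\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.spect_volume <- function(x) dim(x$data)

#' Binary mask congruent with a parent volume
#'
#' @param data Logical (or 0/1) 3-D array.
#' @param side Which hemisphere the mask belongs to: `"left"`, `"right"` or
#'   `"none"`.
#' @return An object of class `spect_mask`.
#' @export
spect_mask <- function(data, side = c("none", "left", "right")) {
  side <- match.arg(side)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("mask `data` must be a 3-D array", call. = FALSE)
  data <- array(as.logical(data), dim(data))
  if (any(is.na(data))) stop("mask contains NA", call. = FALSE)
  structure(list(data = data, side = side), class = "spect_mask")
}

#' @export
print.spect_mask <- function(x, ...) {
  cat(sprintf("<spect_mask> side=%s  %s voxels, %d set\n", x$side,
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
dim.spect_mask <- function(x) dim(x$data)

#' Read a 3-D volume from NIfTI-1 or Analyze 7.5
#'
#' Spacing and affine are taken from the header; data are cast to double.
#' Trailing singleton dimensions are dropped; a genuinely non-3-D image is an
#' error.
#'
#' @param path Path to a `.nii`, `.nii.gz` or Analyze `.hdr/.img` file.
#' @param id Subject identifier; defaults to the file name without extension.
#' @return A [spect_volume()].
#' @export
read_volume <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable or unsupported image format: ",
                                           path, " (", conditionMessage(e), ")",
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      img2 <- array(as.numeric(img), d[1:3])
    } else {
      stop("expected a 3-D image, got dimensions ",
           paste(d, collapse = "x"), call. = FALSE)
    }
  } else if (length(d) < 3L) {
    stop("expected a 3-D image, got dimensions ",
         paste(d, collapse = "x"), call. = FALSE)
  } else {
    img2 <- array(as.numeric(img), d)
  }
  sp <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  if (is.null(id)) id <- sub("\\.(nii|hdr|img)(\\.gz)?$", "", basename(path))
  spect_volume(img2, spacing = abs(sp), affine = aff, id = id)
}

#' Write a volume (or mask) as NIfTI-1
#'
#' @param v A [spect_volume()] or [spect_mask()]; masks are stored as uint8.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  is_mask <- inherits(v, "spect_mask")
  if (!is_mask && !inherits(v, "spect_volume"))
    stop("`v` must be a spect_volume or spect_mask", call. = FALSE)
  dat <- if (is_mask) array(as.integer(v$data), dim(v$data)) else v$data
  img <- RNifti::asNifti(dat)
  sp <- if (is_mask) c(1, 1, 1) else v$spacing
  RNifti::pixdim(img) <- sp
  aff <- if (is_mask) centered_affine(dim(dat), sp) else v$affine
  RNifti::qform(img) <- structure(aff, code = 2L)
  ok <- tryCatch({
    suppressWarnings(RNifti::writeNifti(img, path,
                                        datatype = if (is_mask) "uint8" else "double"))
    TRUE
  },
                 error = function(e) stop("I/O error writing ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (!file.exists(path)) stop("I/O error writing ", path, call. = FALSE)
  invisible(path)
}

# Axis (1, 2 or 3) most aligned with world x: the left-right axis under
# radiological convention. Falls back to axis 1 for degenerate affines.
lr_axis <- function(v) {
  rot <- v$affine[1:3, 1:3]
  xr <- abs(rot[1, ]) / sqrt(colSums(rot^2))
  ax <- which.max(xr)
  if (!is.finite(xr[ax])) 1L else as.integer(ax)
}

#' Reflect a volume across its mid-sagittal plane
#'
#' A pure index flip along the left-right axis (the voxel axis most aligned
#' with world x): exact, interpolation-free, and an involution. The global
#' voxel sum is preserved exactly.
#'
#' @param v A [spect_volume()].
#' @return The reflected [spect_volume()].
#' @export
reflect_midplane <- function(v) {
  ax <- lr_axis(v)
  idx <- rev(seq_len(dim(v$data)[ax]))
  v$data <- switch(ax,
                   v$data[idx, , , drop = FALSE],
                   v$data[, idx, , drop = FALSE],
                   v$data[, , idx, drop = FALSE])
  v
}

# World coordinates (n x 3, mm) of 1-based voxel index rows.
vox_to_world <- function(v, idx) {
  idx0 <- cbind(as.matrix(idx) - 1, 1)
  t(v$affine[1:3, , drop = FALSE] %*% t(idx0))
}
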