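#' Create a voxel image
#'
#' The canonical in-memory representation of a 3D volume: a numeric array
#' indexed `[z, y, x]` with a single isotropic voxel size in millimetres.
#' Binary images hold exactly 0 (background/marrow) and 1 (foreground/bone).
#'
#' @param data 3D numeric array, indexed `[z, y, x]`.
#' @param voxel_size Isotropic voxel side length in mm; must be > 0.
#' @param binary Logical; if `NULL` (default) the image is marked binary
#'   when all values are exactly 0 or 1.
#' @param origin Numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return An object of class `voxel_image`.
#' @export
voxel_image <- function(data, voxel_size, binary = NULL, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array indexed [z, y, x]")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L ||
      !is.finite(voxel_size) || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (mm)")
  if (any(dim(data) < 1L)) stop("all three dimensions must be >= 1")
  storage.mode(data) <- if (is.logical(data)) "integer" else storage.mode(data)
  if (is.null(binary)) binary <- all(data == 0 | data == 1)
  if (binary) {
    if (!all(data == 0 | data == 1))
      stop("binary image must contain only 0 and 1")
    storage.mode(data) <- "integer"
  }
  structure(
    list(data = data, voxel_size = voxel_size, is_binary = isTRUE(binary),
         origin = as.numeric(origin)),
    class = "voxel_image"
  )
}

#' @export
dim.voxel_image <- function(x) dim(x$data)

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d voxels (z,y,x), h = %g mm%s\n",
              d[1], d[2], d[3], x$voxel_size,
              if (x$is_binary) ", binary" else ""))
  if (x$is_binary)
    cat(sprintf("  foreground: %d voxels (BV/TV = %.4f)\n",
                sum(x$data), mean(x$data)))
  invisible(x)
}

stopifnot_binary <- function(img) {
  if (!inherits(img, "voxel_image")) stop("expected a voxel_image")
  if (!img$is_binary)
    stop("a binary image is required; segment() grayscale input first")
  invisible(img)
}

#' Threshold an image to binary
#'
#' Values strictly greater than `threshold` map to foreground. Used both by
#' the segmentation chain and when reading "binary" files whose on-disk
#' foreground value is not 1 (e.g. 0/255 8-bit masks).
#'
#' @param img A `voxel_image`.
#' @param threshold Scalar threshold in image units.
#' @return A binary `voxel_image`.
#' @export
as_binary <- function(img, threshold = 0.5) {
  if (!inherits(img, "voxel_image")) stop("expected a voxel_image")
  d <- array(as.integer(img$data > threshold), dim = dim(img$data))
  voxel_image(d, img$voxel_size, binary = TRUE, origin = img$origin)
}

#' Invert a binary image (swap bone and marrow phases)
#'
#' @param img Binary `voxel_image`.
#' @return Binary `voxel_image` with foreground and background exchanged.
#' @export
invert_image <- function(img) {
  stopifnot_binary(img)
  voxel_image(array(1L - img$data, dim = dim(img$data)), img$voxel_size,
              binary = TRUE, origin = img$origin)
}

#' Crop a rectangular ROI out of a volume
#'
#' @param img A `voxel_image`.
#' @param corner Integer length-3, ZERO-based `(z, y, x)` index of the first
#'   voxel of the ROI (matching the indices stored in exported metadata).
#' @param shape Integer length-3, ROI extent in voxels `(z, y, x)`.
#' @return A `voxel_image` of exactly `shape` voxels; spacing preserved.
#' @export
crop_roi <- function(img, corner, shape) {
  if (!inherits(img, "voxel_image")) stop("expected a voxel_image")
  corner <- as.integer(corner); shape <- as.integer(shape)
  if (length(corner) != 3L || length(shape) != 3L)
    stop("`corner` and `shape` must have length 3 (z, y, x)")
  d <- dim(img$data)
  if (any(corner < 0L) || any(shape < 1L) || any(corner + shape > d))
    stop(sprintf(
      "ROI out of bounds: corner (%s) + shape (%s) exceeds volume (%s)",
      paste(corner, collapse = ","), paste(shape, collapse = ","),
      paste(d, collapse = ",")))
  sub <- img$data[corner[1] + seq_len(shape[1]),
                  corner[2] + seq_len(shape[2]),
                  corner[3] + seq_len(shape[3]), drop = FALSE]
  voxel_image(array(sub, dim = shape), img$voxel_size, binary = img$is_binary,
              origin = img$origin + rev(corner) * img$voxel_size)
}

#' Permute the axes of a volume
#'
#' @param img A `voxel_image`.
#' @param perm Permutation of `c(1, 2, 3)` applied to the `(z, y, x)` axes.
#' @return The permuted `voxel_image`.
#' @export
permute_axes <- function(img, perm) {
  if (!inherits(img, "voxel_image")) stop("expected a voxel_image")
  if (!identical(sort(as.integer(perm)), 1:3)) stop("`perm` must permute 1:3")
  voxel_image(aperm(img$data, perm), img$voxel_size, binary = img$is_binary,
              origin = img$origin)
}
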