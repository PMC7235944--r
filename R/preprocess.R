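#' Segmentation settings
#'
#' Parameters of the segmentation chain applied to grayscale micro-CT scans
#' before morphometry: Gaussian filter (sigma 1.2 voxels, kernel truncated at
#' `gauss_support` multiples of sigma), single-level threshold, removal of
#' unconnected foreground, then morphological closing and opening with a
#' cubic kernel (default 3 voxels per side).
#'
#' @param gauss_sigma Gaussian standard deviation in voxels (> 0).
#' @param gauss_support Kernel truncation in multiples of sigma (>= 1);
#'   kernel radius is `ceiling(gauss_support * gauss_sigma)` voxels.
#' @param threshold Single-level threshold in image units; values strictly
#'   above it become foreground.
#' @param morph_kernel Structuring-element side in voxels; odd, >= 1.
#' @param keep_largest_component_only Drop all but the largest connected
#'   foreground component between thresholding and morphology.
#' @param connectivity Foreground connectivity for component labeling,
#'   6 or 26 (default).
#' @param morph_3d Apply closing/opening with a full 3D cube (default); if
#'   `FALSE`, per-slice 2D squares, for sensitivity checks.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(gauss_sigma = 1.2, gauss_support = 2,
                              threshold = 0.5, morph_kernel = 3,
                              keep_largest_component_only = TRUE,
                              connectivity = 26, morph_3d = TRUE) {
  stopifnot(gauss_sigma > 0, gauss_support >= 1,
            morph_kernel >= 1, morph_kernel %% 2 == 1,
            connectivity %in% c(6, 26))
  structure(list(gauss_sigma = gauss_sigma, gauss_support = gauss_support,
                 threshold = threshold, morph_kernel = morph_kernel,
                 keep_largest_component_only =
                   isTRUE(keep_largest_component_only),
                 connectivity = connectivity, morph_3d = isTRUE(morph_3d)),
            class = "preprocess_config")
}

#' Gaussian smoothing of a volume
#'
#' Separable convolution with a normalised discrete Gaussian, symmetric
#' (mirror) boundary handling, kernel truncated at `support * sigma`.
#'
#' @param img A `voxel_image` (grayscale or binary).
#' @param sigma Standard deviation in voxels.
#' @param support Truncation in multiples of sigma.
#' @return A grayscale `voxel_image`.
#' @export
gaussian_smooth <- function(img, sigma = 1.2, support = 2) {
  if (!inherits(img, "voxel_image")) stop("expected a voxel_image")
  radius <- as.integer(ceiling(support * sigma))
  sm <- .cpp_gaussian_blur(as.numeric(img$data), dim(img$data), sigma, radius)
  voxel_image(array(sm, dim = dim(img$data)), img$voxel_size, binary = FALSE,
              origin = img$origin)
}

#' Keep only the largest connected foreground component
#'
#' Ties between equally large components are broken in favour of the
#' component whose lexicographically smallest `(z, y, x)` voxel comes first.
#'
#' @param img Binary `voxel_image`.
#' @param connectivity 26 (default) or 6.
#' @return Binary `voxel_image`; empty input is returned unchanged with a
#'   `degenerate_mask` attribute and a warning.
#' @export
remove_unconnected <- function(img, connectivity = 26) {
  stopifnot_binary(img)
  stopifnot(connectivity %in% c(6, 26))
  if (sum(img$data) == 0L) {
    warning("degenerate mask: no foreground voxels")
    attr(img, "degenerate_mask") <- TRUE
    return(img)
  }
  lab <- .cpp_label_components(img$data, dim(img$data),
                               as.integer(connectivity))
  n <- attr(lab, "n_components")
  if (n == 1L) return(img)
  sizes <- tabulate(lab[lab > 0L], nbins = n)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # component containing the smallest (z,y,x)-lexicographic voxel wins;
    # array order is z-fastest, so rank voxels by ((z*ny)+y)*nx + x
    d <- dim(img$data)
    idx0 <- which(lab > 0L) - 1L
    z <- idx0 %% d[1]; y <- (idx0 %/% d[1]) %% d[2]; x <- idx0 %/% (d[1] * d[2])
    rank <- (z * d[2] + y) * d[3] + x
    labs <- lab[lab > 0L]
    minrank <- vapply(best, function(b) min(rank[labs == b]), numeric(1))
    best <- best[which.min(minrank)]
  }
  keep <- array(as.integer(lab == best[1]), dim = dim(img$data))
  voxel_image(keep, img$voxel_size, binary = TRUE, origin = img$origin)
}

morph_once <- function(data, dims, radius, dilate, morph_3d) {
  if (morph_3d) return(.cpp_morph(data, dims, radius, dilate))
  out <- data
  for (z in seq_len(dims[1])) {                 # per-slice 2D variant
    slice <- array(data[z, , ], dim = c(1L, dims[2], dims[3]))
    out[z, , ] <- .cpp_morph(slice, dim(slice), radius, dilate)
  }
  out
}

#' Morphological closing / opening with a cubic kernel
#'
#' @param img Binary `voxel_image`.
#' @param kernel Structuring-element side length in voxels (odd).
#' @param morph_3d Full 3D cube (default) or per-slice 2D square.
#' @return Binary `voxel_image`.
#' @export
morph_close <- function(img, kernel = 3, morph_3d = TRUE) {
  stopifnot_binary(img)
  r <- as.integer((kernel - 1) / 2)
  if (r == 0L) return(img)
  d <- morph_once(img$data, dim(img$data), r, TRUE, morph_3d)
  d <- morph_once(d, dim(img$data), r, FALSE, morph_3d)
  voxel_image(array(d, dim = dim(img$data)), img$voxel_size, binary = TRUE,
              origin = img$origin)
}

#' @rdname morph_close
#' @export
morph_open <- function(img, kernel = 3, morph_3d = TRUE) {
  stopifnot_binary(img)
  r <- as.integer((kernel - 1) / 2)
  if (r == 0L) return(img)
  d <- morph_once(img$data, dim(img$data), r, FALSE, morph_3d)
  d <- morph_once(d, dim(img$data), r, TRUE, morph_3d)
  voxel_image(array(d, dim = dim(img$data)), img$voxel_size, binary = TRUE,
              origin = img$origin)
}

#' Segment a grayscale scan into a binary bone mask
#'
#' Pipeline: Gaussian smooth, single-level threshold, removal of unconnected
#' foreground, morphological closing, then opening. A threshold outside the
#' image's value range produces an empty or full mask with a warning (not an
#' error); an empty mask after the pipeline is flagged via the
#' `degenerate_mask` attribute.
#'
#' @param img A `voxel_image` (grayscale; binary input is processed the same
#'   way and is stable under re-segmentation at threshold 0.5 for flat
#'   interfaces).
#' @param cfg A `preprocess_config`.
#' @return A binary `voxel_image`.
#' @export
segment <- function(img, cfg = preprocess_config()) {
  if (!inherits(img, "voxel_image")) stop("expected a voxel_image")
  if (!inherits(cfg, "preprocess_config")) stop("expected a preprocess_config")
  rng <- range(img$data)
  if (cfg$threshold < rng[1] || cfg$threshold >= rng[2])
    warning(sprintf(
      "threshold %g outside image value range [%g, %g]: mask will be %s",
      cfg$threshold, rng[1], rng[2],
      if (cfg$threshold >= rng[2]) "empty" else "full"))
  sm <- gaussian_smooth(img, cfg$gauss_sigma, cfg$gauss_support)
  mask <- as_binary(sm, cfg$threshold)
  if (cfg$keep_largest_component_only && sum(mask$data) > 0L)
    mask <- remove_unconnected(mask, cfg$connectivity)
  mask <- morph_close(mask, cfg$morph_kernel, cfg$morph_3d)
  mask <- morph_open(mask, cfg$morph_kernel, cfg$morph_3d)
  if (sum(mask$data) == 0L) {
    warning("degenerate mask: segmentation produced no foreground")
    attr(mask, "degenerate_mask") <- TRUE
  }
  mask
}
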