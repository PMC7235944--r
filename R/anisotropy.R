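#' Quasi-uniform hemisphere directions
#'
#' Deterministic Fibonacci-spiral points on the upper hemisphere (MIL is a
#' symmetric function of direction, so a hemisphere suffices).
#'
#' @param n Number of directions.
#' @return `n x 3` matrix of unit xyz vectors.
#' @export
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

new_mil_distribution <- function(directions, mil, total_line_length,
                                 intercept_count, method, n_directions,
                                 line_spacing = NA_real_, seed = NA_integer_) {
  structure(list(directions = directions, mil = mil,
                 total_line_length = total_line_length,
                 intercept_count = intercept_count, method = method,
                 n_directions = n_directions, line_spacing = line_spacing,
                 seed = seed),
            class = "mil_distribution")
}

#' @export
print.mil_distribution <- function(x, ...) {
  ok <- is.finite(x$mil)
  cat(sprintf(
    "<mil_distribution> method = %s, %d directions (%d usable)\n  MIL range %.4f - %.4f mm\n",
    x$method, nrow(x$directions), sum(ok),
    min(x$mil[ok]), max(x$mil[ok])))
  invisible(x)
}

#' Mean intercept length from parallel test lines
#'
#' For each direction, a grid of parallel lines (spacing `line_spacing`
#' voxels, seeded random in-plane offsets) is clipped to the ROI and the
#' binary volume is sampled at 0.5-voxel steps; background-to-foreground
#' crossings are counted. MIL is the total clipped line length inside the
#' ROI divided by the crossing count. Directions with zero crossings are
#' recorded as `NA` and excluded from ellipsoid fitting.
#'
#' @param img Binary `voxel_image` with both phases present.
#' @param n_directions Number of hemisphere directions (default 128).
#' @param line_spacing Grid spacing in voxels (default 1).
#' @param seed Seed for the in-plane grid offsets (default 0).
#' @return A `mil_distribution` with `method = "test_lines"`.
#' @export
mil_test_lines <- function(img, n_directions = 128, line_spacing = 1,
                           seed = 0) {
  stopifnot_binary(img)
  nfg <- sum(img$data)
  if (nfg == 0L || nfg == prod(dim(img$data)))
    stop("no interface: a solid or empty volume has no mean intercept length")
  dirs <- fibonacci_hemisphere(n_directions)
  offs <- with_seed(seed,
                    matrix(runif(2 * n_directions, 0, line_spacing),
                           ncol = 2))
  res <- .cpp_mil_lines(img$data, dim(img$data), dirs, line_spacing, offs)
  len_mm <- res$total_length * img$voxel_size
  mil <- ifelse(res$crossings > 0, len_mm / res$crossings, NA_real_)
  new_mil_distribution(dirs, mil, len_mm, res$crossings, "test_lines",
                       n_directions, line_spacing, seed)
}

#' Mean intercept length from the projected triangulated surface
#'
#' MIL(n) = 2 BV / P(n), where P(n) is the interior (non-boundary) bone
#' surface area projected onto the plane normal to n,
#' `sum(|t_normal . n| * area) / 2`. Boundary (cut-plane) triangles are
#' excluded: artificial surfaces carry no structural orientation.
#'
#' @param img Binary `voxel_image` (supplies BV by voxel counting).
#' @param mesh Optional capped `tri_mesh` of `img`; computed when missing.
#' @param n_directions Number of hemisphere directions (default 128).
#' @return A `mil_distribution` with `method = "surface_projection"`.
#' @export
mil_surface_projection <- function(img, mesh = NULL, n_directions = 128) {
  stopifnot_binary(img)
  if (is.null(mesh)) mesh <- triangulate(img, cap_boundary = TRUE)
  keep <- !mesh$is_boundary
  if (!any(keep))
    stop("no interface: the mesh has no interior (non-boundary) triangles")
  V <- mesh$vertices
  Tm <- mesh$triangles[keep, , drop = FALSE]
  a <- V[Tm[, 2], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 3], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])   # 2 * area * normal
  dirs <- fibonacci_hemisphere(n_directions)
  proj <- abs(cr %*% t(dirs))                      # 2*area*|n.t| per tri/dir
  P <- colSums(proj) / 4                           # sum(|n.t| * area) / 2
  bv <- sum(img$data) * img$voxel_size^3
  mil <- ifelse(P > 0, 2 * bv / P, NA_real_)
  new_mil_distribution(dirs, as.numeric(mil), rep(NA_real_, n_directions),
                       rep(NA_integer_, n_directions), "surface_projection",
                       n_directions)
}

#' Fit the MIL ellipsoid (fabric tensor)
#'
#' Least-squares fit of the quadratic form `n' A n = 1 / MIL(n)^2` over the
#' six independent components of the symmetric tensor A. The eigen-system of
#' A encodes the principal structural directions; the MIL ellipsoid
#' semi-axes are `eigenvalues^(-1/2)`.
#'
#' @param dist A `mil_distribution`; at least 6 usable directions spanning
#'   3D are required.
#' @return A `fabric_tensor`: `tensor` (3x3, mm^-2), `eigenvalues`
#'   (ascending), `eigenvectors` (columns, matching order), `mil_semi_axes`
#'   (mm, descending), `fit_residual` (RMS misfit of 1/MIL^2), and the
#'   source `method`.
#' @export
fit_mil_ellipsoid <- function(dist) {
  if (!inherits(dist, "mil_distribution")) stop("expected a mil_distribution")
  ok <- is.finite(dist$mil) & dist$mil > 0
  n <- dist$directions[ok, , drop = FALSE]
  y <- 1 / dist$mil[ok]^2
  if (nrow(n) < 6)
    stop("degenerate sampling: fewer than 6 usable MIL directions")
  D <- cbind(n[, 1]^2, n[, 2]^2, n[, 3]^2,
             2 * n[, 1] * n[, 2], 2 * n[, 1] * n[, 3], 2 * n[, 2] * n[, 3])
  qrD <- qr(D)
  if (qrD$rank < 6)
    stop("degenerate sampling: MIL directions do not span 3D")
  a <- qr.coef(qrD, y)
  A <- matrix(c(a[1], a[4], a[5],
                a[4], a[2], a[6],
                a[5], a[6], a[3]), 3, 3)
  resid <- sqrt(mean((D %*% a - y)^2))
  e <- eigen(A, symmetric = TRUE)               # descending
  if (any(e$values <= 0))
    stop("fit failure: MIL ellipsoid is not positive definite")
  ord <- 3:1                                    # ascending eigenvalues
  structure(list(tensor = A, eigenvalues = e$values[ord],
                 eigenvectors = e$vectors[, ord, drop = FALSE],
                 mil_semi_axes = sort(1 / sqrt(e$values), decreasing = TRUE),
                 fit_residual = resid, method = dist$method,
                 n_directions = dist$n_directions,
                 line_spacing = dist$line_spacing, seed = dist$seed),
            class = "fabric_tensor")
}

#' @export
print.fabric_tensor <- function(x, ...) {
  cat(sprintf(
    "<fabric_tensor> eigenvalues (mm^-2): %s\n  MIL semi-axes (mm): %s, RMS misfit %.3g\n",
    paste(signif(x$eigenvalues, 5), collapse = ", "),
    paste(signif(x$mil_semi_axes, 5), collapse = ", "), x$fit_residual))
  invisible(x)
}

#' Degree of anisotropy
#'
#' Conventions (all derived from the same fabric tensor, differing only in
#' eigenvalue normalisation -- a known source of inter-tool disagreement):
#' \describe{
#'   \item{`eigen_ratio`}{`lambda_max / lambda_min` of the fitted tensor
#'     (default; >= 1, 1 = isotropic).}
#'   \item{`semi_axis_ratio`}{longest / shortest MIL semi-axis
#'     `= sqrt(eigen_ratio)`.}
#'   \item{`one_minus_inverse`}{`1 - lambda_min / lambda_max`, in `[0, 1)`.}
#' }
#'
#' @param fab A `fabric_tensor`.
#' @param convention One of the three conventions above.
#' @return A `da_result`: `da`, `convention`, `method`, sampling metadata
#'   and `principal_axis` (unit xyz eigenvector of the largest MIL
#'   semi-axis).
#' @export
degree_of_anisotropy <- function(fab, convention = c("eigen_ratio",
                                                     "semi_axis_ratio",
                                                     "one_minus_inverse")) {
  if (!inherits(fab, "fabric_tensor")) stop("expected a fabric_tensor")
  convention <- match.arg(convention)
  lmin <- fab$eigenvalues[1]
  lmax <- fab$eigenvalues[3]
  da <- switch(convention,
               eigen_ratio = lmax / lmin,
               semi_axis_ratio = sqrt(lmax / lmin),
               one_minus_inverse = 1 - lmin / lmax)
  structure(list(da = da, convention = convention, method = fab$method,
                 n_directions = fab$n_directions,
                 line_spacing = fab$line_spacing, seed = fab$seed,
                 principal_axis = fab$eigenvectors[, 1],
                 fitted_quantity = "1/MIL^2"),
            class = "da_result")
}

#' @export
print.da_result <- function(x, ...) {
  cat(sprintf(
    "<da_result> DA = %.4f (%s, %s method)\n  principal axis (xyz): %s\n",
    x$da, x$convention, x$method,
    paste(signif(x$principal_axis, 4), collapse = ", ")))
  invisible(x)
}
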