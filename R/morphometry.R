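#' Bone volume fraction by voxel counting
#'
#' BV/TV = foreground voxel count / total voxel count; the total volume is
#' the full cubical ROI.
#'
#' @param img Binary `voxel_image`.
#' @return Fraction in `[0, 1]`.
#' @export
bvtv_voxel <- function(img) {
  stopifnot_binary(img)
  sum(img$data) / prod(dim(img$data))
}

#' Triangulate the bone/marrow interface
#'
#' Extracts the iso-surface at level 0.5 between voxel centers (marching
#' tetrahedra on the uniform 6-tet subdivision; on binary data every vertex
#' is an edge midpoint and the mesh is watertight). With
#' `cap_boundary = TRUE` the volume is conceptually padded with one layer of
#' background so that foreground touching an ROI face is closed by cap
#' triangles on the cut planes (half a voxel outside the outermost voxel
#' centers); caps and their adjoining chamfers are flagged `is_boundary`.
#' With `cap_boundary = FALSE` only interfaces interior to the ROI are
#' generated and no triangle is flagged.
#'
#' @param img Binary `voxel_image`.
#' @param cap_boundary Close the mesh at the ROI faces (default `TRUE`).
#' @return A `tri_mesh`: `vertices` (n x 3 mm, xyz), `triangles` (m x 3
#'   vertex indices, outward-oriented), `is_boundary` (length m), plus the
#'   source geometry. Empty foreground gives a valid mesh with 0 triangles.
#' @export
triangulate <- function(img, cap_boundary = TRUE) {
  stopifnot_binary(img)
  h <- img$voxel_size
  m <- .cpp_marching_tets(img$data, dim(img$data), h, isTRUE(cap_boundary))
  V <- m$vertices
  Tm <- m$triangles
  nb <- rep(FALSE, nrow(Tm))
  if (isTRUE(cap_boundary) && nrow(Tm) > 0) {
    # a vertex is "on the boundary" if it lies on any ROI cut plane; a
    # triangle is artificial if all three of its vertices are
    n_xyz <- rev(dim(img$data))                # (nx, ny, nz)
    tol <- 1e-9
    onplane <- matrix(FALSE, nrow(V), 3)
    for (j in 1:3)
      onplane[, j] <- abs(V[, j] + 0.5 * h) < tol |
                      abs(V[, j] - (n_xyz[j] - 0.5) * h) < tol
    vflag <- rowSums(onplane) > 0
    nb <- vflag[Tm[, 1]] & vflag[Tm[, 2]] & vflag[Tm[, 3]]
  }
  structure(list(vertices = V, triangles = Tm, is_boundary = nb,
                 voxel_size = h, dims = dim(img$data),
                 capped = isTRUE(cap_boundary)),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(
    "<tri_mesh> %d vertices, %d triangles (%d boundary), %s\n",
    nrow(x$vertices), nrow(x$triangles), sum(x$is_boundary),
    if (x$capped) "capped at ROI faces" else "interior surface only"))
  invisible(x)
}

triangle_areas <- function(mesh) {
  V <- mesh$vertices; Tm <- mesh$triangles
  if (nrow(Tm) == 0) return(numeric(0))
  a <- V[Tm[, 2], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  b <- V[Tm[, 3], , drop = FALSE] - V[Tm[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Bone surface area
#'
#' Sum of triangle areas. With `include_boundary = FALSE` the artificial cut
#' surfaces at the ROI faces (`is_boundary` triangles) are not counted,
#' reproducing tools that exclude them; with `TRUE` they are included. The
#' two differ exactly by the summed boundary-triangle area.
#'
#' @param mesh A `tri_mesh`.
#' @param include_boundary Count boundary (cut-plane) triangles.
#' @return Area in mm^2 (0 for an empty mesh).
#' @export
bone_surface <- function(mesh, include_boundary = TRUE) {
  if (!inherits(mesh, "tri_mesh")) stop("expected a tri_mesh")
  ar <- triangle_areas(mesh)
  if (length(ar) == 0) return(0)
  if (include_boundary) sum(ar) else sum(ar[!mesh$is_boundary])
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron summation over outward-oriented triangles.
#'
#' @param mesh A closed `tri_mesh` (from `triangulate(cap_boundary = TRUE)`).
#' @return Volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (!inherits(mesh, "tri_mesh")) stop("expected a tri_mesh")
  Tm <- mesh$triangles
  if (nrow(Tm) == 0) return(0)
  bad <- .cpp_open_edge_count(Tm)
  if (bad > 0)
    stop("mesh is not closed (", bad, " open edges); ",
         "enclosed volume requires cap_boundary = TRUE")
  V <- mesh$vertices
  v0 <- V[Tm[, 1], , drop = FALSE]
  v1 <- V[Tm[, 2], , drop = FALSE]
  v2 <- V[Tm[, 3], , drop = FALSE]
  cx <- v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2]
  cy <- v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3]
  cz <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  sum(v0[, 1] * cx + v0[, 2] * cy + v0[, 3] * cz) / 6
}

#' Bone volume fraction from the triangulated surface
#'
#' BV is the volume enclosed by the (closed, capped) bone surface mesh; TV
#' is the volume of the cubical ROI. This is the mesh-based alternative to
#' voxel counting and differs from it only by sub-voxel surface placement.
#'
#' @param mesh A closed `tri_mesh` of the image.
#' @param img The binary `voxel_image` the mesh came from (supplies TV).
#' @return Fraction.
#' @export
bvtv_mesh <- function(mesh, img) {
  stopifnot_binary(img)
  tv <- prod(dim(img$data)) * img$voxel_size^3
  mesh_volume(mesh) / tv
}
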