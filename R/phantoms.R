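# Binary test volumes with analytic ground truth. These stand in for real
# trabecular bone: plates and rods probe thickness/separation/anisotropy with
# closed-form answers, spheres probe surface and enclosed volume, and the
# thresholded Gaussian random field ("foam") provides an isotropic structure
# with controlled volume fraction.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

axis_slot <- function(axis) {
  slot <- match(axis, c("z", "y", "x"))
  if (is.na(slot)) stop("`axis` must be one of 'z', 'y', 'x'")
  slot
}

axis_unit_xyz <- function(axis) {
  switch(axis, z = c(0, 0, 1), y = c(0, 1, 0), x = c(1, 0, 0))
}

# build a volume whose value depends only on the index along `axis`
profile_volume <- function(dims, axis, fg_of_k) {
  slot <- axis_slot(axis)
  n <- dims[slot]
  fg <- as.integer(fg_of_k(0:(n - 1)))
  perm <- c(slot, setdiff(1:3, slot))
  a <- array(fg, dim = c(n, dims[perm[2]], dims[perm[3]]))
  aperm(a, order(perm))
}

#' Generate a phantom volume with analytic ground truth
#'
#' Kinds:
#' \describe{
#'   \item{`plate_stack`}{Parallel full-extent plates of thickness `t` voxels
#'     separated by gaps of `g` voxels, normal along `axis`. Ground truth:
#'     Tb.Th `= t*h`, Tb.Sp `= g*h`, BV/TV `= t/(t+g)` when the extent is a
#'     whole number of periods (the realized voxel fraction is returned).}
#'   \item{`rod_array`}{Square lattice of parallel rods of diameter `d`
#'     voxels at center spacing `s`, along `axis`; a voxel belongs to a rod
#'     when its center lies within `d/2` of the rod axis (voxelisation error
#'     up to 1 voxel on the diameter). Ground truth: Tb.Th `= d*h`.}
#'   \item{`sphere`}{A single centered solid ball of radius `r` voxels.
#'     Ground truth: BS `= 4*pi*r^2*h^2`, Tb.Th `= 2*r*h`, enclosed volume
#'     `= 4/3*pi*r^3*h^3`.}
#'   \item{`solid_cube`}{Foreground filling the whole ROI; Tb.Sp undefined
#'     (`NA`), interior BS 0.}
#'   \item{`isotropic_foam`}{Seeded white noise smoothed with a Gaussian of
#'     standard deviation `corr_length` voxels and thresholded at the
#'     quantile matching the target `bvtv`; isotropic by construction.}
#' }
#'
#' @param kind One of `"plate_stack"`, `"rod_array"`, `"sphere"`,
#'   `"solid_cube"`, `"isotropic_foam"`.
#' @param dims Integer length-3 `(z, y, x)` extent in voxels (or a scalar
#'   for a cube). Default 128^3.
#' @param voxel_size Voxel side in mm; default 0.018.
#' @param params Kind-specific list: `t`, `g`, `axis` (plates); `d`, `s`,
#'   `axis` (rods); `r` (sphere); `bvtv`, `corr_length` (foam).
#' @param seed Integer seed (foam only); same spec + seed gives a
#'   bit-identical volume.
#' @return A list of class `phantom` with elements `image` (`voxel_image`)
#'   and `truth` (list: `bvtv`, `bs`, `tb_th`, `tb_sp`, `da_class`,
#'   `principal_axis` in xyz, `enclosed_volume` where defined).
#' @export
make_phantom <- function(kind = c("plate_stack", "rod_array", "sphere",
                                  "solid_cube", "isotropic_foam"),
                         dims = c(128L, 128L, 128L), voxel_size = 0.018,
                         params = list(), seed = 0L) {
  kind <- match.arg(kind)
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  dims <- as.integer(dims)
  stopifnot(all(dims >= 1L), voxel_size > 0)
  h <- voxel_size
  p <- params
  out <- switch(kind,
    plate_stack = {
      t <- p$t %||% 11L; g <- p$g %||% 22L; axis <- p$axis %||% "z"
      n <- dims[axis_slot(axis)]
      if (t < 1 || g < 1 || t + g > n)
        stop("geometry error: plate period t+g exceeds the volume")
      a <- profile_volume(dims, axis, function(k) (k %% (t + g)) < t)
      list(a = a,
           truth = list(bvtv = mean(a), bs = NA_real_, tb_th = t * h,
                        tb_sp = g * h, da_class = "transversely_anisotropic",
                        principal_axis = axis_unit_xyz(axis)))
    },
    rod_array = {
      d <- p$d %||% 15; s <- p$s %||% (3 * d); axis <- p$axis %||% "z"
      slot <- axis_slot(axis)
      per <- setdiff(1:3, slot)
      n1 <- dims[per[1]]; n2 <- dims[per[2]]
      if (d < 1 || d > min(n1, n2) || s < 1)
        stop("geometry error: rod diameter exceeds the cross-section")
      near <- function(u, n) {
        centers <- seq((s - 1) / 2, n - 1, by = s)
        apply(abs(outer(u, centers, "-")), 1, min)
      }
      du <- near(0:(n1 - 1), n1)
      dv <- near(0:(n2 - 1), n2)
      cross <- outer(du^2, dv^2, "+") <= (d / 2)^2
      a <- array(0L, dim = c(dims[slot], n1, n2))
      a[] <- rep(as.integer(cross), each = dims[slot])
      a <- aperm(a, order(c(slot, per)))
      list(a = a,
           truth = list(bvtv = mean(a), bs = NA_real_, tb_th = d * h,
                        tb_sp = NA_real_,
                        da_class = "transversely_anisotropic",
                        principal_axis = axis_unit_xyz(axis)))
    },
    sphere = {
      r <- p$r %||% 20
      if (2 * r > min(dims)) stop("geometry error: sphere exceeds the volume")
      ctr <- (dims - 1) / 2
      z2 <- ((0:(dims[1] - 1)) - ctr[1])^2
      y2 <- ((0:(dims[2] - 1)) - ctr[2])^2
      x2 <- ((0:(dims[3] - 1)) - ctr[3])^2
      a <- array(0L, dim = dims)
      a[] <- as.integer(outer(outer(z2, y2, "+"), x2, "+") <= r^2)
      list(a = a,
           truth = list(bvtv = (4 / 3) * pi * r^3 / prod(dims),
                        bs = 4 * pi * r^2 * h^2, tb_th = 2 * r * h,
                        tb_sp = NA_real_, da_class = "isotropic",
                        principal_axis = NULL,
                        enclosed_volume = (4 / 3) * pi * r^3 * h^3))
    },
    solid_cube = {
      a <- array(1L, dim = dims)
      list(a = a,
           truth = list(bvtv = 1, bs = 0, tb_th = NA_real_, tb_sp = NA_real_,
                        tb_sp_undefined = TRUE, da_class = "isotropic",
                        principal_axis = NULL))
    },
    isotropic_foam = {
      target <- p$bvtv %||% 0.25; cl <- p$corr_length %||% 3
      if (target <= 0 || target >= 1) stop("foam bvtv must be in (0, 1)")
      noise <- with_seed(seed, rnorm(prod(dims)))
      sm <- .cpp_gaussian_blur(noise, dims, cl, as.integer(ceiling(3 * cl)))
      thr <- quantile(sm, 1 - target, names = FALSE)
      a <- array(as.integer(sm > thr), dim = dims)
      list(a = a,
           truth = list(bvtv = target, bs = NA_real_, tb_th = NA_real_,
                        tb_sp = NA_real_, da_class = "isotropic",
                        principal_axis = NULL))
    })
  structure(list(
    image = voxel_image(out$a, h, binary = TRUE),
    truth = out$truth,
    spec = list(kind = kind, dims = dims, voxel_size = h, params = p,
                seed = seed)),
    class = "phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> kind = %s, %s voxels, h = %g mm\n",
              x$spec$kind, paste(dim(x$image$data), collapse = " x "),
              x$image$voxel_size))
  tv <- x$truth[!vapply(x$truth, is.null, logical(1))]
  for (nm in names(tv))
    if (is.numeric(tv[[nm]]) && length(tv[[nm]]) == 1L)
      cat(sprintf("  truth %-10s %s\n", nm, format(tv[[nm]])))
  invisible(x)
}
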