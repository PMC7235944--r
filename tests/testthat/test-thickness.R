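h <- 0.018

test_that("a full-extent slab reports its layer count as thickness", {
  ph <- make_phantom("plate_stack", dims = 66, voxel_size = h,
                     params = list(t = 11, g = 22))
  # interior voxels under the default policy
  map <- local_thickness(ph$image, "foreground")
  mid <- map$values[6, 20:40, 20:40]           # center layer of first plate
  expect_true(all(abs(mid - 11 * h) <= h + 1e-12))
  # exclude-edge policy: slab value exact everywhere retained, sd zero
  st <- tb_stats(local_thickness(ph$image, "foreground",
                                 "exclude_edge_voxels"))
  expect_equal(st[["mean"]], 11 * h, tolerance = 1e-12)
  expect_equal(st[["sd"]], 0)
})

test_that("an axis-aligned rod reports its diameter within one voxel", {
  ph <- make_phantom("rod_array", dims = c(40, 45, 45), voxel_size = h,
                     params = list(d = 15, s = 45))
  map <- local_thickness(ph$image, "foreground", "exclude_edge_voxels")
  vals <- map$values[map$values > 0 & !map$excluded]
  mode_val <- as.numeric(names(sort(table(vals), decreasing = TRUE))[1])
  expect_lte(abs(mode_val - 15 * h), h)
  st <- tb_stats(map)
  expect_lte(abs(st[["mean"]] - 15 * h), h)
})

test_that("a single isolated voxel has thickness of one voxel diameter", {
  a <- array(0L, c(9, 9, 9)); a[5, 5, 5] <- 1L
  map <- local_thickness(voxel_image(a, h), "foreground")
  expect_equal(map$values[5, 5, 5], h)
  expect_equal(sum(map$values > 0), 1)
})

test_that("separation is thickness of the complement, exactly", {
  f <- make_phantom("isotropic_foam", dims = 32, seed = 9)$image
  for (pol in c("include_edges", "exclude_edge_voxels")) {
    sp <- local_thickness(f, "background", pol)
    th_c <- local_thickness(invert_image(f), "foreground", pol)
    expect_identical(sp$values, th_c$values, label = pol)
    expect_identical(sp$excluded, th_c$excluded, label = pol)
    expect_identical(unname(tb_stats(sp)), unname(tb_stats(th_c)))
  }
})

test_that("plate gaps are recovered within one voxel", {
  ph <- make_phantom("plate_stack", dims = 66, voxel_size = h,
                     params = list(t = 11, g = 22))
  sp <- tb_stats(local_thickness(ph$image, "background",
                                 "exclude_edge_voxels"))
  expect_lte(abs(sp[["mean"]] - 22 * h), h + 1e-12)
})

test_that("thickness map invariants hold", {
  f <- make_phantom("isotropic_foam", dims = 24, seed = 2)$image
  map <- local_thickness(f, "foreground")
  expect_true(all(map$values >= 0))
  expect_true(all((map$values > 0) == (f$data == 1L)))
  expect_true(all(map$values[map$values > 0] >= f$voxel_size - 1e-12))
})

test_that("thickness is equivariant under axis permutation", {
  f <- make_phantom("isotropic_foam", dims = c(20, 24, 28), seed = 6)$image
  perm <- c(3, 1, 2)
  m1 <- local_thickness(f, "foreground")
  m2 <- local_thickness(permute_axes(f, perm), "foreground")
  expect_identical(m2$values, aperm(m1$values, perm))
})

test_that("dilating the foreground never decreases thickness", {
  f <- make_phantom("isotropic_foam", dims = 24, seed = 3)$image
  dil <- voxel_image(array(trabemorph:::morph_once(f$data, dim(f$data), 1,
                                                   TRUE, TRUE),
                           dim(f$data)), f$voxel_size)
  m0 <- local_thickness(f, "foreground")$values
  m1 <- local_thickness(dil, "foreground")$values
  inside <- f$data == 1L
  expect_true(all(m1[inside] >= m0[inside] - 1e-12))
})

test_that("edge policies agree exactly for fully interior structures", {
  a <- array(0L, c(30, 30, 30)); a[10:20, 10:20, 10:20] <- 1L
  img <- voxel_image(a, h)
  mi <- local_thickness(img, "foreground", "include_edges")
  me <- local_thickness(img, "foreground", "exclude_edge_voxels")
  expect_identical(mi$values, me$values)
  expect_false(any(me$excluded))
})

test_that("edge policies differ only near the ROI faces", {
  pl <- make_phantom("plate_stack", dims = 42, voxel_size = h,
                     params = list(t = 7, g = 14))$image
  vi <- local_thickness(pl, "foreground", "include_edges")$values
  ve <- local_thickness(pl, "foreground", "exclude_edge_voxels")$values
  differs <- which(abs(vi - ve) > 1e-12, arr.ind = TRUE)
  if (nrow(differs) > 0) {
    d <- dim(pl$data)
    # distance of each differing voxel to its nearest ROI face, in voxels
    face_dist <- pmin(differs[, 1] - 1, d[1] - differs[, 1],
                      differs[, 2] - 1, d[2] - differs[, 2],
                      differs[, 3] - 1, d[3] - differs[, 3])
    rmax <- max(vi, ve) / h / 2 + 1
    expect_true(all(face_dist <= rmax))
  }
  expect_gt(nrow(differs), 0)  # face-touching plates must show the effect
})

test_that("thickness maps export and re-import exactly", {
  ph <- make_phantom("plate_stack", dims = 33, voxel_size = h,
                     params = list(t = 11, g = 22))
  map <- local_thickness(ph$image, "foreground")
  td <- withr::local_tempdir()
  thickness_map_export(map, file.path(td, "th.mhd"))
  back <- read_volume(file.path(td, "th.mhd"))
  expect_identical(back$data, map$values)
  # interior plateau of the slab sits at t * h
  expect_equal(median(back$data[back$data > 0]), 11 * h)
})

test_that("degenerate phases raise errors naming the phase", {
  full <- voxel_image(array(1L, c(6, 6, 6)), h)
  expect_error(local_thickness(full, "background"), "background")
  empty <- voxel_image(array(0L, c(6, 6, 6)), h)
  expect_error(local_thickness(empty, "foreground"), "foreground")
})
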