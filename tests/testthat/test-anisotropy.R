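test_that("fibonacci hemisphere directions are unit and well spread", {
  d <- fibonacci_hemisphere(128)
  expect_true(all(abs(sqrt(rowSums(d^2)) - 1) < 1e-9))
  expect_true(all(d[, 3] > 0))
  expect_lt(max(abs(colMeans(d[, 1:2]))), 0.1)
})

test_that("test-line MIL obeys its definitional identity", {
  f <- make_phantom("isotropic_foam", dims = 32, seed = 1)$image
  d <- mil_test_lines(f, 32, 1, 0)
  ok <- d$intercept_count > 0
  expect_true(any(ok))
  expect_equal(d$mil[ok], d$total_line_length[ok] / d$intercept_count[ok])
  expect_true(all(d$mil[ok] > 0))
})

test_that("single-phase volumes have no mean intercept length", {
  expect_error(mil_test_lines(voxel_image(array(1L, c(8, 8, 8)), 1)),
               "no interface|solid")
  s <- voxel_image(array(1L, c(8, 8, 8)), 1)
  expect_error(mil_surface_projection(s), "no interface")
})

test_that("plates have shorter intercepts across than along", {
  pl <- make_phantom("plate_stack", dims = 66,
                     params = list(t = 11, g = 22))$image
  d <- mil_test_lines(pl, 64, 1, 0)
  iz <- which.max(abs(d$directions[, 3]))
  ix <- which.max(abs(d$directions[, 1]))
  expect_lt(d$mil[iz], d$mil[ix])
})

test_that("projected-surface MIL of an analytic sphere is isotropic", {
  # the projection formula on a smooth closed sphere: projected area pi r^2
  # in every direction, so MIL must be constant within discretisation error
  ph <- make_phantom("sphere", dims = 64, params = list(r = 20),
                     voxel_size = 1)
  mesh <- uv_sphere_mesh(20)
  d <- mil_surface_projection(ph$image, mesh, n_directions = 128)
  expect_lt(max(d$mil) / min(d$mil) - 1, 0.02)
})

test_that("doubling the scale doubles every projected-surface MIL", {
  ph <- make_phantom("sphere", dims = 40, params = list(r = 12),
                     voxel_size = 1)
  ph2 <- voxel_image(ph$image$data, 2)
  d1 <- mil_surface_projection(ph$image, n_directions = 32)
  d2 <- mil_surface_projection(ph2, n_directions = 32)
  expect_equal(d2$mil, 2 * d1$mil, tolerance = 1e-12)
})

test_that("ellipsoid fit recovers a forward-generated fabric exactly", {
  dirs <- fibonacci_hemisphere(50)
  A <- diag(c(1, 1, 0.25))                   # semi-axes (1, 1, 2) mm
  fab <- fit_mil_ellipsoid(mil_from_tensor(A, dirs))
  expect_equal(fab$mil_semi_axes, c(2, 1, 1), tolerance = 1e-6)
  expect_lt(fab$fit_residual, 1e-9)
  expect_true(all(fab$eigenvalues > 0))
  expect_equal(diff(fab$eigenvalues) >= 0, c(TRUE, TRUE))
  # orthonormal eigenvectors
  expect_equal(crossprod(fab$eigenvectors), diag(3), tolerance = 1e-9)
})

test_that("a constant MIL distribution gives the isotropic closed form", {
  dirs <- fibonacci_hemisphere(20)
  cc <- 0.7
  fab <- fit_mil_ellipsoid(mil_from_tensor(diag(rep(cc^-2, 3)), dirs))
  expect_equal(fab$tensor, diag(rep(cc^-2, 3)), tolerance = 1e-9)
  expect_equal(fab$eigenvalues, rep(cc^-2, 3), tolerance = 1e-9)
})

test_that("the fit is equivariant under rotations of the directions", {
  dirs <- fibonacci_hemisphere(60)
  A <- diag(c(0.3, 0.8, 1.9))
  R <- random_rotation(17)
  fab0 <- fit_mil_ellipsoid(mil_from_tensor(A, dirs))
  # rotating directions and values together rotates the tensor: feed the
  # same MIL values at rotated directions
  milv <- 1 / sqrt(rowSums((dirs %*% A) * dirs))
  distR <- trabemorph:::new_mil_distribution(dirs %*% t(R), milv,
                                             rep(NA_real_, 60), rep(1L, 60),
                                             "test_lines", 60)
  fabR <- fit_mil_ellipsoid(distR)
  expect_equal(fabR$eigenvalues, fab0$eigenvalues, tolerance = 1e-9)
  expect_equal(fabR$tensor, R %*% fab0$tensor %*% t(R), tolerance = 1e-9)
})

test_that("degenerate direction sets are rejected", {
  dirs <- fibonacci_hemisphere(20)
  few <- trabemorph:::new_mil_distribution(dirs[1:4, ], rep(1, 4),
                                           rep(NA_real_, 4), rep(1L, 4),
                                           "test_lines", 4)
  expect_error(fit_mil_ellipsoid(few), "fewer than 6")
  flat <- trabemorph:::new_mil_distribution(
    matrix(c(1, 0, 0, 0, 1, 0, 1, 1, 0, 1, -1, 0, 2, 1, 0, 1, 2, 0),
           ncol = 3, byrow = TRUE),
    rep(1, 6), rep(NA_real_, 6), rep(1L, 6), "test_lines", 6)
  expect_error(fit_mil_ellipsoid(flat), "span")
})

test_that("DA conventions convert as closed forms require", {
  dirs <- fibonacci_hemisphere(40)
  fab <- fit_mil_ellipsoid(mil_from_tensor(diag(c(1, 1, 4)), dirs))
  expect_equal(degree_of_anisotropy(fab, "eigen_ratio")$da, 4,
               tolerance = 1e-9)
  expect_equal(degree_of_anisotropy(fab, "semi_axis_ratio")$da, 2,
               tolerance = 1e-9)
  expect_equal(degree_of_anisotropy(fab, "one_minus_inverse")$da, 0.75,
               tolerance = 1e-9)
  iso <- fit_mil_ellipsoid(mil_from_tensor(diag(3), dirs))
  expect_equal(degree_of_anisotropy(iso, "eigen_ratio")$da, 1,
               tolerance = 1e-9)
  expect_equal(degree_of_anisotropy(iso, "one_minus_inverse")$da, 0,
               tolerance = 1e-9)
})

test_that("parameter recovery holds across seeded anisotropies with noise", {
  dirs128 <- fibonacci_hemisphere(128)
  dirs50 <- fibonacci_hemisphere(50)
  for (i in 1:8) {
    set.seed(300 + i)
    ratio <- 1 + 3 * runif(1)                 # eigen-ratio in [1, 4]
    lam <- c(1, runif(1, 1, ratio), ratio)
    R <- random_rotation(400 + i)
    A <- R %*% diag(lam) %*% t(R)
    fab <- fit_mil_ellipsoid(mil_from_tensor(A, dirs50))
    expect_lt(abs(degree_of_anisotropy(fab)$da / ratio - 1), 1e-6)
    set.seed(500 + i)
    fabn <- fit_mil_ellipsoid(mil_from_tensor(A, dirs128, noise_sd = 0.02))
    expect_lt(abs(degree_of_anisotropy(fabn)$da / ratio - 1), 0.05)
  }
})

test_that("rod phantoms are strongly anisotropic along the rod axis", {
  rod <- make_phantom("rod_array", dims = 63, params = list(d = 9, s = 21),
                      seed = 0)$image
  da_l <- degree_of_anisotropy(fit_mil_ellipsoid(
    mil_test_lines(rod, 128, 1, 0)))
  da_s <- degree_of_anisotropy(fit_mil_ellipsoid(
    mil_surface_projection(rod, n_directions = 128)))
  for (da in list(da_l, da_s)) {
    expect_gt(da$da, 1.5)
    angle <- acos(min(1, abs(da$principal_axis[3]))) * 180 / pi
    expect_lt(angle, 5)
  }
  # the two acquisition methods agree on the principal direction
  dot <- abs(sum(da_l$principal_axis * da_s$principal_axis))
  expect_gt(dot, cos(5 * pi / 180))
})

test_that("more directions reduce the spread of DA on the isotropic foam", {
  da_at <- function(n_dir) vapply(1:6, function(s) {
    f <- make_phantom("isotropic_foam", dims = 24, seed = s,
                      params = list(bvtv = 0.3, corr_length = 2))$image
    degree_of_anisotropy(fit_mil_ellipsoid(
      mil_test_lines(f, n_dir, 1, s)))$da
  }, numeric(1))
  expect_lt(var(da_at(96)), var(da_at(16)))
})
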