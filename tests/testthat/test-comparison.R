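test_that("percent differences follow their closed forms", {
  expect_equal(percent_difference(110, 100, "ref_b"), 10)
  expect_equal(percent_difference(110, 100, "pair_mean"), 100 * 10 / 105)
  expect_equal(percent_difference(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  # antisymmetry under swap with the pair-mean normalization
  a <- c(1.2, 3.4, 5.6); b <- c(1.0, 3.9, 5.0)
  expect_equal(percent_difference(a, b, "pair_mean"),
               -percent_difference(b, a, "pair_mean"))
  expect_warning(d <- percent_difference(c(1, 2), c(0, 2), "ref_b"),
                 "zero denominator")
  expect_true(is.na(d[1]) && d[2] == 0)
})

test_that("Bland-Altman limits match the closed form", {
  b <- c(100, 100, 100)
  a <- c(99, 100, 101)                       # differences -1, 0, +1 %
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_diff_pct, 0)
  expect_equal(ba$sd_diff_pct, 1)            # n-1 denominator
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  id <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(id$mean_diff_pct, id$sd_diff_pct, id$loa_low, id$loa_high),
               c(0, 0, 0, 0))
  expect_error(bland_altman(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("Bland-Altman recovers known offset and noise from simulation", {
  set.seed(42)
  n <- 500
  b <- runif(n, 50, 150)
  a <- b * (1 + (5 + rnorm(n, 0, 2)) / 100)   # +5% offset, 2% noise
  ba <- bland_altman(a, b)
  expect_lt(abs(ba$mean_diff_pct - 5), 3 * 2 / sqrt(n))
  expect_lt(abs(ba$sd_diff_pct - 2), 0.2)
})

test_that("limits of agreement cover about 95% of Gaussian differences", {
  set.seed(1234)
  n <- 2000
  b <- rep(100, n)
  a <- 100 + rnorm(n, 0.5, 2)
  ba <- bland_altman(a, b)
  cover <- mean(ba$diff_pct >= ba$loa_low & ba$diff_pct <= ba$loa_high)
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("regression closed forms and identities hold", {
  a <- c(1, 2, 3, 4, 5)
  r <- linear_regression(a, 2 * a + 1)
  expect_equal(unname(r), c(2, 1, 1))
  set.seed(99)
  x <- rnorm(1000); y <- rnorm(1000)          # independent noise
  expect_lt(linear_regression(x, y)[["r_squared"]], 0.01)
  # slope(b on a) * slope(a on b) == r^2, and R^2 is swap-invariant
  set.seed(5)
  u <- rnorm(50); v <- 0.5 * u + rnorm(50, 0, 0.3)
  f1 <- linear_regression(u, v); f2 <- linear_regression(v, u)
  expect_equal(f1[["slope"]] * f2[["slope"]], f1[["r_squared"]],
               tolerance = 1e-12)
  expect_equal(f1[["r_squared"]], f2[["r_squared"]])
  expect_error(linear_regression(rep(1, 5), 1:5), "zero variance")
})

make_results <- function(values_by_label) {
  do.call(rbind, lapply(names(values_by_label), function(lab) {
    v <- values_by_label[[lab]]
    data.frame(sample = paste0("s", seq_along(v)), parameter = "BV/TV",
               variant_label = lab, value = v, stringsAsFactors = FALSE)
  }))
}

test_that("a +5% shifted variant reports diff 5%, slope 1.05, R^2 = 1", {
  set.seed(8)
  ref <- runif(20, 0.1, 0.4)
  res <- make_results(list(shifted = 1.05 * ref, reference = ref))
  rep <- compare_variants(res, list(c("shifted", "reference")))
  expect_equal(rep$mean_diff_pct, 5, tolerance = 1e-9)
  expect_equal(rep$sd_diff_pct, 0, tolerance = 1e-9)
  expect_equal(rep$slope, 1.05, tolerance = 1e-9)
  expect_equal(rep$r_squared, 1, tolerance = 1e-12)
  expect_equal(rep$n, 20L)
})

test_that("report is antisymmetric under pair swap with pair_mean", {
  set.seed(12)
  ref <- runif(15, 1, 2)
  other <- ref * (1 + rnorm(15, 0.03, 0.01))
  res <- make_results(list(A = other, B = ref))
  r_ab <- compare_variants(res, list(c("A", "B")), "pair_mean")
  r_ba <- compare_variants(res, list(c("B", "A")), "pair_mean")
  expect_equal(r_ab$mean_diff_pct, -r_ba$mean_diff_pct, tolerance = 1e-12)
  expect_equal(r_ab$r_squared, r_ba$r_squared, tolerance = 1e-12)
})

test_that("samples with missing values are dropped and counted", {
  res <- make_results(list(A = c(1, 2, 3, NA, 5), B = c(1, 2, 3, 4, 5)))
  expect_message(rep <- compare_variants(res, list(c("A", "B"))), "dropped")
  expect_equal(rep$n, 4L)
  expect_equal(rep$n_dropped, 1L)
})

test_that("BV/TV by the package and by the loop oracle agree to 0.00 +/- 0.00", {
  phantoms <- phantom_bag(12, dims = 24, seed0 = 600)
  rows <- do.call(rbind, lapply(seq_along(phantoms), function(i) {
    img <- phantoms[[i]]$image
    data.frame(sample = paste0("p", i), parameter = "BV/TV",
               variant_label = c("package", "oracle"),
               value = c(bvtv_voxel(img),
                         oracle_voxel_count(img$data) / length(img$data)),
               stringsAsFactors = FALSE)
  }))
  rep <- compare_variants(rows, list(c("package", "oracle")))
  expect_equal(rep$mean_diff_pct, 0)
  expect_equal(rep$sd_diff_pct, 0)
  expect_equal(rep$r_squared, 1)
})

test_that("agreement plots render without error", {
  set.seed(3)
  b <- runif(30, 1, 2); a <- b * 1.02
  path <- file.path(withr::local_tempdir(), "p.png")
  grDevices::png(path)
  ba <- plot_agreement(a, b, "BV/TV")
  grDevices::dev.off()
  expect_true(file.exists(path))
  expect_equal(ba$mean_diff_pct, 2, tolerance = 1e-9)
})
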