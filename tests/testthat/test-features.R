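test_that("discretisation follows the fixed-bin-width definition", {
  v <- volume_grid(array(c(0, 24.9, 25, 60, 0, 0, 0, 0), c(2, 2, 2)))
  m <- mask_volume(array(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), c(2, 2, 2)))
  d <- discretize(v, m, 25)
  expect_equal(d$levels[m$values == 1L], c(1L, 1L, 2L, 3L))
  expect_equal(d$ng, 3L)
  const <- discretize(volume_grid(array(7, c(3, 3, 3))),
                      mask_volume(array(1L, c(3, 3, 3))), 25)
  expect_true(all(const$levels == 1L))
  expect_equal(const$ng, 1L)
  expect_error(discretize(v, m, 0), "positive")
  # histogram of levels matches direct re-binning
  set.seed(31)
  vv <- rand_volume(c(6, 6, 6), seed = 31)
  mm <- rand_mask(c(6, 6, 6), seed = 32)
  d2 <- discretize(vv, mm, 40)
  x <- vv$values[mm$values == 1L]
  direct <- as.vector(table(floor((x - min(x)) / 40) + 1))
  expect_equal(as.vector(table(d2$levels[mm$values == 1L])), direct)
})

test_that("first-order features match hand values and a direct oracle", {
  v <- volume_grid(array(c(1, 2, 3, 0, 0, 0, 0, 0), c(2, 2, 2)))
  m <- mask_volume(array(c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L), c(2, 2, 2)))
  fo <- first_order_features(v, m)
  expect_equal(unname(fo["Mean"]), 2)
  expect_equal(unname(fo["Range"]), 2)
  expect_equal(unname(fo["Variance"]), 2 / 3)  # population convention
  # constant ROI
  cv <- volume_grid(array(5, c(3, 3, 3)))
  cm <- mask_volume(array(1L, c(3, 3, 3)))
  foc <- suppressWarnings(first_order_features(cv, cm))
  expect_equal(unname(foc["Variance"]), 0)
  expect_equal(unname(foc["Uniformity"]), 1)
  expect_equal(unname(foc["Entropy"]), 0)
  # random ROI against an independently coded direct-summation oracle
  set.seed(7)
  vv <- rand_volume(c(8, 8, 8), spacing = c(0.7, 0.8, 1.1), seed = 7)
  mm <- rand_mask(c(8, 8, 8), spacing = c(0.7, 0.8, 1.1), seed = 8,
                  p = 0.4)
  x <- vv$values[mm$values == 1L]
  got <- first_order_features(vv, mm, bin_width = 30)
  lev <- floor((x - min(x)) / 30)
  p <- as.vector(table(lev)) / length(x)
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  rob <- x[x >= q[1] & x <= q[5]]
  want <- c(sum(x^2), prod(c(0.7, 0.8, 1.1)) * sum(x^2),
            -sum(p * log2(p)), min(x), q[1], q[5], max(x), mean(x), q[3],
            q[4] - q[2], max(x) - min(x), mean(abs(x - mean(x))),
            mean(abs(rob - mean(rob))), sqrt(mean(x^2)),
            mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5,
            mean((x - mean(x))^4) / mean((x - mean(x))^2)^2,
            mean((x - mean(x))^2), sum(p^2))
  expect_equal(unname(got), want, tolerance = 1e-9)
  # single voxel: NaN skewness/kurtosis with a warning, not an error
  sm <- mask_volume(array(c(1L, rep(0L, 7)), c(2, 2, 2)))
  sv <- volume_grid(array(1, c(2, 2, 2)))
  expect_warning(fo1 <- first_order_features(sv, sm), "undefined")
  expect_true(is.nan(fo1[["Skewness"]]))
})

test_that("shape features reproduce analytic solids", {
  sh1 <- suppressWarnings(
    shape_features(mask_volume(array(c(rep(0L, 13), 1L, rep(0L, 13)),
                                     c(3, 3, 3)))))
  expect_equal(unname(sh1["VoxelVolume"]), 1)
  expect_true(is.nan(sh1[["MeshVolume"]]))
  sph <- sphere_mask(10, spacing = 0.5)
  sh <- shape_features(sph)
  expect_gt(sh[["Sphericity"]], 0.97)
  expect_lte(sh[["Sphericity"]], 1.0)
  expect_lt(abs(sh[["MeshVolume"]] / (pi * 10^3 / 6) - 1), 0.03)
  expect_lt(abs(sh[["Maximum3DDiameter"]] - 10), 0.6)
  # PCA axis length of a uniform ball: 4 * sqrt(r^2 / 5)
  expect_lt(abs(sh[["MajorAxisLength"]] - 4 * 5 / sqrt(5)), 0.3)
  # prolate ellipsoid with semi-axes (10, 5, 5) mm
  n <- 36
  ax <- seq_len(n) - (n + 1) / 2
  r2 <- outer(outer((ax / 10)^2, (ax / 5)^2, `+`), (ax / 5)^2, `+`)
  ell <- mask_volume(array(as.integer(r2 <= 1), rep(n, 3)))
  she <- shape_features(ell)
  expect_lt(abs(she[["Elongation"]] - 0.5), 0.025)
  expect_lt(abs(she[["Flatness"]] - 0.5), 0.025)
})

test_that("shape names and axis ordering are stable", {
  sph <- sphere_mask(8, spacing = 1)
  sh <- shape_features(sph)
  expect_named(sh, c("MeshVolume", "VoxelVolume", "SurfaceArea",
                     "SurfaceVolumeRatio", "Sphericity",
                     "Maximum3DDiameter", "Maximum2DDiameterSlice",
                     "Maximum2DDiameterColumn", "Maximum2DDiameterRow",
                     "MajorAxisLength", "MinorAxisLength",
                     "LeastAxisLength", "Elongation", "Flatness"))
  expect_equal(sh[["SurfaceVolumeRatio"]],
               sh[["SurfaceArea"]] / sh[["MeshVolume"]])
})
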