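test_that("Dice formula cases are exact", {
  m <- rand_mask(c(6, 6, 6), seed = 1, p = 0.4)
  expect_equal(dice(m, m), 1)
  a <- mask_volume(array(0L, c(4, 4, 4)))
  b <- mask_volume(array(0L, c(4, 4, 4)))
  a$values[1:2, 1:2, 1:2] <- 1L
  b$values[3:4, 3:4, 3:4] <- 1L
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 8, overlap 4 -> 0.5
  b2 <- mask_volume(array(0L, c(4, 4, 4)))
  b2$values[1:2, 1:2, 2:3] <- 1L
  expect_equal(dice(a, b2), 0.5)
  expect_equal(dice(a, b2), dice(b2, a))
  empty <- mask_volume(array(0L, c(4, 4, 4)))
  expect_error(dice(empty, empty), "empty")
})

test_that("diameter estimation recovers analytic in-plane extents", {
  sph <- sphere_mask(10, spacing = 0.5)
  expect_lt(abs(estimate_diameter(sph) - 1.0), 0.05)
  one <- mask_volume(array(0L, c(5, 5, 5)))
  one$values[3, 3, 3] <- 1L
  expect_equal(estimate_diameter(one), 0.1)
  # 20 x 10 mm in-plane ellipse -> (2.0 + 1.0) / 2 = 1.5 cm
  n <- 31
  ax <- seq_len(n) - 16
  inplane <- outer((ax / 10)^2, (ax / 5)^2, `+`)
  ell <- array(0L, c(n, n, 3))
  ell[, , 2] <- as.integer(inplane <= 1)
  expect_lt(abs(estimate_diameter(mask_volume(ell)) - 1.5), 0.075)
})

test_that("Lin's CCC matches hand values and symmetry cases", {
  x <- c(1, 2, 3)
  expect_equal(lin_ccc(x, x), 1)
  expect_equal(lin_ccc(x, c(2, 3, 4)), 4 / 7, tolerance = 1e-12)
  z <- c(-1, 0, 1)
  expect_equal(lin_ccc(z, -z), -1)
  expect_equal(lin_ccc(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(lin_ccc(c(2, 2, 2), c(3, 3, 3)), 0)
})

test_that("OCCC reduces to Lin's CCC at J = 2 and detects identity", {
  set.seed(10)
  for (r in 1:100) {
    mm <- matrix(rnorm(2 * (2 + r %% 8)), ncol = 2)
    expect_equal(as.numeric(occc(mm)), lin_ccc(mm[, 1], mm[, 2]),
                 tolerance = 1e-12)
  }
  mm <- matrix(rnorm(15), 5, 3)
  mm[, 2] <- mm[, 1]
  mm[, 3] <- mm[, 1]
  expect_equal(as.numeric(occc(mm)), 1)
  mm[3, 3] <- mm[3, 3] + 0.5
  expect_lt(as.numeric(occc(mm)), 1)
})

test_that("OCCC equals the weighted pairwise-CCC oracle", {
  set.seed(11)
  for (J in 3:5) for (r in 1:10) {
    mm <- matrix(rnorm(J * 8, sd = r), 8, J) +
      matrix(rep(rnorm(8, sd = 2), J), 8)
    expect_equal(as.numeric(occc(mm)), oracle_occc_pairwise(mm),
                 tolerance = 1e-12)
  }
  # the spec-sheet example: two identical columns plus a shifted one
  mm <- cbind(1:4, 1:4, 2:5)
  expect_equal(as.numeric(occc(mm)), oracle_occc_pairwise(mm),
               tolerance = 1e-12)
})

test_that("OCCC is invariant to a common positive affine transform", {
  set.seed(12)
  mm <- matrix(rnorm(40), 10, 4)
  o1 <- as.numeric(occc(mm))
  o2 <- as.numeric(occc(3.7 * mm + 11))
  expect_equal(o1, o2, tolerance = 1e-10)
})

test_that("OCCC drops incomplete rows with a report", {
  set.seed(13)
  mm <- matrix(rnorm(30), 10, 3)
  mm[4, 2] <- NaN
  o <- occc(mm)
  expect_equal(attr(o, "n_dropped"), 1L)
  expect_equal(as.numeric(o), as.numeric(occc(mm[-4, ])),
               tolerance = 1e-12)
})

test_that("ICC(2,1) matches its mean-squares definition", {
  set.seed(14)
  x <- rnorm(30)
  expect_equal(icc_agreement(cbind(x, x))$icc, 1)
  # shift penalised under absolute agreement; direct formula oracle
  y <- x + 1
  mm <- cbind(x, y)
  n <- 30; k <- 2
  grand <- mean(mm)
  msr <- k * sum((rowMeans(mm) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(mm) - grand)^2) / (k - 1)
  mse <- sum((mm - outer(rowMeans(mm), rep(1, k)) -
                outer(rep(1, n), colMeans(mm)) + grand)^2) /
    ((n - 1) * (k - 1))
  want <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  got <- icc_agreement(mm)
  expect_equal(got$icc, want, tolerance = 1e-12)
  expect_lt(got$icc, 1)
  expect_true(got$lower <= got$icc && got$icc <= got$upper)
  # independent columns: small ICC at n = 200
  set.seed(15)
  hits <- sum(vapply(1:20, function(r) {
    mm0 <- matrix(rnorm(400), 200, 2)
    abs(icc_agreement(mm0)$icc) < 0.2
  }, TRUE))
  expect_gte(hits, 19)
  # degenerate between-subject variance
  expect_warning(z <- icc_agreement(matrix(rep(c(1, 2), each = 5), 5, 2)),
                 "zero between-subject")
  expect_equal(z$icc, 0)
})

test_that("stability classification bins are inclusive on the left", {
  expect_equal(as.character(classify_stability(c(0.93, 0.90, 0.89, 0.75,
                                                 0.7499, 0.5, 0.49999,
                                                 -0.3))),
               c("very_good", "very_good", "good", "good", "average",
                 "average", "poor", "poor"))
  cls <- classify_stability(c(0.8, NaN))
  expect_true(is.na(cls[2]))
  expect_equal(attr(cls, "excluded"), 2L)
  # exhaustive and mutually exclusive over finite reals
  set.seed(16)
  x <- runif(500, -1.5, 1.5)
  expect_false(any(is.na(classify_stability(x))))
})

test_that("agreement records summarise all pairs and anchor a reference", {
  ref <- generate_phantom(phantom_spec("SN", 9,
                                       grid_shape = c(24, 24, 24)))$mask
  masks <- c(list(ref), lapply(1:6, function(k)
    simulate_observer_mask(ref, observer_profile(paste0("o", k),
                                                 jitter_mm = 1,
                                                 seed = k), 5)))
  ar <- agreement_record(masks)
  expect_equal(dim(ar$dice), c(7L, 7L))
  expect_equal(sum(upper.tri(ar$dice)), 21L)
  expect_equal(unname(diag(ar$dice)), rep(1, 7))
  expect_equal(ar$dice, t(ar$dice))
  expect_equal(ar$median_dc, median(ar$dice[upper.tri(ar$dice)]))
  expect_length(ar$dc_vs_reference, 6L)
  same <- agreement_record(list(ref, ref, ref))
  expect_equal(same$median_dc, 1)
  # analytic check: nested spheres via pure dilation bias
  dil <- simulate_observer_mask(ref, observer_profile("D", bias_mm = 1), 1)
  ar2 <- agreement_record(list(ref, dil))
  expect_lt(abs(ar2$dice[1, 2] - 2 * 4.5^3 / (4.5^3 + 5.5^3)), 0.08)
})
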