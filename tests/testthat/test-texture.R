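# Matrix-level checks against independent brute-force counters, plus the
# hand-enumerable degenerate cases of each family.

test_that("GLCM matrices equal the brute-force pair counter", {
  for (seed in 1:6) {
    d <- rand_roi(c(6, 6, 6), ng = 4, seed = seed)
    expect_identical(glcm_matrix(d), oracle_glcm(d))
  }
})

test_that("GLCM hand cases: constant ROI and in-plane checkerboard", {
  const <- discretize(volume_grid(array(1, c(3, 3, 3))),
                      mask_volume(array(1L, c(3, 3, 3))), 25)
  f <- glcm_features(const)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["JointEnergy"]), 1)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["Correlation"]), 1)  # documented Ng=1 fallback
  expect_equal(unname(f["MCC"]), 1)
  expect_equal(unname(f["Imc1"]), 0)
  # 4x4x1 checkerboard of levels 1/2: axis pairs always differ (contrast
  # 1), in-plane diagonal pairs always match (contrast 0)
  chk <- array(0, c(4, 4, 1))
  for (i in 1:4) for (j in 1:4) chk[i, j, 1] <- 10 * ((i + j) %% 2)
  d <- discretize(volume_grid(chk), mask_volume(array(1L, c(4, 4, 1))), 10)
  arr <- glcm_matrix(d)
  per_dir_contrast <- vapply(1:13, function(k) {
    P <- matrix(arr[, , k], 2)
    if (sum(P) == 0) return(NA_real_)
    sum(outer(1:2, 1:2, `-`)^2 * P / sum(P))
  }, 0)
  expect_equal(per_dir_contrast[1:2], c(1, 1))    # x and y axis pairs
  expect_equal(per_dir_contrast[4:5], c(0, 0))    # in-plane diagonals
})

test_that("GLRLM matrices equal the brute-force run scanner", {
  for (seed in 1:6) {
    d <- rand_roi(c(6, 6, 6), ng = 3, seed = seed + 10)
    expect_identical(glrlm_matrix(d), oracle_glrlm(d))
  }
})

test_that("GLRLM hand cases: one long run; all-distinct levels", {
  line <- mask_volume(array(1L, c(1, 1, 4)))
  d <- discretize(volume_grid(array(0, c(1, 1, 4))), line, 25)
  arr <- glrlm_matrix(d)
  expect_equal(arr[1, , 3], c(0, 0, 0, 1))  # z direction: single run of 4
  expect_equal(sum(arr[1, 1, -3]), 48)  # other 12 dirs: 4 runs of 1 each
  # per-direction LRE for the axis run: 16
  P <- matrix(arr[, , 3], nrow = 1)
  expect_equal(sum(P * (1:4)^2) / sum(P), 16)
  # strictly increasing values: every run has length 1
  v <- volume_grid(array(seq(0, 175, by = 25), c(8, 1, 1)) + 0)
  dv <- discretize(v, mask_volume(array(1L, c(8, 1, 1))), 25)
  fr <- glrlm_features(dv)
  expect_equal(unname(fr["ShortRunEmphasis"]), 1)
  expect_equal(unname(fr["RunPercentage"]), 1)
})

test_that("GLSZM zone tables equal the flood-fill oracle", {
  for (seed in 1:6) {
    d <- rand_roi(c(6, 6, 6), ng = 3, seed = seed + 20)
    expect_identical(glszm_matrix(d), oracle_glszm(d))
  }
})

test_that("GLSZM hand cases: single zone; two disjoint blobs", {
  const <- discretize(volume_grid(array(1, c(3, 3, 3))),
                      mask_volume(array(1L, c(3, 3, 3))), 25)
  P <- glszm_matrix(const)
  expect_equal(dim(P), c(1L, 27L))
  expect_equal(P[1, 27], 1L)
  f <- glszm_features(const)
  expect_equal(unname(f["ZonePercentage"]), 1 / 27)
  blobs <- array(0L, c(7, 3, 3))
  blobs[1:2, , ] <- 1L
  blobs[6:7, , ] <- 1L
  d2 <- discretize(volume_grid(array(0, c(7, 3, 3))),
                   mask_volume(blobs), 25)
  expect_equal(sum(glszm_matrix(d2)), 2L)  # two zones of one level
})

test_that("GLDM matrices equal the brute-force neighbour counter", {
  for (seed in 1:6) {
    d <- rand_roi(c(6, 6, 6), ng = 3, seed = seed + 30)
    expect_identical(gldm_matrix(d, 0L), oracle_gldm(d, 0L))
  }
  # nonzero alpha changes the count and still matches
  d <- rand_roi(c(6, 6, 6), ng = 4, seed = 55)
  expect_identical(gldm_matrix(d, 1L), oracle_gldm(d, 1L))
})

test_that("GLDM hand cases: full cube centre; isolated voxel", {
  const <- discretize(volume_grid(array(1, c(3, 3, 3))),
                      mask_volume(array(1L, c(3, 3, 3))), 25)
  P <- gldm_matrix(const)
  expect_equal(P[1, 27], 1L)  # centre voxel: dependence 26 -> column 27
  single <- discretize(volume_grid(array(1, c(1, 1, 1))),
                       mask_volume(array(1L, c(1, 1, 1))), 25)
  P1 <- gldm_matrix(single)
  expect_equal(dim(P1), c(1L, 1L))
  expect_equal(P1[1, 1], 1L)
})

test_that("normalised texture probabilities are coherent", {
  d <- rand_roi(c(7, 7, 7), ng = 4, seed = 77)
  arr <- glcm_matrix(d)
  for (k in c(1, 5, 13)) {
    P <- matrix(arr[, , k], d$ng) / sum(arr[, , k])
    expect_equal(sum(P), 1)
    expect_equal(P, t(P))
  }
  f <- glcm_features(d)
  expect_gte(unname(f["Contrast"]), 0)
  # GLRLM: total run length equals the in-mask voxel count per direction
  rl <- glrlm_matrix(d)
  np <- sum(d$mask$values)
  for (k in 1:13) {
    P <- matrix(rl[, , k], d$ng)
    expect_equal(sum(t(P) * seq_len(ncol(P))), np)
  }
  # GLSZM: zone sizes account for every in-mask voxel
  sz <- glszm_matrix(d)
  expect_equal(sum(t(sz) * seq_len(ncol(sz))), np)
})

test_that("first-order features ignore voxel ordering", {
  vv <- rand_volume(c(6, 6, 6), seed = 41)
  mm <- mask_volume(array(1L, c(6, 6, 6)))
  base <- first_order_features(vv, mm)
  set.seed(42)
  perm <- array(sample(as.vector(vv$values)), dim(vv$values))
  expect_equal(first_order_features(volume_grid(perm), mm), base,
               tolerance = 1e-12)
})
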