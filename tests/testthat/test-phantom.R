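test_that("noise-free phantom is a two-level image with a correct mask", {
  spec <- phantom_spec("SN", 10, noise_sd_hu = 0,
                       grid_shape = c(24, 24, 24))
  ph <- generate_phantom(spec)
  inm <- ph$mask$values == 1L
  expect_true(all(ph$volume$values[inm] == spec$nodule_hu))
  expect_true(all(ph$volume$values[!inm] == spec$background_hu))
})

test_that("voxelised sphere volume approaches the analytic ball volume", {
  true_v <- pi * 10^3 / 6
  v_coarse <- sum(sphere_mask(10, spacing = 1)$values) * 1
  v_fine <- sum(sphere_mask(10, spacing = 0.5)$values) * 0.5^3
  expect_lt(abs(v_fine / true_v - 1), 0.05)
  expect_lt(abs(v_fine - true_v), abs(v_coarse - true_v) + 1e-9)
})

test_that("phantom generation is deterministic and class rules hold", {
  spec <- phantom_spec("pSN", 12, grid_shape = c(32, 32, 32), seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$values, b$volume$values)
  expect_identical(a$mask$values, b$mask$values)
  # pSN: solid core brighter than its ground-glass shell
  spec0 <- phantom_spec("pSN", 12, noise_sd_hu = 0,
                        grid_shape = c(32, 32, 32))
  ph <- generate_phantom(spec0)
  vals <- sort(unique(as.vector(ph$volume$values)))
  expect_length(vals, 3)  # background < shell < core
  # oversized nodule is rejected
  expect_error(phantom_spec("SN", 28, grid_shape = c(24, 24, 24)),
               "sizing")
  expect_error(phantom_spec("SN", 31), "30 mm")
  # pGGN attenuation must sit between background and solid
  expect_error(phantom_spec("pGGN", 10, nodule_hu = 100), "pGGN")
})

test_that("zero-perturbation observer reproduces the reference exactly", {
  ref <- generate_phantom(phantom_spec("SN", 8,
                                       grid_shape = c(24, 24, 24)))$mask
  out <- simulate_observer_mask(ref, observer_profile("A"), 1)
  expect_identical(out$values, ref$values)
  expect_equal(dice(out, ref), 1)
})

test_that("pure dilation bias matches the nested-sphere Dice", {
  ref <- sphere_mask(10, spacing = 1, margin_vox = 6)
  out <- simulate_observer_mask(ref, observer_profile("B", bias_mm = 1), 1)
  expect_true(all(out$values[ref$values == 1L] == 1L))  # superset
  # direct voxel-count oracle: ball of radius 6 around the same centre
  n <- dim(ref$values)[1]
  ax <- (seq_len(n) - 1)
  c0 <- (n - 1) / 2
  r2 <- outer(outer((ax - c0)^2, (ax - c0)^2, `+`), (ax - c0)^2, `+`)
  s5 <- sum(r2 <= 25)
  s6 <- sum(r2 <= 36)
  oracle_vox <- 2 * s5 / (s5 + s6)
  analytic <- 2 * 5^3 / (5^3 + 6^3)
  expect_lt(abs(dice(out, ref) - oracle_vox), 0.03)
  expect_lt(abs(dice(out, ref) - analytic), 0.06)
})

test_that("mean Dice decreases monotonically with jitter", {
  ref <- generate_phantom(phantom_spec("SN", 10,
                                       grid_shape = c(28, 28, 28)))$mask
  mean_dice <- vapply(c(0, 1, 2), function(j) {
    pr <- observer_profile("J", jitter_mm = j, seed = 9)
    mean(vapply(1:20, function(s)
      dice(simulate_observer_mask(ref, pr, s), ref), 0))
  }, 0)
  expect_true(all(diff(mean_dice) < 0))
})

test_that("observer simulation is deterministic in its two seeds", {
  ref <- generate_phantom(phantom_spec("SN", 8,
                                       grid_shape = c(24, 24, 24)))$mask
  pr <- observer_profile("B", jitter_mm = 1.5, seed = 4)
  a <- simulate_observer_mask(ref, pr, 17)
  b <- simulate_observer_mask(ref, pr, 17)
  c_ <- simulate_observer_mask(ref, pr, 18)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c_$values))
})

test_that("profile calibration hits its Dice target and flags infeasible", {
  ref <- generate_phantom(phantom_spec("SN", 10,
                                       grid_shape = c(28, 28, 28)))$mask
  exact <- calibrate_profile_to_dice(ref, 1.0)
  expect_equal(exact$jitter_mm, 0)
  expect_equal(exact$bias_mm, 0)
  cal <- calibrate_profile_to_dice(ref, 0.75,
                                   observer_profile("X", seed = 3))
  realized <- mean(vapply(1:20, function(s)
    dice(simulate_observer_mask(ref, cal, s), ref), 0))
  expect_gte(realized, 0.73)
  expect_lte(realized, 0.77)
  expect_error(
    calibrate_profile_to_dice(ref, 0.2, observer_profile("Y", seed = 3),
                              max_jitter_mm = 1),
    "attainable")
})

test_that("smaller phantoms yield lower expected Dice at fixed jitter", {
  pr <- observer_profile("S", jitter_mm = 1.2, seed = 21)
  diams <- seq(4, 20, length.out = 30)
  md <- vapply(seq_along(diams), function(i) {
    ref <- generate_phantom(phantom_spec("SN", diams[i],
                                         grid_shape = c(28, 28, 28),
                                         noise_sd_hu = 0))$mask
    mean(vapply(1:8, function(s)
      dice(simulate_observer_mask(ref, pr, s), ref), 0))
  }, 0)
  expect_gt(cor(diams, md, method = "spearman"), 0)
})

test_that("generate_study writes a reproducible file set", {
  dir1 <- file.path(tempdir(), "study_a")
  dir2 <- file.path(tempdir(), "study_b")
  profs <- list(observer_profile("A"),
                observer_profile("B", jitter_mm = 1, seed = 2),
                observer_profile("C", jitter_mm = 1.5, seed = 3))
  des <- study_design(n_nodules = 5, observer_profiles = profs,
                      grid_shape = c(24, 24, 24), master_seed = 77)
  man1 <- generate_study(des, dir1)
  man2 <- generate_study(des, dir2)
  expect_equal(nrow(man1), 5)
  expect_equal(sum(grepl("_mask_", list.files(dir1))), 5 * 4)
  man2$volume_path <- man1$volume_path  # paths differ, content must not
  for (col in c("nodule_type", "true_diameter_mm", "seed"))
    expect_equal(man1[[col]], man2[[col]])
  v1 <- read_volume(man1$volume_path[1])
  v2 <- read_volume(file.path(dir2, basename(man1$volume_path[1])))
  expect_identical(v1$values, v2$values)
})

test_that("default design reproduces the cohort type composition", {
  des <- study_design()
  expect_equal(des$n_nodules, 232L)
  expect_equal(unname(des$type_proportions), c(81, 40, 111) / 232,
               tolerance = 1e-12)
  set.seed(99)
  draws <- sample(c("SN", "pSN", "pGGN"), 232, replace = TRUE,
                  prob = des$type_proportions)
  counts <- table(factor(draws, levels = c("SN", "pSN", "pGGN")))
  # multinomial sampling band: +-4 sd around the expected counts
  expected <- c(81, 40, 111)
  sds <- sqrt(expected * (1 - expected / 232))
  expect_true(all(abs(counts - expected) <= 4 * sds))
})

test_that("diameter sampling matches its configured median and truncation", {
  des <- study_design()
  set.seed(5)
  d <- sample_diameters(des, 4000)
  expect_true(all(d > 2 & d < 30))
  expect_lt(abs(median(d) - 5.6), 0.25)
  expect_lt(abs(IQR(d) - 4.0), 0.5)
})
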