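# Synthetic CT-like nodule phantoms with simulated observer segmentations.
# Stand-in for a private CT cohort: spherical nodules in three density
# classes on a lung-like background, segmented by simulated observers whose
# boundary errors are smooth random fields in mm.

SN_HU_DEFAULT <- 60       # solid tissue attenuation
PGGN_HU_DEFAULT <- -450   # ground-glass attenuation
BACKGROUND_HU_DEFAULT <- -800
NOISE_SD_HU_DEFAULT <- 20

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

seed_combine <- function(a, b) {
  as.integer(((as.numeric(a) %% 65521) * 32749 + (as.numeric(b) %% 32749)) %%
               2147483647)
}

#' Specification of one synthetic nodule phantom
#'
#' Defines a spherical nodule of one of three CT density classes: `SN`
#' (solid, uniform high attenuation), `pGGN` (pure ground-glass, uniform
#' attenuation strictly between background and solid level) and `pSN`
#' (part-solid: ground-glass shell around a solid core of radius
#' `core_fraction` times the nodule radius). Gaussian noise of sd
#' `noise_sd_hu` is added to the volume; the reference mask is noise-free.
#'
#' @param nodule_type `"SN"`, `"pSN"` or `"pGGN"`.
#' @param diameter_mm nodule diameter, must be below 30 mm (larger lesions
#'   are masses, not nodules, and are excluded).
#' @param center_mm sphere centre in world mm; defaults to the grid centre.
#' @param core_fraction solid-core radius fraction in (0,1), pSN only.
#' @param nodule_hu peak nodule attenuation (HU); class-dependent default.
#' @param background_hu background attenuation (HU).
#' @param noise_sd_hu additive Gaussian noise sd (HU), >= 0.
#' @param grid_shape integer length-3 grid size.
#' @param spacing_mm voxel spacing in mm.
#' @param seed integer noise seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(nodule_type = c("SN", "pSN", "pGGN"),
                         diameter_mm = 10,
                         center_mm = NULL,
                         core_fraction = 0.5,
                         nodule_hu = NULL,
                         background_hu = BACKGROUND_HU_DEFAULT,
                         noise_sd_hu = NOISE_SD_HU_DEFAULT,
                         grid_shape = c(64, 64, 32),
                         spacing_mm = c(1, 1, 1),
                         seed = 1L) {
  nodule_type <- match.arg(nodule_type)
  if (is.null(nodule_hu))
    nodule_hu <- switch(nodule_type, SN = SN_HU_DEFAULT,
                        pSN = SN_HU_DEFAULT, pGGN = PGGN_HU_DEFAULT)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            length(spacing_mm) == 3, all(spacing_mm > 0),
            noise_sd_hu >= 0, diameter_mm > 0)
  if (diameter_mm >= 30)
    stop("diameter_mm must be < 30 mm (lesions of 3 cm or more are masses)")
  extent <- (grid_shape - 1) * spacing_mm
  if (is.null(center_mm)) center_mm <- extent / 2
  r <- diameter_mm / 2
  if (any(center_mm - r <= 0) || any(center_mm + r >= extent))
    stop("sizing error: the ", diameter_mm,
         " mm sphere touches the grid boundary; enlarge grid_shape or ",
         "recentre")
  if (nodule_type == "pGGN" &&
      !(nodule_hu > background_hu && nodule_hu < SN_HU_DEFAULT))
    stop("pGGN attenuation must lie strictly between background (",
         background_hu, ") and the solid level (", SN_HU_DEFAULT, ")")
  if (nodule_type == "pSN" && !(core_fraction > 0 && core_fraction < 1))
    stop("core_fraction must be in (0,1) for pSN")
  structure(list(nodule_type = nodule_type, diameter_mm = diameter_mm,
                 center_mm = center_mm, core_fraction = core_fraction,
                 nodule_hu = nodule_hu, background_hu = background_hu,
                 noise_sd_hu = noise_sd_hu,
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = spacing_mm, seed = as.integer(seed)),
            class = "phantom_spec")
}

# contrast-to-noise ratio of the nodule's outer boundary; for pSN the
# outer (segmented) boundary is the ground-glass shell
phantom_cnr <- function(spec) {
  edge_hu <- switch(spec$nodule_type,
                    SN = spec$nodule_hu,
                    pGGN = spec$nodule_hu,
                    pSN = (spec$background_hu + spec$nodule_hu) / 2)
  abs(edge_hu - spec$background_hu) / max(spec$noise_sd_hu, 1e-8)
}

# Observer difficulty multiplier applied to the jitter amplitude:
# boundary localisation error grows as the edge contrast-to-noise drops
# below the solid-nodule reference (ground-glass interfaces are blurred
# and harder to trace). The boundary error itself stays in absolute mm,
# which is what couples Dice to nodule size: the same error costs a small
# nodule more overlap than a large one.
phantom_difficulty <- function(spec) {
  ref_cnr <- abs(SN_HU_DEFAULT - BACKGROUND_HU_DEFAULT) /
    max(spec$noise_sd_hu, 1e-8)
  (ref_cnr / phantom_cnr(spec))^0.25
}

#' Generate a phantom volume and its reference mask
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([volume_grid()]) and `mask`
#'   ([mask_volume()], voxels whose centres lie within the sphere).
#'   Deterministic given `spec$seed`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  sp <- spec$spacing_mm
  ax <- lapply(1:3, function(a) (seq_len(gs[a]) - 1) * sp[a])
  dx2 <- outer(outer((ax[[1]] - spec$center_mm[1])^2,
                     (ax[[2]] - spec$center_mm[2])^2, `+`),
               (ax[[3]] - spec$center_mm[3])^2, `+`)
  r <- spec$diameter_mm / 2
  inside <- dx2 <= r^2
  vals <- array(spec$background_hu, gs)
  if (spec$nodule_type == "pSN") {
    shell_hu <- (spec$background_hu + spec$nodule_hu) / 2
    vals[inside] <- shell_hu
    vals[dx2 <= (spec$core_fraction * r)^2] <- spec$nodule_hu
  } else {
    vals[inside] <- spec$nodule_hu
  }
  if (spec$noise_sd_hu > 0)
    vals <- vals + with_seed(spec$seed,
                             array(rnorm(prod(gs), 0, spec$noise_sd_hu), gs))
  list(volume = volume_grid(vals, sp),
       mask = mask_volume(array(as.integer(inside), gs), sp))
}

#' An observer's boundary-error profile
#'
#' A simulated observer perturbs the reference segmentation boundary by a
#' spatially smooth random field: `bias_mm` is the systematic signed offset
#' (positive = over-segmentation), `jitter_mm` the random amplitude (sd of
#' the field) and `smoothness` its spatial correlation length in mm.
#' `bias_mm = jitter_mm = 0` reproduces the reference exactly.
#'
#' @param name observer label.
#' @param bias_mm signed systematic boundary offset (mm).
#' @param jitter_mm nonnegative random boundary roughness amplitude (mm).
#' @param smoothness positive correlation length of the error field (mm).
#' @param seed integer observer seed.
#' @param target_dice optional mean Dice target against the reference; used
#'   by the study pipeline to calibrate `jitter_mm` at run time.
#' @return object of class `observer_profile`.
#' @export
observer_profile <- function(name = "observer", bias_mm = 0, jitter_mm = 0,
                             smoothness = 2, seed = 1L,
                             target_dice = NULL) {
  stopifnot(jitter_mm >= 0, smoothness > 0)
  structure(list(name = name, bias_mm = bias_mm, jitter_mm = jitter_mm,
                 smoothness = smoothness, seed = as.integer(seed),
                 target_dice = target_dice),
            class = "observer_profile")
}

smooth_gaussian_field <- function(dm, spacing, smoothness) {
  white <- array(rnorm(prod(dm)), dm)
  resp <- lapply(1:3, function(a) {
    sig <- smoothness / spacing[a]
    R <- max(1L, ceiling(4 * sig))
    off <- -R:R
    g <- exp(-off^2 / (2 * sig^2))
    axis_response(g / sum(g), off, dm[a])
  })
  f <- apply_separable(white, resp[[1]], resp[[2]], resp[[3]])
  s <- sd(as.vector(f))
  if (s > 0) f / s else f
}

#' Simulate one observer's segmentation of a nodule
#'
#' Thresholds the signed Euclidean distance transform of the reference mask
#' (negative inside, mm) at a smooth Gaussian random field with mean
#' `bias_mm` and sd `jitter_mm`: voxels where `sdist <= field` form the
#' observer mask. A perturbation that empties the mask is retried with the
#' jitter halved, up to 5 times. Deterministic given
#' `(profile$seed, nodule_seed)`.
#'
#' @param reference nonempty reference [mask_volume()].
#' @param profile an [observer_profile()].
#' @param nodule_seed integer per-nodule seed.
#' @param difficulty multiplier applied to `jitter_mm` (used by the study
#'   pipeline to couple boundary error to lesion conspicuity).
#' @return a [mask_volume()].
#' @export
simulate_observer_mask <- function(reference, profile, nodule_seed = 1L,
                                   difficulty = 1) {
  stopifnot(inherits(reference, "mask_volume"),
            inherits(profile, "observer_profile"))
  if (sum(reference$values) == 0) stop("empty reference mask")
  jit <- profile$jitter_mm * difficulty
  if (jit == 0 && profile$bias_mm == 0) return(reference)
  dm <- dim(reference$values)
  sp <- reference$spacing
  sdist <- array(cpp_signed_edt(as.integer(reference$values),
                                dm[1], dm[2], dm[3], sp[1], sp[2], sp[3]),
                 dm)
  seed <- seed_combine(profile$seed, nodule_seed)
  for (attempt in 0:5) {
    f <- if (jit > 0)
      with_seed(seed_combine(seed, attempt),
                profile$bias_mm +
                  jit * 0.5^attempt *
                  smooth_gaussian_field(dm, sp, profile$smoothness))
    else array(profile$bias_mm, dm)
    newm <- sdist <= f
    if (any(newm))
      return(mask_volume(array(as.integer(newm), dm), sp,
                         reference$origin))
    if (jit == 0) break
  }
  stop("observer perturbation emptied the mask even after damping; ",
       "profile '", profile$name, "' is too aggressive for this nodule")
}

#' Calibrate an observer profile to a target mean Dice
#'
#' Bisects on `jitter_mm` until the mean Dice of the simulated masks
#' against the reference, over `n_seeds` seeds, is within `tol` of
#' `target_dice`. Mean Dice is monotone non-increasing in jitter, which
#' makes bisection valid.
#'
#' @param reference nonempty reference [mask_volume()].
#' @param target_dice target mean Dice in (0, 1].
#' @param template an [observer_profile()] supplying bias, smoothness and
#'   seed; its jitter is replaced.
#' @param n_seeds number of simulation seeds averaged per evaluation
#'   (>= 20 recommended).
#' @param tol calibration tolerance on the mean Dice.
#' @param max_jitter_mm upper end of the jitter search range.
#' @param difficulty passed through to [simulate_observer_mask()].
#' @return the calibrated [observer_profile()].
#' @export
calibrate_profile_to_dice <- function(reference, target_dice,
                                      template = observer_profile(),
                                      n_seeds = 20, tol = 0.02,
                                      max_jitter_mm = 8,
                                      difficulty = 1) {
  stopifnot(target_dice > 0, target_dice <= 1)
  mean_dice <- function(jit) {
    pr <- template
    pr$jitter_mm <- jit
    mean(vapply(seq_len(n_seeds), function(s)
      dice(simulate_observer_mask(reference, pr, s, difficulty), reference),
      0))
  }
  if (target_dice == 1 && template$bias_mm == 0) {
    out <- template
    out$jitter_mm <- 0
    out$target_dice <- 1
    return(out)
  }
  lo <- 0
  hi <- max_jitter_mm
  d_lo <- mean_dice(lo)
  d_hi <- mean_dice(hi)
  if (target_dice > d_lo + tol || target_dice < d_hi - tol)
    stop(sprintf(paste0("target Dice %.3f unreachable: attainable range ",
                        "is [%.3f, %.3f] for jitter in [0, %g] mm"),
                 target_dice, d_hi, d_lo, max_jitter_mm))
  j <- hi / 2
  for (iter in 1:25) {
    dj <- mean_dice(j)
    if (abs(dj - target_dice) <= tol / 2) break
    if (dj > target_dice) lo <- j else hi <- j
    j <- (lo + hi) / 2
  }
  out <- template
  out$jitter_mm <- j
  out$target_dice <- target_dice
  out
}

#' Default observer panel
#'
#' Seven profiles mirroring a reference reader, five additional readers and
#' one automatic algorithm: the reference is exact (Dice 1 against itself)
#' and the others carry mean-Dice calibration targets of 0.75, 0.76, 0.80,
#' 0.72, 0.66 and 0.69, realised by [calibrate_profile_to_dice()] when a
#' study is generated.
#'
#' @param targets mean Dice targets for the non-reference observers.
#' @param smoothness boundary-error correlation length (mm).
#' @return list of [observer_profile()] objects; the first is the
#'   reference.
#' @export
default_observer_profiles <- function(targets = c(B = 0.75, C = 0.76,
                                                  D = 0.80, E = 0.72,
                                                  F = 0.66, AI = 0.69),
                                      smoothness = 2) {
  out <- list(observer_profile("A", 0, 0, smoothness, seed = 101L,
                               target_dice = 1))
  for (k in seq_along(targets))
    out[[k + 1]] <- observer_profile(names(targets)[k], 0, 1, smoothness,
                                     seed = 101L + k,
                                     target_dice = unname(targets[k]))
  out
}

#' Study design for a synthetic cohort
#'
#' Defaults reproduce the composition of the emulated cohort: 232 nodules
#' with density-class proportions 81/40/111 (SN/pSN/pGGN), diameters drawn
#' from a log-normal law fitted to median 0.56 cm and IQR 0.40 cm and
#' truncated to (2, 30) mm, and a seven-observer panel.
#'
#' @param n_nodules number of nodules.
#' @param type_proportions length-3 probabilities (SN, pSN, pGGN) summing
#'   to 1.
#' @param diameter_median_mm,diameter_iqr_mm log-normal location/spread.
#' @param diameter_range_mm truncation interval (mm).
#' @param observer_profiles list of [observer_profile()]; first entry is
#'   the reference.
#' @param grid_shape,spacing_mm phantom grid geometry.
#' @param noise_sd_hu phantom noise level (HU).
#' @param master_seed integer master seed; every downstream artifact is a
#'   pure function of it.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_nodules = 232,
                         type_proportions = c(SN = 81, pSN = 40,
                                              pGGN = 111) / 232,
                         diameter_median_mm = 5.6,
                         diameter_iqr_mm = 4.0,
                         diameter_range_mm = c(2, 30),
                         observer_profiles = default_observer_profiles(),
                         grid_shape = c(64, 64, 32),
                         spacing_mm = c(1, 1, 1),
                         noise_sd_hu = NOISE_SD_HU_DEFAULT,
                         master_seed = 1L) {
  stopifnot(n_nodules >= 1, length(type_proportions) == 3,
            abs(sum(type_proportions) - 1) < 1e-8,
            length(observer_profiles) >= 2)
  structure(list(n_nodules = as.integer(n_nodules),
                 type_proportions = type_proportions,
                 diameter_median_mm = diameter_median_mm,
                 diameter_iqr_mm = diameter_iqr_mm,
                 diameter_range_mm = diameter_range_mm,
                 observer_profiles = observer_profiles,
                 grid_shape = as.integer(grid_shape),
                 spacing_mm = spacing_mm,
                 noise_sd_hu = noise_sd_hu,
                 master_seed = as.integer(master_seed)),
            class = "study_design")
}

#' Sample nodule diameters from the design's log-normal law
#'
#' The log-normal sigma solves `2 * median * sinh(z * sigma) = IQR` with
#' `z = qnorm(0.75)`; draws outside the truncation interval are rejected
#' and redrawn.
#'
#' @param design a [study_design()].
#' @param n number of diameters.
#' @return numeric vector of diameters in mm (uses the current RNG state).
#' @export
sample_diameters <- function(design, n) {
  mu <- log(design$diameter_median_mm)
  z <- stats::qnorm(0.75)
  sigma <- asinh(design$diameter_iqr_mm /
                   (2 * design$diameter_median_mm)) / z
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(n, mu, sigma)
    out <- c(out, x[x > design$diameter_range_mm[1] &
                      x < design$diameter_range_mm[2]])
  }
  out[seq_len(n)]
}

# resolve target_dice-bearing profiles into concrete jitters against a
# median-diameter solid reference phantom
resolve_profiles <- function(design) {
  needs <- vapply(design$observer_profiles, function(p)
    !is.null(p$target_dice) && p$target_dice < 1 && p$jitter_mm >= 0, TRUE)
  if (!any(needs)) return(design$observer_profiles)
  spec <- phantom_spec("SN", design$diameter_median_mm,
                       grid_shape = design$grid_shape,
                       spacing_mm = design$spacing_mm,
                       noise_sd_hu = design$noise_sd_hu,
                       seed = seed_combine(design$master_seed, 7L))
  ref <- generate_phantom(spec)$mask
  lapply(design$observer_profiles, function(p) {
    if (is.null(p$target_dice) || p$target_dice >= 1) return(p)
    calibrate_profile_to_dice(ref, p$target_dice, template = p)
  })
}

#' Generate a full synthetic study on disk
#'
#' Writes, per nodule, the phantom volume plus the reference mask and one
#' mask per observer (NIfTI by default, NRRD via `config$io_format`),
#' together with `manifest.csv` describing every nodule (id, density
#' class, true diameter, difficulty, file paths, seed). Fully reproducible
#' from `design$master_seed`.
#'
#' @param design a [study_design()].
#' @param out_dir output directory (created if missing).
#' @param config a [radstab_config()] (controls the file format).
#' @return the manifest as a data.frame, invisibly; also written as CSV.
#' @export
generate_study <- function(design, out_dir,
                           config = radstab_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- resolve_profiles(design)
  ext <- if (config$io_format == "nifti") ".nii.gz" else ".nrrd"
  types <- c("SN", "pSN", "pGGN")
  draws <- with_seed(design$master_seed, list(
    type = sample(types, design$n_nodules, replace = TRUE,
                  prob = design$type_proportions),
    diam = sample_diameters(design, design$n_nodules)))
  rows <- vector("list", design$n_nodules)
  for (i in seq_len(design$n_nodules)) {
    nodule_seed <- seed_combine(design$master_seed, i)
    spec <- phantom_spec(draws$type[i], draws$diam[i],
                         grid_shape = design$grid_shape,
                         spacing_mm = design$spacing_mm,
                         noise_sd_hu = design$noise_sd_hu,
                         seed = nodule_seed)
    ph <- generate_phantom(spec)
    id <- sprintf("nodule%03d", i)
    vol_path <- file.path(out_dir, paste0(id, "_ct", ext))
    ref_path <- file.path(out_dir, paste0(id, "_mask_reference", ext))
    write_volume(ph$volume, vol_path)
    write_mask(ph$mask, ref_path)
    diff <- phantom_difficulty(spec)
    obs_paths <- character(length(profiles))
    for (k in seq_along(profiles)) {
      mk <- simulate_observer_mask(ph$mask, profiles[[k]], nodule_seed,
                                   difficulty = diff)
      obs_paths[k] <- file.path(out_dir,
                                paste0(id, "_mask_",
                                       profiles[[k]]$name, ext))
      write_mask(mk, obs_paths[k])
    }
    rows[[i]] <- data.frame(
      nodule_id = id, nodule_type = draws$type[i],
      true_diameter_mm = draws$diam[i], difficulty = diff,
      seed = nodule_seed, volume_path = vol_path,
      reference_mask_path = ref_path,
      t(setNames(obs_paths, paste0("mask_",
                                   vapply(profiles, `[[`, "", "name")))))
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}
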