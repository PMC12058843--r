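#' The canonical feature catalogue
#'
#' Canonical names are `<imagetype>_<class>_<feature>`. Shape features are
#' geometric and therefore computed once, on the original-resolution mask;
#' every image type (original, 5 LoG scales, 8 wavelet sub-bands)
#' contributes 18 first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM =
#' 88 intensity/texture features. Under the defaults the catalogue holds
#' 102 original + 440 LoG + 704 wavelet = 1,246 names.
#'
#' @param config a [radstab_config()].
#' @return data.frame with columns `name`, `image_type`, `class`,
#'   `feature`.
#' @export
feature_catalogue <- function(config = radstab_config()) {
  types <- image_type_catalogue(config)
  rows <- list()
  cls <- list(firstorder = first_order_names, glcm = glcm_feature_names,
              glrlm = glrlm_feature_names, glszm = glszm_feature_names,
              gldm = gldm_feature_names)
  for (ty in types) {
    if (ty == "original")
      rows[[length(rows) + 1L]] <- data.frame(
        image_type = ty, class = "shape", feature = shape_names)
    for (cl in names(cls))
      rows[[length(rows) + 1L]] <- data.frame(
        image_type = ty, class = cl, feature = cls[[cl]])
  }
  out <- do.call(rbind, rows)
  # fixed catalogue order: image type, then shape first on original,
  # then the intensity classes
  out$name <- paste(out$image_type, out$class, out$feature, sep = "_")
  rownames(out) <- NULL
  out[, c("name", "image_type", "class", "feature")]
}

extract_one_image <- function(img, m, config) {
  cr <- crop_to_mask(img, m, pad_voxels = 1L)
  d <- discretize(cr$volume, cr$mask, config$bin_width)
  c(setNames(first_order_features(cr$volume, cr$mask, config$bin_width),
             paste0("firstorder_", first_order_names)),
    setNames(glcm_features(d), paste0("glcm_", glcm_feature_names)),
    setNames(glrlm_features(d), paste0("glrlm_", glrlm_feature_names)),
    setNames(glszm_features(d), paste0("glszm_", glszm_feature_names)),
    setNames(gldm_features(d, config$gldm_alpha),
             paste0("gldm_", gldm_feature_names)))
}

#' Extract features from precomputed image types
#'
#' The workhorse behind [extract_all()]: when many observer masks share one
#' volume, compute [filtered_images()] once and reuse it here per mask.
#' Per-class failures are converted to `NaN` entries (with a warning), so a
#' pathological ROI degrades rather than aborts a study run.
#'
#' @param imgs named list from [filtered_images()].
#' @param m a [mask_volume()] aligned with the images.
#' @param config a [radstab_config()].
#' @return named numeric vector in catalogue order.
#' @export
extract_from_images <- function(imgs, m, config = radstab_config()) {
  cat_df <- feature_catalogue(config)
  out <- setNames(rep(NaN, nrow(cat_df)), cat_df$name)
  sh <- tryCatch(shape_features(m), error = function(e) {
    warning("shape features failed: ", conditionMessage(e))
    setNames(rep(NaN, length(shape_names)), shape_names)
  })
  out[paste0("original_shape_", names(sh))] <- sh
  for (ty in names(imgs)) {
    vals <- tryCatch(extract_one_image(imgs[[ty]], m, config),
                     error = function(e) {
                       warning("extraction failed on image type '", ty,
                               "': ", conditionMessage(e))
                       NULL
                     })
    if (!is.null(vals)) out[paste(ty, names(vals), sep = "_")] <- vals
  }
  out
}

#' Extract the full radiomic feature vector
#'
#' Applies the 14 image types (original, LoG scales, wavelet sub-bands) to
#' the volume and runs every feature class on each, returning exactly the
#' names of [feature_catalogue()] in fixed order. Deterministic: identical
#' inputs give bit-identical vectors.
#'
#' @param v a [volume_grid()].
#' @param m an aligned nonempty [mask_volume()].
#' @param config a [radstab_config()].
#' @return named numeric vector (1,246 entries under the defaults).
#' @export
extract_all <- function(v, m, config = radstab_config()) {
  check_alignment(v, m)
  if (sum(m$values) == 0) stop("empty mask")
  extract_from_images(filtered_images(v, config), m, config)
}
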