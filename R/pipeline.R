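# Study orchestration: generate -> segment -> extract -> agree -> OCCC ->
# classify -> summarise. One OCCC per feature per study, computed across
# observers (columns) over nodules (rows); a per-nodule-type recomputation
# supports the subgroup comparison.

feature_stratum <- function(image_type, class) {
  ifelse(grepl("^log-", image_type), "LOG",
         ifelse(grepl("^wavelet-", image_type), "Wavelet",
                paste0("Original_", class)))
}

feature_strata_levels <- c("Original_firstorder", "Original_shape",
                           "Original_glcm", "Original_glrlm",
                           "Original_glszm", "Original_gldm", "LOG",
                           "Wavelet")

#' Run a complete synthetic stability study
#'
#' For every nodule of the design: generate the phantom, simulate every
#' observer's segmentation, extract the full feature catalogue per
#' observer (filtered images computed once per nodule and shared across
#' observers), and record the pairwise Dice agreement. Then compute one
#' OCCC per feature across observers over all nodules, classify it, and
#' recompute OCCC within each nodule-type stratum. Deterministic given
#' `design$master_seed`.
#'
#' @param design a [study_design()].
#' @param config a [radstab_config()].
#' @param out_dir optional directory; when given, the result tables are
#'   written there as CSV/JSON.
#' @param verbose print per-stage progress.
#' @return object of class `study_result`: list with `design`, `config`,
#'   `nodules` (per-nodule data.frame), `agreement` (list of
#'   [agreement_record()]s), `features` (array nodule x observer x
#'   feature), `occc` (per-feature data.frame with stability class),
#'   `occc_by_type` (matrix feature x type), `catalogue`.
#' @export
run_study <- function(design, config = radstab_config(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  t0 <- Sys.time()
  profiles <- resolve_profiles(design)
  J <- length(profiles)
  obs_names <- vapply(profiles, `[[`, "", "name")
  cat_df <- feature_catalogue(config)
  nf <- nrow(cat_df)
  types <- c("SN", "pSN", "pGGN")
  draws <- with_seed(design$master_seed, list(
    type = sample(types, design$n_nodules, replace = TRUE,
                  prob = design$type_proportions),
    diam = sample_diameters(design, design$n_nodules)))
  feats <- array(NA_real_, c(design$n_nodules, J, nf),
                 dimnames = list(NULL, obs_names, cat_df$name))
  agreement <- vector("list", design$n_nodules)
  est_diam <- numeric(design$n_nodules)
  for (i in seq_len(design$n_nodules)) {
    nodule_seed <- seed_combine(design$master_seed, i)
    spec <- phantom_spec(draws$type[i], draws$diam[i],
                         grid_shape = design$grid_shape,
                         spacing_mm = design$spacing_mm,
                         noise_sd_hu = design$noise_sd_hu,
                         seed = nodule_seed)
    ph <- generate_phantom(spec)
    diff <- phantom_difficulty(spec)
    imgs <- filtered_images(ph$volume, config)
    masks <- vector("list", J)
    for (k in seq_len(J)) {
      masks[[k]] <- simulate_observer_mask(ph$mask, profiles[[k]],
                                           nodule_seed, difficulty = diff)
      feats[i, k, ] <- suppressWarnings(
        extract_from_images(imgs, masks[[k]], config))
    }
    names(masks) <- obs_names
    agreement[[i]] <- agreement_record(masks, reference_index = 1L)
    est_diam[i] <- estimate_diameter(ph$mask)
    if (verbose && i %% 10 == 0)
      message(sprintf("nodule %d/%d (%.1f s elapsed)", i,
                      design$n_nodules,
                      as.numeric(difftime(Sys.time(), t0, "secs"))))
  }
  nodules <- data.frame(
    nodule_id = sprintf("nodule%03d", seq_len(design$n_nodules)),
    nodule_type = factor(draws$type, levels = types),
    true_diameter_mm = draws$diam,
    est_diameter_cm = est_diam,
    median_dc = vapply(agreement, `[[`, 0, "median_dc"))
  safe_occc <- function(mm)
    tryCatch(as.numeric(occc(mm)), error = function(e) NaN)
  occc_all <- vapply(seq_len(nf), function(f)
    safe_occc(feats[, , f, drop = TRUE]), 0)
  occc_df <- data.frame(cat_df,
                        occc = occc_all,
                        stability = classify_stability(occc_all),
                        stratum = factor(feature_stratum(cat_df$image_type,
                                                         cat_df$class),
                                         levels = feature_strata_levels))
  occc_by_type <- sapply(types, function(ty) {
    rows <- which(draws$type == ty)
    if (length(rows) < 2) return(rep(NA_real_, nf))
    vapply(seq_len(nf), function(f)
      safe_occc(feats[rows, , f, drop = TRUE]), 0)
  })
  rownames(occc_by_type) <- cat_df$name
  sr <- structure(list(design = design, config = config,
                       profiles = profiles, nodules = nodules,
                       agreement = agreement, features = feats,
                       occc = occc_df, occc_by_type = occc_by_type,
                       catalogue = cat_df),
                  class = "study_result")
  if (!is.null(out_dir)) write_study_result(sr, out_dir)
  sr
}

#' @export
print.study_result <- function(x, ...) {
  good <- mean(x$occc$occc >= 0.75, na.rm = TRUE)
  cat(sprintf(paste0("<study_result> %d nodules x %d observers, %d ",
                     "features\n  median DC %.3f; good-stability rate ",
                     "%.1f%%\n"),
              nrow(x$nodules), dim(x$features)[2], nrow(x$occc),
              median(x$nodules$median_dc), 100 * good))
  invisible(x)
}

write_study_result <- function(sr, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sr$occc, file.path(out_dir, "occc_per_feature.csv"),
            row.names = FALSE)
  write.csv(stability_table(sr), file.path(out_dir, "stability_table.csv"),
            row.names = FALSE)
  write.csv(dc_table(sr), file.path(out_dir, "dc_table.csv"),
            row.names = FALSE)
  write.csv(sr$nodules, file.path(out_dir, "nodules.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(n_nodules = nrow(sr$nodules),
         observers = vapply(sr$profiles, `[[`, "", "name"),
         master_seed = sr$design$master_seed,
         good_stability_rate = mean(sr$occc$occc >= 0.75, na.rm = TRUE)),
    file.path(out_dir, "study_manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}

#' Stability distribution table
#'
#' Counts and percentages of features per stability bin (OCCC < 0.5,
#' 0.5-0.75, 0.75-0.90, >= 0.90) for each feature stratum and in total,
#' plus the good-stability rate (share with OCCC >= 0.75). Features whose
#' OCCC could not be computed are itemised in the `excluded` column.
#'
#' @param sr a [run_study()] result.
#' @return data.frame, one row per stratum plus a `Total` row.
#' @export
stability_table <- function(sr) {
  df <- sr$occc
  one <- function(sub, label) {
    cls <- classify_stability(sub$occc)
    n_bad <- sum(is.na(cls))
    counts <- table(cls)
    n_ok <- sum(counts)
    data.frame(stratum = label, total = nrow(sub),
               poor = as.integer(counts["poor"]),
               average = as.integer(counts["average"]),
               good = as.integer(counts["good"]),
               very_good = as.integer(counts["very_good"]),
               pct_poor = 100 * counts[["poor"]] / max(n_ok, 1),
               pct_average = 100 * counts[["average"]] / max(n_ok, 1),
               pct_good = 100 * counts[["good"]] / max(n_ok, 1),
               pct_very_good = 100 * counts[["very_good"]] / max(n_ok, 1),
               good_stability_rate =
                 100 * sum(counts[c("good", "very_good")]) / max(n_ok, 1),
               excluded = n_bad)
  }
  rows <- lapply(levels(df$stratum), function(s)
    one(df[df$stratum == s, ], s))
  out <- rbind(do.call(rbind, rows), one(df, "Total"))
  rownames(out) <- NULL
  out
}

#' Per-observer Dice table against the reference
#'
#' Median (IQR) of the reference-anchored Dice per observer, overall and
#' within each nodule density class, with a Kruskal-Wallis p-value across
#' observers per column. The reference observer's own column is omitted
#' (its Dice against itself is identically 1).
#'
#' @param sr a [run_study()] result.
#' @param reference_observer index of the reference (default 1).
#' @return data.frame, one row per non-reference observer plus a p-value
#'   row.
#' @export
dc_table <- function(sr, reference_observer = 1L) {
  J <- dim(sr$features)[2]
  obs <- dimnames(sr$features)[[2]]
  others <- setdiff(seq_len(J), reference_observer)
  # dc[i, k]: Dice of observer k against the reference on nodule i
  dc <- matrix(vapply(sr$agreement, function(ar)
    ar$dice[reference_observer, others], numeric(length(others))),
    ncol = length(others), byrow = TRUE,
    dimnames = list(NULL, obs[others]))
  strata <- list(Total = rep(TRUE, nrow(sr$nodules)),
                 SN = sr$nodules$nodule_type == "SN",
                 pSN = sr$nodules$nodule_type == "pSN",
                 pGGN = sr$nodules$nodule_type == "pGGN")
  fmt <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) return(NA_character_)
    sprintf("%.2f (%.2f)", median(x), stats::IQR(x))
  }
  out <- data.frame(observer = obs[others])
  pvals <- c()
  for (s in names(strata)) {
    sel <- strata[[s]]
    if (sum(sel) < 2) {
      out[[s]] <- NA_character_
      pvals[s] <- NA_real_
      next
    }
    out[[s]] <- vapply(colnames(dc), function(o) fmt(dc[sel, o]), "")
    long <- data.frame(dc = as.vector(dc[sel, , drop = FALSE]),
                       obs = rep(colnames(dc), each = sum(sel)))
    pvals[s] <- if (length(unique(long$dc)) > 1)
      suppressWarnings(kruskal.test(dc ~ factor(obs), long)$p.value)
      else NA_real_
  }
  prow <- data.frame(observer = "p_value")
  for (s in names(strata))
    prow[[s]] <- ifelse(is.na(pvals[s]), NA_character_,
                        format.pval(pvals[s], digits = 3, eps = 1e-3))
  rbind(out, prow)
}

#' Diameter versus median Dice analysis
#'
#' Spearman correlation between the true nodule diameter (cm) and the
#' per-nodule median Dice over all observer pairs, plus the ordinary
#' least-squares slope of median Dice on diameter.
#'
#' @param sr a [run_study()] result with at least 10 nodules.
#' @return list with `spearman_rs`, `p`, `slope`, `intercept`, `n`.
#' @export
dc_diameter_analysis <- function(sr) {
  stopifnot(nrow(sr$nodules) >= 10)
  d_cm <- sr$nodules$true_diameter_mm / 10
  dc <- sr$nodules$median_dc
  if (length(unique(dc)) < 2)
    return(list(spearman_rs = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(dc)))
  ct <- suppressWarnings(cor.test(d_cm, dc, method = "spearman"))
  fit <- coef(lm(dc ~ d_cm))
  list(spearman_rs = unname(ct$estimate), p = ct$p.value,
       slope = unname(fit[2]), intercept = unname(fit[1]),
       n = length(dc))
}

#' Compare OCCC distributions between feature subgroups
#'
#' Median (IQR) OCCC per group, a Kruskal-Wallis test across groups and
#' pairwise rank-sum post-hoc tests with Bonferroni adjustment. Groupings:
#' `feature_class` (the 8 strata), `image_type` (original/LoG/wavelet),
#' `wavelet_subband` (8 x 88 features), `log_sigma` (5 x 88), and
#' `nodule_type`, which uses the per-type OCCC recomputation. Empty groups
#' are dropped with a note.
#'
#' @param sr a [run_study()] result.
#' @param grouping one of the groupings above.
#' @return list with `table` (per-group summary), `kruskal_p`, `pairwise`
#'   (Bonferroni-adjusted p matrix) and `dropped`.
#' @export
subgroup_occc_comparison <- function(sr,
                                     grouping = c("feature_class",
                                                  "image_type",
                                                  "wavelet_subband",
                                                  "log_sigma",
                                                  "nodule_type")) {
  grouping <- match.arg(grouping)
  df <- sr$occc
  if (grouping == "feature_class") {
    values <- df$occc
    groups <- as.character(df$stratum)
  } else if (grouping == "image_type") {
    values <- df$occc
    groups <- ifelse(grepl("^log-", df$image_type), "LOG",
                     ifelse(grepl("^wavelet-", df$image_type), "Wavelet",
                            "Original"))
  } else if (grouping == "wavelet_subband") {
    sel <- grepl("^wavelet-", df$image_type)
    values <- df$occc[sel]
    groups <- sub("^wavelet-", "", df$image_type[sel])
  } else if (grouping == "log_sigma") {
    sel <- grepl("^log-", df$image_type)
    values <- df$occc[sel]
    groups <- df$image_type[sel]
  } else {
    ob <- sr$occc_by_type
    values <- as.vector(ob)
    groups <- rep(colnames(ob), each = nrow(ob))
  }
  ok <- is.finite(values)
  values <- values[ok]
  groups <- groups[ok]
  tab <- table(groups)
  dropped <- names(tab)[tab < 2]
  keep <- !(groups %in% dropped)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2)
    stop("fewer than 2 usable groups for grouping '", grouping, "'")
  summ <- do.call(rbind, lapply(levels(groups), function(g) {
    x <- values[groups == g]
    data.frame(group = g, n = length(x), median_occc = median(x),
               iqr_occc = stats::IQR(x))
  }))
  kw <- kruskal.test(values, groups)
  pw <- suppressWarnings(
    pairwise.wilcox.test(values, groups, p.adjust.method = "bonferroni"))
  list(table = summ, kruskal_p = kw$p.value, pairwise = pw$p.value,
       dropped = dropped, grouping = grouping)
}
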