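# Multi-rater agreement statistics: Dice overlap, diameter estimation,
# ICC, Lin's CCC and its multi-observer generalisation (OCCC), and the
# OCCC-based stability classification.

#' Dice overlap between two masks
#'
#' `2|A intersect B| / (|A| + |B|)`, symmetric, in `[0, 1]`.
#'
#' @param a,b aligned [mask_volume()]s; at least one must be nonempty.
#' @return scalar Dice coefficient.
#' @export
dice <- function(a, b) {
  check_alignment(a, b)
  na <- sum(a$values)
  nb <- sum(b$values)
  if (na + nb == 0) stop("both masks are empty: Dice undefined")
  2 * sum(a$values == 1L & b$values == 1L) / (na + nb)
}

#' Estimate the nodule diameter from a mask
#'
#' Clinical long/short-axis convention: on the axial (xy) slice with the
#' largest in-plane extent (ties broken toward the lowest slice index), the
#' maximum pairwise distance between in-mask voxel centres gives the long
#' diameter; the maximal extent perpendicular to that direction gives the
#' short diameter. Both are floored at one voxel spacing so a single-voxel
#' mask reports its voxel size. Returns their mean in cm.
#'
#' @param m a nonempty [mask_volume()].
#' @return scalar diameter estimate in cm.
#' @export
estimate_diameter <- function(m) {
  stopifnot(inherits(m, "mask_volume"))
  if (sum(m$values) == 0) stop("empty mask: no diameter")
  idx <- which(m$values == 1L, arr.ind = TRUE)
  sp <- m$spacing
  floor_mm <- mean(sp[1:2])
  best <- list(dlong = -1, slice = NA, dir = c(1, 0), pts = NULL)
  for (z in sort(unique(idx[, 3]))) {
    pts <- idx[idx[, 3] == z, 1:2, drop = FALSE]
    pts <- cbind((pts[, 1] - 1) * sp[1], (pts[, 2] - 1) * sp[2])
    hull <- if (nrow(pts) >= 3) pts[grDevices::chull(pts), , drop = FALSE]
      else pts
    dlong <- 0
    dir <- c(1, 0)
    if (nrow(hull) >= 2) {
      dd <- as.matrix(stats::dist(hull))
      w <- which(dd == max(dd), arr.ind = TRUE)[1, ]
      dlong <- max(dd)
      if (dlong > 0) dir <- (hull[w[2], ] - hull[w[1], ]) / dlong
    }
    if (dlong > best$dlong + 1e-12) {
      best <- list(dlong = dlong, slice = z, dir = dir, pts = hull)
    }
  }
  perp <- c(-best$dir[2], best$dir[1])
  proj <- as.matrix(best$pts) %*% perp
  dshort <- diff(range(proj))
  dlong <- max(best$dlong, floor_mm)
  dshort <- max(dshort, floor_mm)
  (dlong + dshort) / 2 / 10
}

#' Lin's concordance correlation coefficient
#'
#' `2 s_xy / (s_x^2 + s_y^2 + (m_x - m_y)^2)`. Population (1/n) moments by
#' default so that the two-observer OCCC reduction is exact; sample
#' moments are available via `moments = "sample"`. Two equal constant
#' series give 1; two different constants give 0.
#'
#' @param x,y numeric vectors of equal length >= 2, finite.
#' @param moments `"population"` or `"sample"`.
#' @return scalar in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  stopifnot(length(x) == length(y), length(x) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  f <- if (moments == "population") (n - 1) / n else 1
  sx <- var(x) * f
  sy <- var(y) * f
  sxy <- cov(x, y) * f
  den <- sx + sy + (mean(x) - mean(y))^2
  if (den == 0) return(1)  # identical constant series
  2 * sxy / den
}

#' Overall concordance correlation coefficient (OCCC)
#'
#' Generalisation of Lin's CCC to `J >= 2` observers:
#' `OCCC = 2 sum_{j<k} s_jk / ((J-1) sum_j s_j^2 + sum_{j<k} (m_j - m_k)^2)`
#' with population moments, which makes the `J = 2` case equal [lin_ccc()]
#' exactly. Equals 1 iff all columns are identical; it can be negative and
#' is reported as computed (classified as poor, not clamped). Rows
#' containing non-finite values are dropped; the count is attached as
#' attribute `n_dropped`.
#'
#' @param mm numeric matrix, subjects in rows, observers in columns
#'   (`J >= 2`, at least 2 complete rows).
#' @param moments `"population"` or `"sample"`.
#' @return scalar OCCC with attribute `n_dropped`.
#' @export
occc <- function(mm, moments = c("population", "sample")) {
  moments <- match.arg(moments)
  mm <- as.matrix(mm)
  J <- ncol(mm)
  stopifnot(J >= 2)
  ok <- apply(is.finite(mm), 1, all)
  dropped <- sum(!ok)
  mm <- mm[ok, , drop = FALSE]
  n <- nrow(mm)
  if (n < 2) stop("fewer than 2 complete rows: OCCC undefined")
  f <- if (moments == "population") (n - 1) / n else 1
  cv <- stats::cov(mm) * f
  mns <- colMeans(mm)
  num <- 2 * sum(cv[upper.tri(cv)])
  den <- (J - 1) * sum(diag(cv)) +
    sum(outer(mns, mns, `-`)[upper.tri(cv)]^2)
  out <- if (den == 0) 1 else num / den
  attr(out, "n_dropped") <- dropped
  out
}

#' Two-way random-effects, absolute-agreement, single-measure ICC
#'
#' ICC(2,1) from the standard mean-squares decomposition of the subject x
#' rater table, with the conventional F-based 95% confidence interval.
#' Returns 0 (with a warning) when there is no between-subject variance.
#'
#' @param mm numeric matrix, `n >= 3` subjects in rows, raters in columns.
#' @param conf confidence level for the interval.
#' @return list with `icc`, `lower`, `upper`, `n`, `k`.
#' @export
icc_agreement <- function(mm, conf = 0.95) {
  mm <- as.matrix(mm)
  mm <- mm[apply(is.finite(mm), 1, all), , drop = FALSE]
  n <- nrow(mm)
  k <- ncol(mm)
  stopifnot(n >= 3, k >= 2)
  grand <- mean(mm)
  rmean <- rowMeans(mm)
  cmean <- colMeans(mm)
  msr <- k * sum((rmean - grand)^2) / (n - 1)
  msc <- n * sum((cmean - grand)^2) / (k - 1)
  sse <- sum((mm - outer(rmean, rep(1, k)) -
                outer(rep(1, n), cmean) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * abs(grand + 1)) {
    warning("zero between-subject variance: ICC set to 0")
    return(list(icc = 0, lower = NA_real_, upper = NA_real_, n = n, k = k))
  }
  r <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  if (r < 1) {
    a <- k * r / (n * (1 - r))
    b <- 1 + k * r * (n - 1) / (n * (1 - r))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    lower <- upper <- 1
  }
  list(icc = r, lower = lower, upper = upper, n = n, k = k)
}

stability_levels <- c("poor", "average", "good", "very_good")

#' Classify OCCC values into stability classes
#'
#' poor: OCCC < 0.5; average: 0.5 <= OCCC < 0.75; good:
#' 0.75 <= OCCC < 0.90; very_good: OCCC >= 0.90. Boundaries are inclusive
#' on the left, negative values map to poor, and non-finite values yield
#' `NA` (excluded, with the reason recorded in the `excluded` attribute).
#'
#' @param occc_value numeric vector of OCCC values.
#' @return factor with levels poor/average/good/very_good; `NA` for
#'   non-finite input.
#' @export
classify_stability <- function(occc_value) {
  out <- cut(as.numeric(occc_value),
             breaks = c(-Inf, 0.5, 0.75, 0.90, Inf),
             labels = stability_levels, right = FALSE)
  bad <- !is.finite(occc_value)
  if (any(bad)) {
    out[bad] <- NA
    attr(out, "excluded") <- which(bad)
  }
  out
}

#' Pairwise Dice agreement record for one nodule
#'
#' Full `J x J` pairwise Dice matrix over the observers, the per-nodule
#' median over the `J(J-1)/2` distinct pairs, and the `J - 1`
#' reference-anchored Dice values. Empty masks are excluded with a
#' warning.
#'
#' @param masks list of `J >= 2` aligned [mask_volume()]s.
#' @param reference_index index of the reference observer (default 1).
#' @param observer_names optional labels.
#' @return object of class `agreement_record` with elements `dice`
#'   (matrix), `median_dc`, `dc_vs_reference`, `excluded`.
#' @export
agreement_record <- function(masks, reference_index = 1L,
                             observer_names = NULL) {
  J <- length(masks)
  stopifnot(J >= 2)
  if (is.null(observer_names))
    observer_names <- if (!is.null(names(masks))) names(masks)
      else paste0("obs", seq_len(J))
  empty <- vapply(masks, function(m) sum(m$values) == 0, TRUE)
  if (any(empty))
    warning("excluding empty observer mask(s): ",
            paste(observer_names[empty], collapse = ", "))
  keep <- which(!empty)
  if (length(keep) < 2) stop("fewer than 2 nonempty masks")
  D <- matrix(NA_real_, J, J, dimnames = list(observer_names,
                                              observer_names))
  for (a in keep) D[a, a] <- 1
  for (a in keep) for (b in keep) if (a < b)
    D[a, b] <- D[b, a] <- dice(masks[[a]], masks[[b]])
  ut <- D[upper.tri(D)]
  ref_ok <- reference_index %in% keep
  structure(list(
    dice = D,
    median_dc = median(ut, na.rm = TRUE),
    dc_vs_reference = if (ref_ok)
      D[reference_index, setdiff(seq_len(J), reference_index)]
      else rep(NA_real_, J - 1),
    excluded = observer_names[empty]),
    class = "agreement_record")
}
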