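# The four gray-level texture-matrix families. Matrix counting runs in C++
# (see src/radstab_core.cpp); feature formulas live here. GLCM and GLRLM are
# computed per displacement direction (13 unique 3D directions, distance 1)
# and the feature values averaged over directions; GLSZM and GLDM are single
# matrices per ROI.

glcm_feature_names <- c(
  "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
  "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
  "DifferenceEntropy", "DifferenceVariance", "JointEnergy", "JointEntropy",
  "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn", "InverseVariance",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares", "MCC")

glrlm_feature_names <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis")

glszm_feature_names <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis")

gldm_feature_names <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis")

stopifnot_roi <- function(d) {
  if (!inherits(d, "discretized_roi")) stop("expected a discretized_roi")
}

#' Gray-level co-occurrence matrices
#'
#' Symmetrised co-occurrence counts of in-mask voxel pairs at distance 1,
#' one `Ng x Ng` slice per displacement direction (each unordered pair is
#' counted once per order, so slices are symmetric integer matrices).
#'
#' @param d a [discretize()]d ROI.
#' @return integer array `Ng x Ng x 13`.
#' @export
glcm_matrix <- function(d) {
  stopifnot_roi(d)
  dm <- dim(d$levels)
  cnt <- cpp_glcm_counts(as.integer(d$levels), dm[1], dm[2], dm[3], d$ng)
  arr <- array(cnt, c(d$ng, d$ng, 13))
  for (k in 1:13) arr[, , k] <- arr[, , k] + t(arr[, , k])
  arr
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  P <- P / tot
  i <- seq_len(ng)
  px <- rowSums(P)
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  ip <- outer(i, i, `+`)
  im <- outer(i, i, `-`)
  ps <- as.vector(rowsum(as.vector(P), as.vector(ip)))        # k = 2..2ng
  pd <- as.vector(rowsum(as.vector(P), as.vector(abs(im))))   # k = 0..ng-1
  ks <- 2:(2 * ng)
  kd <- 0:(ng - 1)
  plog <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  hx <- plog(px)
  hxy <- plog(P)
  occ <- px > 0
  lpxy <- outer(px[occ], px[occ])
  Pi <- P[occ, occ, drop = FALSE]
  hxy1 <- -sum(Pi[Pi > 0] * log2(lpxy[Pi > 0]))
  hxy2 <- plog(lpxy)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(1 - exp(-2 * max(hxy2 - hxy, 0)))
  da <- sum(kd * pd)
  corr <- if (sig2 > 0) (sum(outer(i, i) * P) - mu^2) / sig2 else 1
  mcc <- {
    if (sum(occ) < 2) 1 else {
      # Q(a,b) = sum_k P(a,k) P(b,k) / (px(a) px(k))
      Q2 <- sweep(Pi, 1, px[occ], `/`) %*% t(sweep(Pi, 2, px[occ], `/`))
      ev <- sort(Re(eigen(Q2, only.values = TRUE)$values),
                 decreasing = TRUE)
      sqrt(max(ev[2], 0))
    }
  }
  c(Autocorrelation = sum(outer(i, i) * P),
    JointAverage = mu,
    ClusterProminence = sum((ip - 2 * mu)^4 * P),
    ClusterShade = sum((ip - 2 * mu)^3 * P),
    ClusterTendency = sum((ip - 2 * mu)^2 * P),
    Contrast = sum(im^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = plog(pd),
    DifferenceVariance = sum((kd - da)^2 * pd),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + im^2)),
    Idmn = sum(P / (1 + im^2 / ng^2)),
    Id = sum(P / (1 + abs(im))),
    Idn = sum(P / (1 + abs(im) / ng)),
    InverseVariance = sum(P[im != 0] / im[im != 0]^2),
    MaximumProbability = max(P),
    SumAverage = sum(ks * ps),
    SumEntropy = plog(ps),
    SumSquares = sig2,
    MCC = mcc)
}

#' GLCM features (24), averaged over the 13 directions
#'
#' Per direction the symmetrised matrix is normalised to a joint
#' probability and the 24 standard co-occurrence features are computed;
#' values are then averaged with equal weight over directions that contain
#' at least one voxel pair. Degenerate single-level ROIs fall back to
#' Correlation 1, Imc1 0, Imc2 0, MCC 1.
#'
#' @param d a [discretize()]d ROI.
#' @return named numeric vector of length 24.
#' @export
glcm_features <- function(d) {
  arr <- glcm_matrix(d)
  vals <- matrix(NA_real_, 13, length(glcm_feature_names))
  for (k in 1:13) {
    P <- matrix(arr[, , k], nrow = dim(arr)[1])
    if (sum(P) == 0) next
    vals[k, ] <- glcm_features_one(P)
  }
  ok <- !is.na(vals[, 1])
  if (!any(ok)) {
    warning("no co-occurring voxel pairs in any direction; GLCM NaN")
    return(setNames(rep(NaN, length(glcm_feature_names)),
                    glcm_feature_names))
  }
  setNames(colMeans(vals[ok, , drop = FALSE]), glcm_feature_names)
}

#' Gray-level run-length matrices
#'
#' Counts of maximal equal-level in-mask runs per gray level and run
#' length, one slice per direction. Trailing all-zero run-length columns
#' are trimmed jointly across directions.
#'
#' @param d a [discretize()]d ROI.
#' @return integer array `Ng x Lmax x 13`.
#' @export
glrlm_matrix <- function(d) {
  stopifnot_roi(d)
  dm <- dim(d$levels)
  maxlen <- max(dm)
  cnt <- cpp_glrlm_counts(as.integer(d$levels), dm[1], dm[2], dm[3], d$ng,
                          maxlen)
  arr <- array(cnt, c(d$ng, maxlen, 13))
  used <- which(apply(arr, 2, sum) > 0)
  lmax <- if (length(used)) max(used) else 1L
  arr[, seq_len(lmax), , drop = FALSE]
}

rl_family_features <- function(P, np) {
  # shared formula core for GLRLM (runs) / GLSZM (zones) / GLDM
  # (dependencies): P is level x size, np the in-mask voxel count
  nr <- sum(P)
  i <- seq_len(nrow(P))
  j <- seq_len(ncol(P))
  p <- P / nr
  pg <- rowSums(p)
  pr <- colSums(p)
  mu_i <- sum(i * pg)
  mu_j <- sum(j * pr)
  plog <- function(q) { q <- q[q > 0]; -sum(q * log2(q)) }
  vals <- c(
    sum(t(t(P) / j^2)) / nr,
    sum(t(t(P) * j^2)) / nr,
    sum(rowSums(P)^2) / nr,
    sum(rowSums(P)^2) / nr^2,
    sum(colSums(P)^2) / nr,
    sum(colSums(P)^2) / nr^2,
    nr / np,
    sum(pg * (i - mu_i)^2),
    sum(pr * (j - mu_j)^2),
    plog(p),
    sum(P / i^2) / nr,
    sum(P * i^2) / nr,
    sum(outer(1 / i^2, 1 / j^2) * P) / nr,
    sum(outer(i^2, 1 / j^2) * P) / nr,
    sum(outer(1 / i^2, j^2) * P) / nr,
    sum(outer(i^2, j^2) * P) / nr)
  vals
}

#' GLRLM features (16), averaged over the 13 directions
#' @param d a [discretize()]d ROI.
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(d) {
  arr <- glrlm_matrix(d)
  np <- sum(d$mask$values)
  vals <- matrix(NA_real_, 13, 16)
  for (k in 1:13) {
    P <- matrix(arr[, , k], nrow = dim(arr)[1])
    if (sum(P) == 0) next
    vals[k, ] <- rl_family_features(P, np)
  }
  ok <- !is.na(vals[, 1])
  setNames(colMeans(vals[ok, , drop = FALSE]), glrlm_feature_names)
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected components of equal gray level inside the mask;
#' the matrix counts zones per level (rows) and zone size (columns).
#'
#' @param d a [discretize()]d ROI.
#' @return integer matrix `Ng x max_zone_size`.
#' @export
glszm_matrix <- function(d) {
  stopifnot_roi(d)
  dm <- dim(d$levels)
  z <- cpp_glszm_zones(as.integer(d$levels), dm[1], dm[2], dm[3])
  smax <- max(z[, 2])
  P <- matrix(0L, d$ng, smax)
  for (r in seq_len(nrow(z))) P[z[r, 1], z[r, 2]] <- P[z[r, 1], z[r, 2]] + 1L
  P
}

#' GLSZM features (16)
#' @param d a [discretize()]d ROI.
#' @return named numeric vector of length 16.
#' @export
glszm_features <- function(d) {
  P <- glszm_matrix(d)
  np <- sum(d$mask$values)
  setNames(rl_family_features(P, np), glszm_feature_names)
}

#' Gray-level dependence matrix
#'
#' The dependence count of an in-mask voxel is the number of its 26
#' in-mask neighbours whose level differs by at most `alpha`; column `j`
#' holds dependence `j - 1`, so an isolated voxel lands in column 1.
#' Trailing all-zero columns are trimmed.
#'
#' @param d a [discretize()]d ROI.
#' @param alpha nonnegative integer level-difference cut-off.
#' @return integer matrix `Ng x (max_dependence + 1)`.
#' @export
gldm_matrix <- function(d, alpha = 0L) {
  stopifnot_roi(d)
  dm <- dim(d$levels)
  P <- cpp_gldm_counts(as.integer(d$levels), dm[1], dm[2], dm[3], d$ng,
                       as.integer(alpha))
  used <- which(colSums(P) > 0)
  P[, seq_len(if (length(used)) max(used) else 1L), drop = FALSE]
}

#' GLDM features (14)
#' @inheritParams gldm_matrix
#' @return named numeric vector of length 14.
#' @export
gldm_features <- function(d, alpha = 0L) {
  P <- gldm_matrix(d, alpha)
  np <- sum(d$mask$values)
  v <- rl_family_features(P, np)
  # the GLDM catalogue keeps 14 of the 16 family formulas: it drops the
  # normalised gray-level non-uniformity and the (here trivial) percentage
  keep <- c(1, 2, 3, 5, 6, 8, 9, 10, 11, 12, 13, 14, 15, 16)
  setNames(v[keep], gldm_feature_names)
}
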