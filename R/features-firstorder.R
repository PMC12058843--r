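#' Gray-level discretisation with a fixed bin width
#'
#' In-mask intensities are binned as
#' `level = floor((x - min_in_mask) / bin_width) + 1`; voxels outside the
#' mask get level 0. `Ng` is the highest occupied level.
#'
#' @param v a [volume_grid()].
#' @param m an aligned nonempty [mask_volume()].
#' @param bin_width positive bin width in intensity units.
#' @return a `discretized_roi`: list with `levels` (integer array), `ng`,
#'   `bin_width` and `mask`.
#' @export
discretize <- function(v, m, bin_width = 25) {
  check_alignment(v, m)
  if (bin_width <= 0) stop("bin_width must be positive")
  inm <- m$values == 1L
  if (!any(inm)) stop("empty mask")
  lev <- array(0L, dim(v$values))
  x <- v$values[inm]
  lev[inm] <- as.integer(floor((x - min(x)) / bin_width)) + 1L
  structure(list(levels = lev, ng = max(lev), bin_width = bin_width,
                 mask = m),
            class = "discretized_roi")
}

first_order_names <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity")

#' First-order intensity features
#'
#' The 18 standard first-order statistics of the in-mask intensity
#' distribution. `Entropy` and `Uniformity` are computed on the
#' fixed-bin-width discretised histogram; `TotalEnergy` scales `Energy` by
#' the voxel volume. Moments use the population (1/n) convention; kurtosis
#' is not excess-corrected. A single-voxel mask yields `NaN`
#' skewness/kurtosis with a warning rather than an error.
#'
#' @param v a [volume_grid()].
#' @param m an aligned nonempty [mask_volume()].
#' @param bin_width histogram bin width for Entropy/Uniformity.
#' @return named numeric vector of length 18.
#' @export
first_order_features <- function(v, m, bin_width = 25) {
  check_alignment(v, m)
  x <- v$values[m$values == 1L]
  n <- length(x)
  if (n == 0) stop("empty mask")
  d <- discretize(v, m, bin_width)
  p <- tabulate(d$levels[d$mask$values == 1L], nbins = d$ng) / n
  p_pos <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  if (m2 > 0) {
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2
  } else {
    if (n == 1)
      warning("single-voxel mask: skewness and kurtosis undefined")
    else
      warning("constant ROI: skewness and kurtosis undefined")
    skew <- NaN
    kurt <- NaN
  }
  q <- quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  robust <- x[x >= q[1] & x <= q[5]]
  c(Energy = sum(x^2),
    TotalEnergy = voxel_volume(v) * sum(x^2),
    Entropy = -sum(p_pos * log2(p_pos)),
    Minimum = min(x),
    "10Percentile" = q[1],
    "90Percentile" = q[5],
    Maximum = max(x),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = m2,
    Uniformity = sum(p^2))
}
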