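#' Extraction configuration
#'
#' Central knob set for feature extraction and filtering. Defaults follow
#' the prevailing radiomics conventions: fixed 25 HU bin width on raw CT
#' intensities, five evenly spaced Laplacian-of-Gaussian scales, a
#' single-level undecimated Coiflet-1 wavelet with periodic boundary, and
#' no intensity normalisation (Hounsfield units are already calibrated).
#'
#' @param bin_width positive gray-level discretisation bin width (HU).
#' @param gldm_alpha nonnegative integer dependence cut-off for GLDM.
#' @param log_sigmas_mm positive LoG scales in mm.
#' @param normalize_mode passed to [normalize_intensities()].
#' @param io_format `"nifti"` or `"nrrd"` for files written by the study
#'   generator.
#' @return a named list of class `radstab_config`.
#' @export
radstab_config <- function(bin_width = 25, gldm_alpha = 0L,
                           log_sigmas_mm = c(1, 2, 3, 4, 5),
                           normalize_mode = "none",
                           io_format = c("nifti", "nrrd")) {
  stopifnot(bin_width > 0, gldm_alpha >= 0, all(log_sigmas_mm > 0))
  structure(list(bin_width = bin_width,
                 gldm_alpha = as.integer(gldm_alpha),
                 log_sigmas_mm = log_sigmas_mm,
                 normalize_mode = normalize_mode,
                 io_format = match.arg(io_format)),
            class = "radstab_config")
}

# Coiflet-1 orthogonal analysis filters (6 taps).
COIF1_LO <- c(-0.015655728135791993, -0.07273261951252645,
              0.3848648468648578, 0.8525720202116004,
              0.3378976624574818, -0.07273261951252645)
COIF1_HI <- c(0.07273261951252645, 0.3378976624574818,
              -0.8525720202116004, 0.3848648468648578,
              0.07273261951252645, -0.015655728135791993)

# frequency response along one axis of length n for taps at integer offsets
axis_response <- function(taps, offsets, n) {
  f <- (seq_len(n) - 1) / n
  resp <- rep(0 + 0i, n)
  for (j in seq_along(taps))
    resp <- resp + taps[j] * exp(-2i * pi * f * offsets[j])
  resp
}

# multiply the 3D FFT by separable per-axis responses and invert
apply_separable <- function(arr, rx, ry, rz) {
  d <- dim(arr)
  fa <- fft(arr)
  fa <- fa * rep(rx, times = d[2] * d[3])
  fa <- fa * rep(rep(ry, each = d[1]), times = d[3])
  fa <- fa * rep(rz, each = d[1] * d[2])
  Re(fft(fa, inverse = TRUE)) / prod(d)
}

#' Laplacian-of-Gaussian filter at a physical scale
#'
#' Convolves the volume with a spacing-aware LoG kernel of scale `sigma_mm`
#' (per-axis sigma in voxels is `sigma_mm / spacing`), built as the sum of
#' the three separable second-derivative-of-Gaussian terms sampled from the
#' closed form and corrected to exact zero DC, so a constant volume maps to
#' zero. Boundary handling is periodic (circular convolution).
#'
#' @param v a [volume_grid()].
#' @param sigma_mm positive filter scale in mm; scales below half the
#'   largest spacing are under-resolved and trigger a warning.
#' @return a [volume_grid()] on the same grid.
#' @export
log_filter <- function(v, sigma_mm) {
  stopifnot(inherits(v, "volume_grid"), sigma_mm > 0)
  if (!all(is.finite(v$values))) stop("non-finite input volume")
  if (sigma_mm < max(v$spacing) / 2)
    warning("sigma_mm = ", sigma_mm, " mm is below half the voxel spacing; ",
            "the LoG kernel is under-resolved")
  d <- dim(v$values)
  resp1 <- vector("list", 3)  # smoothing terms
  resp2 <- vector("list", 3)  # second-derivative terms
  for (a in 1:3) {
    h <- v$spacing[a]
    R <- max(1L, ceiling(4.5 * sigma_mm / h))
    off <- -R:R
    x <- off * h
    g <- exp(-x^2 / (2 * sigma_mm^2)) / (sqrt(2 * pi) * sigma_mm)
    g1 <- g * h
    g1 <- g1 / sum(g1)                       # unit DC smoothing kernel
    g2 <- (x^2 - sigma_mm^2) / sigma_mm^4 * g * h
    g2 <- g2 - mean(g2)                      # exact zero DC
    resp1[[a]] <- axis_response(g1, off, d[a])
    resp2[[a]] <- axis_response(g2, off, d[a])
  }
  out <- apply_separable(v$values, resp2[[1]], resp1[[2]], resp1[[3]]) +
    apply_separable(v$values, resp1[[1]], resp2[[2]], resp1[[3]]) +
    apply_separable(v$values, resp1[[1]], resp1[[2]], resp2[[3]])
  volume_grid(out, v$spacing, v$origin)
}

wavelet_subband_names <- function() {
  lab <- c("L", "H")
  out <- character(8)
  k <- 1
  for (x in 1:2) for (y in 1:2) for (z in 1:2) {
    out[k] <- paste0(lab[x], lab[y], lab[z])
    k <- k + 1
  }
  out
}

#' Single-level undecimated 3D wavelet decomposition
#'
#' Separable stationary (undecimated) Coiflet-1 transform with periodic
#' boundary. Returns the eight sub-bands `LLL` ... `HHH`; the three letters
#' name the low/high-pass choice along the x, y and z axes in that order.
#' Every sub-band has the shape of the input, and the transform is
#' invertible: correlating each sub-band with its analysis filters and
#' summing reproduces the input (up to a factor 8 handled internally by
#' [wavelet_reconstruct()]).
#'
#' @param v a [volume_grid()]; each dimension must be at least 6 voxels
#'   (the filter length).
#' @return named list of 8 [volume_grid()] objects.
#' @export
wavelet_decompose <- function(v) {
  stopifnot(inherits(v, "volume_grid"))
  d <- dim(v$values)
  if (any(d < 6L))
    stop("volume smaller than the wavelet filter support (6); ",
         "pad the volume to at least 6 voxels per axis")
  off <- -2:3
  resp <- list(L = lapply(d, function(n) axis_response(COIF1_LO, off, n)),
               H = lapply(d, function(n) axis_response(COIF1_HI, off, n)))
  out <- list()
  for (nm in wavelet_subband_names()) {
    b <- strsplit(nm, "")[[1]]
    arr <- apply_separable(v$values, resp[[b[1]]][[1]], resp[[b[2]]][[2]],
                           resp[[b[3]]][[3]])
    out[[nm]] <- volume_grid(arr, v$spacing, v$origin)
  }
  out
}

#' Invert the undecimated wavelet decomposition
#'
#' Applies the adjoint analysis filters to each sub-band and averages; for
#' an orthogonal filter bank this reproduces the input exactly (used as a
#' self-check; extraction itself only consumes the analysis sub-bands).
#'
#' @param subbands the list returned by [wavelet_decompose()].
#' @return a [volume_grid()].
#' @export
wavelet_reconstruct <- function(subbands) {
  stopifnot(length(subbands) == 8L)
  ref <- subbands[[1]]
  d <- dim(ref$values)
  off <- -2:3
  resp <- list(L = lapply(d, function(n) axis_response(COIF1_LO, off, n)),
               H = lapply(d, function(n) axis_response(COIF1_HI, off, n)))
  acc <- array(0, d)
  for (nm in wavelet_subband_names()) {
    b <- strsplit(nm, "")[[1]]
    acc <- acc + apply_separable(subbands[[nm]]$values,
                                 Conj(resp[[b[1]]][[1]]),
                                 Conj(resp[[b[2]]][[2]]),
                                 Conj(resp[[b[3]]][[3]]))
  }
  volume_grid(acc / 8, ref$spacing, ref$origin)
}

#' The catalogue of image types
#'
#' One `original` entry, one LoG entry per configured sigma
#' (`log-sigma-<s>-mm-3D`), and eight wavelet sub-bands
#' (`wavelet-<LLL..HHH>`): 14 image types under the default configuration.
#'
#' @param config a [radstab_config()].
#' @return character vector of canonical image-type names.
#' @export
image_type_catalogue <- function(config = radstab_config()) {
  log_names <- sprintf("log-sigma-%s-mm-3D",
                       gsub(".", "-", format(config$log_sigmas_mm,
                                             nsmall = 1, trim = TRUE),
                            fixed = TRUE))
  c("original", log_names, paste0("wavelet-", wavelet_subband_names()))
}

#' Compute all filtered image types for a volume
#'
#' @param v a [volume_grid()].
#' @param config a [radstab_config()].
#' @return named list of [volume_grid()] objects, one per entry of
#'   [image_type_catalogue()].
#' @export
filtered_images <- function(v, config = radstab_config()) {
  v <- normalize_intensities(v, config$normalize_mode)
  out <- list(original = v)
  for (s in config$log_sigmas_mm) {
    nm <- sprintf("log-sigma-%s-mm-3D",
                  gsub(".", "-", format(s, nsmall = 1, trim = TRUE),
                       fixed = TRUE))
    out[[nm]] <- log_filter(v, s)
  }
  wb <- wavelet_decompose(v)
  for (nm in names(wb)) out[[paste0("wavelet-", nm)]] <- wb[[nm]]
  out
}
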