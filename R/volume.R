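#' 3D scalar volume on a regular grid
#'
#' A `volume_grid` is a 3D array of finite scalar values (Hounsfield units
#' for CT-like data) together with its voxel spacing and world origin, both
#' in millimetres. World coordinates follow
#' `world = origin + index * spacing` with 0-based indices; no axis
#' reordering is ever performed.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("volume values must all be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)")
  if (length(origin) != 3L)
    stop("`origin` must have length 3")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "volume_grid")
}

#' Binary mask volume on a regular grid
#'
#' Same geometry model as [volume_grid()]; values are constrained to 0/1.
#'
#' @inheritParams volume_grid
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  v <- as.integer(values)
  if (anyNA(v) || !all(v %in% c(0L, 1L)))
    stop("mask values must be binary (0/1)")
  dim(v) <- dim(values)
  g <- volume_grid(v, spacing, origin)
  class(g) <- "mask_volume"
  g
}

#' @export
dim.volume_grid <- function(x) dim(x$values)
#' @export
dim.mask_volume <- function(x) dim(x$values)

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, spacing %s mm, origin %s mm\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

#' @export
print.mask_volume <- function(x, ...) {
  cat(sprintf("<mask_volume> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$values), collapse = "x"),
              sum(x$values),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Voxel volume in mm^3
#' @param x a `volume_grid` or `mask_volume`.
#' @return scalar, product of the spacings.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Check that a mask shares the grid of a volume
#'
#' Shape must match exactly; spacing and origin within `tol` mm. Errors name
#' the offending field.
#'
#' @param v a `volume_grid`.
#' @param m a `mask_volume`.
#' @param tol geometric tolerance in mm.
#' @return invisibly `TRUE` (errors otherwise).
#' @export
check_alignment <- function(v, m, tol = 1e-3) {
  if (!identical(dim(v$values), dim(m$values)))
    stop("alignment error: shape differs between volume (",
         paste(dim(v$values), collapse = "x"), ") and mask (",
         paste(dim(m$values), collapse = "x"), ")")
  if (any(abs(v$spacing - m$spacing) > tol))
    stop("alignment error: spacing differs beyond ", tol, " mm")
  if (any(abs(v$origin - m$origin) > tol))
    stop("alignment error: origin differs beyond ", tol, " mm")
  invisible(TRUE)
}

# ---- NIfTI / NRRD I/O ------------------------------------------------------

format_from_path <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lp)) return("nifti")
  if (grepl("\\.nrrd$", lp)) return("nrrd")
  stop("unrecognised volume format for '", path,
       "' (expected .nii, .nii.gz or .nrrd)")
}

read_grid <- function(path) {
  fmt <- format_from_path(path)
  if (!file.exists(path)) stop("file not found: ", path)
  if (fmt == "nifti") {
    img <- RNifti::readNifti(path)
    xf <- RNifti::xform(img)
    rot <- xf[1:3, 1:3]
    if (any(abs(rot - diag(diag(rot))) > 1e-6) || any(diag(rot) <= 0))
      stop("non-axis-aligned orientation in '", path,
           "'; refusing to resample implicitly")
    vals <- array(as.vector(as.array(img)), dim = dim(img)[1:3])
    list(values = vals, spacing = as.numeric(diag(rot)),
         origin = as.numeric(xf[1:3, 4]))
  } else {
    read_nrrd(path)
  }
}

#' Read a scalar volume (NIfTI or NRRD)
#'
#' Orientation must be axis-aligned with positive scales; anything else is
#' rejected rather than silently resampled.
#'
#' @param path file path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return a [volume_grid()].
#' @export
read_volume <- function(path) {
  g <- read_grid(path)
  volume_grid(g$values, g$spacing, g$origin)
}

#' Read a binary mask (NIfTI or NRRD)
#' @inheritParams read_volume
#' @return a [mask_volume()].
#' @export
read_mask <- function(path) {
  g <- read_grid(path)
  mask_volume(g$values, g$spacing, g$origin)
}

write_grid <- function(x, path, datatype) {
  fmt <- format_from_path(path)
  if (fmt == "nifti") {
    img <- RNifti::asNifti(x$values + 0)
    RNifti::pixdim(img) <- x$spacing
    xf <- rbind(cbind(diag(x$spacing), x$origin), c(0, 0, 0, 1))
    xf <- structure(xf, code = 2L)
    RNifti::qform(img) <- xf
    RNifti::writeNifti(img, path, datatype = datatype)
  } else {
    write_nrrd(x, path, datatype)
  }
  invisible(path)
}

#' Write a volume or mask to NIfTI or NRRD
#'
#' Round-trips are bit-exact in values and preserve geometry to better than
#' 1e-6 mm. Masks are written as unsigned 8-bit, volumes as float64.
#'
#' @param v a [volume_grid()].
#' @param path output path (`.nii`, `.nii.gz` or `.nrrd`).
#' @return the path, invisibly.
#' @export
write_volume <- function(v, path) write_grid(v, path, "double")

#' @rdname write_volume
#' @param m a [mask_volume()].
#' @export
write_mask <- function(m, path) write_grid(m, path, "uint8")

# Minimal NRRD0004 reader/writer (raw little-endian encoding, 3D scalar
# grids only) -- sufficient for the package's own output files.
write_nrrd <- function(x, path, datatype) {
  type <- if (datatype == "uint8") "uint8" else "double"
  dims <- dim(x$values)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dims, collapse = " ")),
    paste0("space directions: ",
           sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                   x$spacing[1], x$spacing[2], x$spacing[3])),
    "kinds: domain domain domain",
    "endian: little",
    "encoding: raw",
    paste0("space origin: ",
           sprintf("(%.17g,%.17g,%.17g)",
                   x$origin[1], x$origin[2], x$origin[3])),
    ""
  )
  writeLines(hdr, con, sep = "\n")
  if (type == "uint8") {
    writeBin(as.raw(as.integer(x$values)), con)
  } else {
    writeBin(as.double(x$values), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0 || ln == "") break
    lines <- c(lines, ln)
  }
  if (length(lines) == 0 || !grepl("^NRRD", lines[1]))
    stop("not an NRRD file: ", path)
  fields <- lines[grepl(":", lines, fixed = TRUE)]
  keys <- tolower(trimws(sub(":.*$", "", fields)))
  vals <- trimws(sub("^[^:]*:=?", "", fields))
  get <- function(k) vals[match(k, keys)]
  if (!is.na(get("encoding")) && get("encoding") != "raw")
    stop("only raw-encoded NRRD is supported")
  dims <- as.integer(strsplit(get("sizes"), "\\s+")[[1]])
  if (length(dims) != 3) stop("only 3D NRRD volumes are supported")
  type <- get("type")
  spacing <- c(1, 1, 1)
  if (!is.na(get("space directions"))) {
    nums <- regmatches(get("space directions"),
                       gregexpr("-?[0-9.eE+]+", get("space directions")))[[1]]
    m <- matrix(as.numeric(nums), nrow = 3, byrow = TRUE)
    if (any(abs(m - diag(diag(m))) > 1e-9) || any(diag(m) <= 0))
      stop("non-axis-aligned NRRD space directions are not supported")
    spacing <- diag(m)
  }
  origin <- c(0, 0, 0)
  if (!is.na(get("space origin"))) {
    origin <- as.numeric(
      regmatches(get("space origin"),
                 gregexpr("-?[0-9.eE+]+", get("space origin")))[[1]])
  }
  n <- prod(dims)
  values <- if (type %in% c("uint8", "uchar", "unsigned char")) {
    as.integer(readBin(con, "raw", n = n))
  } else if (type %in% c("double", "float64")) {
    readBin(con, "double", n = n, size = 8, endian = "little")
  } else stop("unsupported NRRD type: ", type)
  dim(values) <- dims
  list(values = values, spacing = spacing, origin = origin)
}

# ---- preparation -----------------------------------------------------------

#' Normalise volume intensities
#'
#' `none` is the identity (the default convention for calibrated CT
#' Hounsfield units); `unit_range` maps the observed range to `[0, 1]`;
#' `zscore` centres to mean 0, sd 1 over the whole volume.
#'
#' @param v a [volume_grid()].
#' @param mode one of `"none"`, `"unit_range"`, `"zscore"`.
#' @return a [volume_grid()] with transformed values.
#' @export
normalize_intensities <- function(v, mode = c("none", "unit_range",
                                              "zscore")) {
  mode <- match.arg(mode)
  if (mode == "none") return(v)
  x <- v$values
  if (mode == "unit_range") {
    rng <- range(x)
    if (rng[2] <= rng[1])
      stop("degenerate scale: constant volume cannot be range-normalised")
    volume_grid((x - rng[1]) / (rng[2] - rng[1]), v$spacing, v$origin)
  } else {
    s <- sd(as.vector(x))
    if (s == 0)
      stop("degenerate scale: constant volume cannot be z-scored")
    volume_grid((x - mean(x)) / s, v$spacing, v$origin)
  }
}

#' Crop a volume and mask to the mask bounding box
#'
#' All feature definitions use only in-mask voxels and mask geometry, so
#' features computed on the cropped pair equal those on the full pair.
#'
#' @param v a [volume_grid()].
#' @param m an aligned nonempty [mask_volume()].
#' @param pad_voxels nonnegative integer padding added on each side
#'   (clipped at the grid boundary).
#' @return list with elements `volume` and `mask`.
#' @export
crop_to_mask <- function(v, m, pad_voxels = 0L) {
  check_alignment(v, m)
  if (sum(m$values) == 0) stop("empty mask: nothing to crop to")
  pad_voxels <- as.integer(pad_voxels)
  stopifnot(pad_voxels >= 0L)
  idx <- which(m$values == 1L, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - pad_voxels, 1L)
  hi <- pmin(apply(idx, 2, max) + pad_voxels, dim(m$values))
  sel <- list(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
  new_origin <- m$origin + (lo - 1L) * m$spacing
  list(
    volume = volume_grid(v$values[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
                         v$spacing, new_origin),
    mask = mask_volume(m$values[sel[[1]], sel[[2]], sel[[3]], drop = FALSE],
                       m$spacing, new_origin)
  )
}
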