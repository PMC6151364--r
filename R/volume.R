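#' 3D image volume with voxel spacing
#'
#' Light container for a 3D scalar image as used throughout the pipeline: a
#' numeric array indexed `[x, y, z]` plus the physical voxel spacing and origin
#' in millimetres. The world coordinate of voxel index `v` (1-based) is
#' `origin + (v - 1) * spacing`, i.e. indices address voxel centers.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, mm per voxel along x, y, z. All > 0.
#' @param origin Numeric length-3, world position (mm) of voxel `[1, 1, 1]`.
#' @return An object of class `lv_volume`.
#' @examples
#' v <- volume(array(0, c(8, 8, 4)), spacing = c(1, 1, 2))
#' dim(v$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  }
  if (length(origin) != 3 || any(!is.finite(origin))) {
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "lv_volume")
}

#' Binary label mask aligned with a volume
#'
#' Same geometry contract as [volume()], but the array is coerced to 0/1.
#'
#' @inheritParams volume
#' @return An object of class `lv_mask` (inherits `lv_volume`).
#' @export
label_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  v <- volume(data, spacing, origin)
  vals <- as.numeric(v$data)
  if (!all(vals %in% c(0, 1))) stop("mask values must be 0/1", call. = FALSE)
  storage.mode(v$data) <- "integer"
  class(v) <- c("lv_mask", "lv_volume")
  v
}

#' @exportS3Method base::print
print.lv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              class(x)[1], d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @exportS3Method base::dim
dim.lv_volume <- function(x) dim(x$data)

check_aligned <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9 ||
      max(abs(a$origin - b$origin)) > 1e-9) {
    stop("volume and mask are not geometrically aligned", call. = FALSE)
  }
  invisible(TRUE)
}

## world (mm) <-> continuous voxel index (1-based)
mm_to_index <- function(vol, pts) {
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

index_to_mm <- function(vol, idx) {
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Sample a volume at arbitrary world points by trilinear interpolation
#'
#' Points are given in mm; coordinates are clamped to the volume domain so
#' out-of-bounds queries return the nearest boundary value.
#'
#' @param vol An [volume()].
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return Numeric vector of n interpolated values.
#' @export
trilinear_sample <- function(vol, pts) {
  trilinear_core(vol, pts)$value
}

#' Spatial gradient of the trilinear interpolant at world points
#'
#' Returns the exact derivative of the trilinear interpolant (piecewise linear
#' in each coordinate), in units of field-value per mm. Using the interpolant's
#' own derivative keeps sampled energies and their reported gradients mutually
#' consistent, which matters for gradient-descent surface evolution and for
#' finite-difference gradient checks.
#'
#' @inheritParams trilinear_sample
#' @return n x 3 matrix of partial derivatives.
#' @export
trilinear_gradient <- function(vol, pts) {
  trilinear_core(vol, pts)$gradient
}

trilinear_core <- function(vol, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  d <- dim(vol$data)
  idx <- mm_to_index(vol, pts)
  # clamp into [1, d]; interior cells index i0 in [1, d-1]
  for (k in 1:3) idx[, k] <- pmin(pmax(idx[, k], 1), d[k])
  i0 <- pmin(floor(idx), matrix(rep(d - 1L, each = nrow(idx)), ncol = 3))
  i0 <- pmax(i0, 1)
  f <- idx - i0  # in [0, 1]
  a <- vol$data
  at <- function(dx, dy, dz) {
    a[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  }
  c000 <- at(0L, 0L, 0L); c100 <- at(1L, 0L, 0L)
  c010 <- at(0L, 1L, 0L); c110 <- at(1L, 1L, 0L)
  c001 <- at(0L, 0L, 1L); c101 <- at(1L, 0L, 1L)
  c011 <- at(0L, 1L, 1L); c111 <- at(1L, 1L, 1L)
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  val <- c0 * (1 - fz) + c1 * fz
  # partials of the interpolant, chain rule through index = (mm - origin)/spacing
  dx00 <- c100 - c000; dx10 <- c110 - c010; dx01 <- c101 - c001; dx11 <- c111 - c011
  dx0 <- dx00 * (1 - fy) + dx10 * fy
  dx1 <- dx01 * (1 - fy) + dx11 * fy
  gx <- (dx0 * (1 - fz) + dx1 * fz) / vol$spacing[1]
  gy0 <- c10 - c00; gy1 <- c11 - c01
  gy <- (gy0 * (1 - fz) + gy1 * fz) / vol$spacing[2]
  gz <- (c1 - c0) / vol$spacing[3]
  list(value = val, gradient = cbind(gx, gy, gz, deparse.level = 0))
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-0.5 * ((-r:r) / sigma_vox)^2)
  k / sum(k)
}

convolve_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(a)
  d <- dim(a)
  # move target axis first, filter columns, move back
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  # replicate-pad along the filtered axis
  mp <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(dp[1], r), , drop = FALSE])
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * mp[j:(j + dp[1] - 1L), , drop = FALSE]
  }
  ap2 <- array(out, dp)
  aperm(ap2, order(perm))
}

#' Gaussian smoothing of a volume, spacing-aware
#'
#' Separable Gaussian filter; `sigma_mm` is interpreted in millimetres and
#' converted per-axis to voxels, so anisotropic spacing is respected. Borders
#' use replicate padding.
#'
#' @param vol An [volume()].
#' @param sigma_mm Gaussian standard deviation in mm (scalar).
#' @return A smoothed [volume()] with the same geometry.
#' @export
gaussian_smooth_volume <- function(vol, sigma_mm) {
  stopifnot(is.numeric(sigma_mm), length(sigma_mm) == 1, sigma_mm >= 0)
  a <- vol$data
  storage.mode(a) <- "double"
  for (axis in 1:3) {
    a <- convolve_axis(a, gaussian_kernel_1d(sigma_mm / vol$spacing[axis]), axis)
  }
  volume(a, vol$spacing, vol$origin)
}

#' Central-difference spatial gradient of a volume
#'
#' @param vol An [volume()].
#' @return List of three volumes `gx`, `gy`, `gz` (units: value per mm), using
#'   one-sided differences at the array borders.
#' @export
volume_gradient <- function(vol) {
  a <- vol$data
  d <- dim(a)
  diff_axis <- function(axis) {
    n <- d[axis]
    hi <- pmin(seq_len(n) + 1L, n)
    lo <- pmax(seq_len(n) - 1L, 1L)
    denom <- (hi - lo) * vol$spacing[axis]
    idx_hi <- switch(axis, a[hi, , , drop = FALSE], a[, hi, , drop = FALSE], a[, , hi, drop = FALSE])
    idx_lo <- switch(axis, a[lo, , , drop = FALSE], a[, lo, , drop = FALSE], a[, , lo, drop = FALSE])
    g <- idx_hi - idx_lo
    if (axis == 1) {
      g <- g / array(denom, d)
    } else if (axis == 2) {
      g <- g / array(rep(denom, each = d[1]), d)
    } else {
      g <- g / array(rep(denom, each = d[1] * d[2]), d)
    }
    volume(g, vol$spacing, vol$origin)
  }
  list(gx = diff_axis(1), gy = diff_axis(2), gz = diff_axis(3))
}

# ---- MetaImage (.mhd + .raw) ----
# Minimal MetaImage support: 3D, MET_FLOAT or MET_UCHAR, local raw file.

#' Write a volume as MetaImage (.mhd + .raw)
#'
#' @param vol An [volume()] or mask.
#' @param path Path to the `.mhd` header; the `.raw` block is written next to it.
#' @param element_type `"MET_FLOAT"` (default for volumes) or `"MET_UCHAR"`
#'   (default for masks).
#' @return `path`, invisibly.
#' @export
write_mhd <- function(vol, path,
                      element_type = if (inherits(vol, "lv_mask")) "MET_UCHAR" else "MET_FLOAT") {
  stopifnot(grepl("\\.mhd$", path))
  element_type <- match.arg(element_type, c("MET_FLOAT", "MET_UCHAR"))
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  d <- dim(vol$data)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %.9g %.9g %.9g", vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("Offset = %.9g %.9g %.9g", vol$origin[1], vol$origin[2], vol$origin[3]),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", raw_name)
  )
  writeLines(hdr, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  vals <- as.vector(vol$data)  # column-major == x fastest, matching MetaImage
  if (element_type == "MET_UCHAR") {
    writeBin(as.raw(as.integer(round(vals))), con)
  } else {
    writeBin(as.numeric(vals), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a MetaImage (.mhd + .raw) volume
#'
#' @param path Path to the `.mhd` header.
#' @param as_mask Coerce to [label_mask()]?
#' @return An [volume()] or [label_mask()].
#' @export
read_mhd <- function(path, as_mask = FALSE) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  get <- function(k, default = NULL) {
    i <- match(tolower(k), tolower(keys))
    if (is.na(i)) default else vals[i]
  }
  d <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  spacing <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  origin <- as.numeric(strsplit(get("Offset", "0 0 0"), "\\s+")[[1]])
  etype <- get("ElementType", "MET_FLOAT")
  dfile <- get("ElementDataFile")
  raw_path <- if (dfile == "LOCAL") path else file.path(dirname(path), dfile)
  n <- prod(d)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  a <- if (etype == "MET_UCHAR") {
    array(as.integer(readBin(con, "raw", n)), d)
  } else if (etype %in% c("MET_FLOAT", "MET_DOUBLE")) {
    array(readBin(con, "double", n, size = if (etype == "MET_FLOAT") 4 else 8,
                  endian = "little"), d)
  } else {
    stop("unsupported ElementType: ", etype, call. = FALSE)
  }
  if (as_mask) label_mask(a, spacing, origin) else volume(a, spacing, origin)
}

# ---- NIfTI via RNifti ----

#' Write a volume as NIfTI (.nii.gz)
#' @inheritParams write_mhd
#' @export
write_nifti_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data, reference = list(pixdim = c(1, vol$spacing, 1, 1, 1, 1)))
  img <- RNifti::updateNifti(img, list(pixdim = c(1, vol$spacing, 1, 1, 1, 1)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#' @inheritParams read_mhd
#' @export
read_nifti_volume <- function(path, as_mask = FALSE) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  a <- array(as.numeric(img), dim(img)[1:3])
  if (as_mask) label_mask(round(a), spacing) else volume(a, spacing)
}

#' Read or write a volume, format chosen by file extension
#'
#' `.mhd` goes through the MetaImage reader/writer, `.nii`/`.nii.gz` through
#' RNifti.
#' @inheritParams write_mhd
#' @param as_mask Coerce to [label_mask()]?
#' @export
write_volume <- function(vol, path) {
  if (grepl("\\.mhd$", path)) write_mhd(vol, path) else write_nifti_volume(vol, path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, as_mask = FALSE) {
  if (grepl("\\.mhd$", path)) read_mhd(path, as_mask) else read_nifti_volume(path, as_mask)
}
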