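#' Specification of a synthetic 3DE-like phantom
#'
#' Describes a digital phantom that emulates the geometry and first-order
#' appearance of a left-ventricle 3D echocardiogram: a dark half-ellipsoid LV
#' cavity (truncated at its equatorial/basal plane) inside a bright myocardial
#' shell, an adjacent dark atrial cavity beyond the basal wall connected to the
#' LV through a circular mitral opening (the LV/LA leak hazard), multiplicative
#' speckle, and Gaussian blur. The defaults define the study conditions used
#' throughout the package's tests and examples.
#'
#' @param grid_shape Integer length-3, voxels along x, y, z.
#' @param spacing Numeric length-3, mm per voxel.
#' @param cavity_semi_axes Numeric length-3 `(a, b, c)` in mm: semi-axes of the
#'   half-ellipsoid cavity; `c` is along z (the long axis).
#' @param wall_thickness Myocardial shell thickness, mm.
#' @param cavity_intensity,wall_intensity,background_intensity Gray levels in
#'   `[0, 1]` for blood pool, myocardium and surrounding tissue.
#' @param atrium_enabled Add the atrial cavity and mitral opening?
#' @param atrium_offset mm from the basal plane to the bottom of the atrial
#'   cavity (the connecting channel spans this gap through the basal wall).
#' @param atrium_semi_axes Numeric length-3, mm semi-axes of the atrial cavity.
#' @param mitral_opening_radius Radius (mm) of the opening connecting LV and LA.
#' @param speckle_scale Relative standard deviation of the multiplicative
#'   speckle (unit-mean gamma); 0 disables noise.
#' @param smoothing_sigma Gaussian blur sigma in mm applied after speckle;
#'   0 disables.
#' @param apex_margin mm of padding below the apex.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(grid_shape = c(32, 32, 40),
#'                      cavity_semi_axes = c(8, 8, 20))
#' spec$basal_z
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 80),
                         spacing = c(1, 1, 1),
                         cavity_semi_axes = c(16, 16, 40),
                         wall_thickness = 4,
                         cavity_intensity = 0.15,
                         wall_intensity = 0.75,
                         background_intensity = 0.35,
                         atrium_enabled = TRUE,
                         atrium_offset = 4,
                         atrium_semi_axes = c(12, 12, 9),
                         mitral_opening_radius = 8,
                         speckle_scale = 0.15,
                         smoothing_sigma = 1,
                         apex_margin = 2,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            length(spacing) == 3, all(spacing > 0),
            length(cavity_semi_axes) == 3)
  if (any(cavity_semi_axes <= 0) || wall_thickness <= 0 ||
      mitral_opening_radius <= 0 || any(atrium_semi_axes <= 0)) {
    stop("semi-axes, wall thickness and radii must be strictly positive",
         call. = FALSE)
  }
  ints <- c(cavity_intensity, wall_intensity, background_intensity)
  if (any(ints < 0) || any(ints > 1)) {
    stop("intensities must lie in [0, 1]", call. = FALSE)
  }
  if (speckle_scale < 0 || smoothing_sigma < 0) {
    stop("speckle_scale and smoothing_sigma must be >= 0", call. = FALSE)
  }
  extent <- (grid_shape - 1) * spacing
  a <- cavity_semi_axes[1]; b <- cavity_semi_axes[2]; cc <- cavity_semi_axes[3]
  t <- wall_thickness
  center_xy <- extent[1:2] / 2
  basal_z <- apex_margin + t + cc
  z_need <- basal_z + t
  if (atrium_enabled) {
    z_need <- basal_z + atrium_offset + 2 * atrium_semi_axes[3] + t
  }
  if (center_xy[1] < a + t || center_xy[2] < b + t || z_need > extent[3]) {
    stop(sprintf(paste0("grid too small for cavity + wall: need >= %.1f x %.1f x %.1f mm, ",
                        "have %.1f x %.1f x %.1f mm"),
                 2 * (a + t), 2 * (b + t), z_need,
                 extent[1], extent[2], extent[3]), call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 cavity_semi_axes = cavity_semi_axes,
                 wall_thickness = wall_thickness,
                 cavity_intensity = cavity_intensity,
                 wall_intensity = wall_intensity,
                 background_intensity = background_intensity,
                 atrium_enabled = isTRUE(atrium_enabled),
                 atrium_offset = atrium_offset,
                 atrium_semi_axes = as.numeric(atrium_semi_axes),
                 mitral_opening_radius = mitral_opening_radius,
                 speckle_scale = speckle_scale,
                 smoothing_sigma = smoothing_sigma,
                 apex_margin = apex_margin,
                 seed = as.integer(seed),
                 center_xy = center_xy, basal_z = basal_z),
            class = "phantom_spec")
}

#' Write / read a phantom spec as YAML
#' @param spec A [phantom_spec()].
#' @param path YAML file path.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec[setdiff(names(spec), c("center_xy", "basal_z"))]),
                   path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  do.call(phantom_spec, yaml::read_yaml(path))
}

phantom_regions <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  cx <- spec$center_xy[1]; cy <- spec$center_xy[2]; zb <- spec$basal_z
  a <- spec$cavity_semi_axes[1]; b <- spec$cavity_semi_axes[2]
  cc <- spec$cavity_semi_axes[3]; t <- spec$wall_thickness

  ell2 <- function(ax, bx, cx2, zc) {
    # squared normalized ellipsoid coordinate field centered at (cx, cy, zc)
    exy <- outer(((xs - cx) / ax)^2, ((ys - cy) / bx)^2, "+")
    outer(exy, ((zs - zc) / cx2)^2, "+")
  }
  zarr <- function() array(rep(zs, each = d[1] * d[2]), d)
  Z <- zarr()
  r_xy2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
  R2 <- array(rep(r_xy2, times = d[3]), d)

  cavity <- ell2(a, b, cc, zb) <= 1 & Z <= zb
  shell_outer <- ell2(a + t, b + t, cc + t, zb) <= 1 & Z <= zb
  cap <- Z > zb & Z <= zb + t & R2 <= (a + t)^2
  wall <- (shell_outer | cap) & !cavity

  channel <- atrium <- atrium_wall <- array(FALSE, d)
  if (spec$atrium_enabled) {
    aa <- spec$atrium_semi_axes
    z_cap_top <- zb + t
    z_atr_bottom <- zb + spec$atrium_offset
    za_c <- z_atr_bottom + aa[3]
    atr_full <- ell2(aa[1], aa[2], aa[3], za_c) <= 1
    atrium <- atr_full & Z > z_cap_top
    atrium_wall <- (ell2(aa[1] + t, aa[2] + t, aa[3] + t, za_c) <= 1) &
      Z > z_cap_top & !atrium
    channel <- Z > zb & Z <= z_cap_top & R2 < spec$mitral_opening_radius^2
  }
  list(cavity = cavity, wall = wall, channel = channel,
       atrium = atrium, atrium_wall = atrium_wall)
}

#' Generate a synthetic 3DE-like phantom
#'
#' Builds the analytic region map described by a [phantom_spec()], applies
#' multiplicative unit-mean gamma speckle and Gaussian smoothing, and returns
#' the noisy volume, the exact binary cavity mask (the half-ellipsoid interior;
#' atrium and mitral channel are excluded), and a tube mesh sampling the
#' analytic cavity surface.
#'
#' @param spec A [phantom_spec()].
#' @param n_points Contour points per ring of the returned ground-truth mesh.
#' @return List with elements `volume` ([volume()]), `mask` ([label_mask()]),
#'   `mesh` (`tube_mesh`), and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(32, 32, 40),
#'                                     cavity_semi_axes = c(8, 8, 16),
#'                                     atrium_enabled = FALSE,
#'                                     speckle_scale = 0))
#' range(ph$mask$data)
#' @export
generate_phantom <- function(spec, n_points = 36) {
  stopifnot(inherits(spec, "phantom_spec"))
  reg <- phantom_regions(spec)
  d <- spec$grid_shape
  img <- array(spec$background_intensity, d)
  img[reg$wall | reg$atrium_wall] <- spec$wall_intensity
  img[reg$cavity | reg$channel | reg$atrium] <- spec$cavity_intensity

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  if (spec$speckle_scale > 0) {
    shape <- 1 / spec$speckle_scale^2
    img <- img * array(stats::rgamma(prod(d), shape = shape, scale = 1 / shape), d)
  }
  vol <- volume(img, spec$spacing)
  if (spec$smoothing_sigma > 0) {
    vol <- gaussian_smooth_volume(vol, spec$smoothing_sigma)
  }
  vol$data <- pmin(pmax(vol$data, 0), 1)
  mask <- label_mask(array(as.integer(reg$cavity), d), spec$spacing)
  list(volume = vol, mask = mask,
       mesh = analytic_cavity_mesh(spec, n_points = n_points), spec = spec)
}

#' Analytic ground-truth cavity surface as a tube mesh
#'
#' Samples the half-ellipsoid cavity surface on the phantom's z slices: one
#' elliptical contour ring per slice plane intersecting the cavity, apex vertex
#' at the analytic apex point.
#'
#' @param spec A [phantom_spec()].
#' @param n_points Points per ring.
#' @param min_radius_mm Rings with cross-section semi-axis below this are
#'   dropped (degenerate near-apex circles).
#' @return A `tube_mesh` in mm coordinates.
#' @export
analytic_cavity_mesh <- function(spec, n_points = 36, min_radius_mm = 1) {
  a <- spec$cavity_semi_axes[1]; b <- spec$cavity_semi_axes[2]
  cc <- spec$cavity_semi_axes[3]
  cx <- spec$center_xy[1]; cy <- spec$center_xy[2]; zb <- spec$basal_z
  zs <- (seq_len(spec$grid_shape[3]) - 1) * spec$spacing[3]
  zs <- zs[zs <= zb & zs >= zb - cc]
  s <- sqrt(pmax(0, 1 - ((zs - zb) / cc)^2))
  keep <- s * min(a, b) >= min_radius_mm
  zs <- zs[keep]; s <- s[keep]
  th <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  M <- length(zs)
  rp <- array(0, c(M, n_points, 3))
  for (r in seq_len(M)) {
    rp[r, , 1] <- cx + a * s[r] * cos(th)
    rp[r, , 2] <- cy + b * s[r] * sin(th)
    rp[r, , 3] <- zs[r]
  }
  make_tube_mesh(rp, apex_pt = c(cx, cy, zb - cc))
}

disc_brush <- function(r) {
  EBImage::makeBrush(2L * as.integer(r) + 1L, shape = "disc")
}

stamp_disc <- function(m, cx, cy, r, value) {
  nx <- nrow(m); ny <- ncol(m)
  xr <- max(1L, cx - r):min(nx, cx + r)
  yr <- max(1L, cy - r):min(ny, cy + r)
  sub <- outer((xr - cx)^2, (yr - cy)^2, "+") <= r^2
  block <- m[xr, yr, drop = FALSE]
  block[sub] <- value
  m[xr, yr] <- block
  m
}

#' Degrade a clean mask to emulate coarse per-slice network output
#'
#' Applies, slice by slice along z: random morphological boundary jitter
#' (erosion or dilation by up to `boundary_jitter` voxels), random hole
#' dropout inside the foreground, and spurious off-target blobs — the failure
#' modes a coarse per-slice segmenter exhibits. With all rates and the jitter
#' at zero the input is returned unchanged; a fixed seed gives reproducible
#' degradation.
#'
#' @param mask A [label_mask()].
#' @param dropout_rate Per-slice probability of punching a hole, in `[0, 1)`.
#' @param blob_rate Per-slice probability of adding a spurious blob, in `[0, 1)`.
#' @param boundary_jitter Maximum erosion/dilation radius in voxels (>= 0).
#' @param seed Integer RNG seed.
#' @return A degraded [label_mask()] with the same geometry.
#' @export
degrade_mask <- function(mask, dropout_rate = 0.05, blob_rate = 0.1,
                         boundary_jitter = 1, seed = 1L) {
  stopifnot(inherits(mask, "lv_mask"))
  if (dropout_rate < 0 || dropout_rate >= 1 || blob_rate < 0 || blob_rate >= 1) {
    stop("rates must lie in [0, 1)", call. = FALSE)
  }
  boundary_jitter <- as.integer(boundary_jitter)
  if (boundary_jitter < 0) stop("boundary_jitter must be >= 0", call. = FALSE)
  if (dropout_rate == 0 && blob_rate == 0 && boundary_jitter == 0) return(mask)

  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  d <- dim(mask$data)
  out <- mask$data
  for (z in seq_len(d[3])) {
    m <- out[, , z]
    has_fg <- any(m > 0)
    if (has_fg && boundary_jitter > 0) {
      j <- sample(seq(-boundary_jitter, boundary_jitter), 1)
      if (j > 0) {
        m <- EBImage::dilate(m, disc_brush(j))
      } else if (j < 0) {
        m <- EBImage::erode(m, disc_brush(-j))
      }
    }
    if (has_fg && dropout_rate > 0 && stats::runif(1) < dropout_rate && any(m > 0)) {
      fg <- which(m > 0, arr.ind = TRUE)
      p <- fg[sample.int(nrow(fg), 1), ]
      m <- stamp_disc(m, p[1], p[2], sample(1:3, 1), 0L)
    }
    if (blob_rate > 0 && stats::runif(1) < blob_rate) {
      r <- sample(2:4, 1)
      fg <- which(m > 0, arr.ind = TRUE)
      for (try in 1:20) {
        cx <- sample.int(d[1], 1); cy <- sample.int(d[2], 1)
        clear <- if (nrow(fg) == 0) TRUE else
          min((fg[, 1] - cx)^2 + (fg[, 2] - cy)^2) > (r + 2)^2
        if (clear && cx > r && cy > r && cx <= d[1] - r && cy <= d[2] - r) {
          m <- stamp_disc(m, cx, cy, r, 1L)
          break
        }
      }
    }
    out[, , z] <- as.integer(m > 0)
  }
  label_mask(out, mask$spacing, mask$origin)
}

#' Build a training set of phantom slices
#'
#' Generates one or more phantoms (differing only in seed), slices them along
#' z, and deterministically subsamples to `n_slices` — the standard toy
#' training set for the coarse network.
#'
#' @param n_slices Slices to keep (<= total available).
#' @param seeds Phantom seeds, one phantom per seed.
#' @param spec Base [phantom_spec()]; its seed is overridden per phantom.
#' @param subsample_seed Seed for the slice subsample.
#' @return A `slice_stack` with masks.
#' @export
phantom_slice_dataset <- function(n_slices = 200, seeds = 1:3,
                                  spec = phantom_spec(),
                                  subsample_seed = 99L) {
  stacks <- lapply(seeds, function(s) {
    sp <- spec
    sp$seed <- as.integer(s)
    ph <- generate_phantom(sp)
    slice_volume(ph$volume, ph$mask, provenance = sprintf("phantom%d", s))
  })
  st <- do.call(concat_stacks, stacks)
  total <- length(st$images)
  stopifnot(n_slices <= total)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(subsample_seed)
  keep <- sample(seq_len(total), n_slices)
  st$images <- st$images[keep]
  st$masks <- st$masks[keep]
  st$z_index <- st$z_index[keep]
  st
}
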