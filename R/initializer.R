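#' Per-slice LV center estimates from coarse masks
#'
#' The raw center of a slice is the arithmetic mean of its foreground pixel
#' coordinates. Slices without foreground are kept in the table with `NA`
#' centers (flagged, never fabricated); at least 3 foreground slices are
#' required, since the downstream center-curve correction fits a quadratic.
#'
#' @param stack A `slice_stack` with masks (coarse segmentation output).
#' @return A tibble with one row per slice: `z` (0-based slice index), `cx`,
#'   `cy` (1-based pixel coordinates of the foreground centroid, `NA` when
#'   empty), `n_fg` (foreground pixel count).
#' @export
estimate_centers <- function(stack) {
  stopifnot(inherits(stack, "slice_stack"))
  if (is.null(stack$masks)) stop("stack has no masks", call. = FALSE)
  rows <- lapply(seq_along(stack$masks), function(i) {
    m <- stack$masks[[i]]
    fg <- which(m > 0, arr.ind = TRUE)
    if (nrow(fg) == 0) {
      tibble::tibble(z = stack$z_index[i], cx = NA_real_, cy = NA_real_,
                     n_fg = 0L)
    } else {
      tibble::tibble(z = stack$z_index[i], cx = mean(fg[, 1]),
                     cy = mean(fg[, 2]), n_fg = nrow(fg))
    }
  })
  out <- dplyr::bind_rows(rows)
  if (sum(out$n_fg > 0) < 3) {
    stop("fewer than 3 slices contain foreground; cannot initialize",
         call. = FALSE)
  }
  out
}

#' Quadratic center-curve correction
#'
#' Least-squares fits `x(z)` and `y(z)` as quadratic polynomials in the slice
#' index over slices with foreground, then evaluates the fitted curves at every
#' slice — including empty interior slices, which are thereby interpolated.
#' This removes slice-to-slice misalignment of the raw centroids before the
#' tube mesh is stacked.
#'
#' @param centers Tibble from [estimate_centers()].
#' @param weights Optional per-slice fitting weights (recycled to the
#'   foreground slices). `NULL` fits ordinary (unweighted) least squares;
#'   [initialize_lv_mesh()] passes the foreground areas, which damps the
#'   leverage of small apical slices whose centroids are easily corrupted by
#'   spurious islands.
#' @return The input tibble with columns `cx_fit`, `cy_fit` appended, plus
#'   attribute `coef` (a 3 x 2 matrix of polynomial coefficients: intercept,
#'   z, z^2).
#' @export
fit_center_curve <- function(centers, weights = NULL) {
  ok <- !is.na(centers$cx)
  if (sum(ok) < 3) stop("need at least 3 non-empty slices", call. = FALSE)
  z <- centers$z[ok]
  if (length(unique(z)) < 3) {
    stop("degenerate fit: fewer than 3 distinct z positions", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, sum(ok)) else {
    stopifnot(length(weights) %in% c(sum(ok), nrow(centers)))
    ww <- if (length(weights) == nrow(centers)) weights[ok] else weights
    if (any(ww < 0)) stop("weights must be >= 0", call. = FALSE)
    ww
  }
  X <- cbind(1, z, z^2)
  Xw <- X * w
  cf <- qr.solve(crossprod(Xw, X),
                 crossprod(Xw, cbind(centers$cx[ok], centers$cy[ok])))
  Za <- cbind(1, centers$z, centers$z^2)
  centers$cx_fit <- as.numeric(Za %*% cf[, 1])
  centers$cy_fit <- as.numeric(Za %*% cf[, 2])
  attr(centers, "coef") <- cf
  centers
}

main_component <- function(m, center) {
  lab <- EBImage::bwlabel(m)
  if (max(lab) <= 1) return(m > 0)
  ci <- round(center)
  ci[1] <- min(max(ci[1], 1), nrow(m))
  ci[2] <- min(max(ci[2], 1), ncol(m))
  target <- lab[ci[1], ci[2]]
  if (target == 0) {
    sizes <- tabulate(lab[lab > 0])
    target <- which.max(sizes)
  }
  lab == target
}

#' Circular contour estimate of one slice by 8-ray casting
#'
#' Casts `n_rays` rays from the (corrected) center at equal angles and takes
#' `R_i` as the distance to the outermost foreground-to-background transition
#' of the slice's main connected component along ray `i` (spurious islands are
#' ignored). The ring radius is the mean of the valid rays,
#' `R = (R_1 + ... + R_8) / 8`, and the contour is sampled as `n_points`
#' equally spaced points on the circle of radius `R` — the circular LV
#' cross-section assumption.
#'
#' @param mask_slice 2D binary matrix.
#' @param center Length-2 center `(x, y)` in 1-based pixel coordinates; must
#'   lie inside the image.
#' @param n_rays Number of rays (default 8, at 45 degree increments).
#' @param n_points Contour points sampled on the fitted circle.
#' @param step Ray-marching step in pixels.
#' @param min_valid_rays Slices with fewer valid rays are rejected.
#' @return An object of class `contour_ring`: `center`, `ray_radii` (length
#'   `n_rays`, `NA` where a ray saw no foreground), `R`, `points`
#'   (`n_points x 2`), `n_valid`.
#' @export
estimate_ring <- function(mask_slice, center, n_rays = 8, n_points = 36,
                          step = 0.25, min_valid_rays = 4) {
  stopifnot(is.matrix(mask_slice), length(center) == 2)
  nx <- nrow(mask_slice); ny <- ncol(mask_slice)
  if (center[1] < 1 || center[1] > nx || center[2] < 1 || center[2] > ny) {
    stop("center lies outside the image", call. = FALSE)
  }
  if (!any(mask_slice > 0)) stop("empty slice", call. = FALSE)
  comp <- main_component(mask_slice, center)
  ang <- (seq_len(n_rays) - 1) * 2 * pi / n_rays
  radii <- rep(NA_real_, n_rays)
  rmax <- sqrt(nx^2 + ny^2)
  ts <- seq(0, rmax, by = step)
  for (i in seq_len(n_rays)) {
    xs <- center[1] + ts * cos(ang[i])
    ys <- center[2] + ts * sin(ang[i])
    inb <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny
    if (!any(inb)) next
    hit <- comp[cbind(round(xs[inb]), round(ys[inb]))]
    if (any(hit)) radii[i] <- ts[inb][max(which(hit))]
  }
  n_valid <- sum(!is.na(radii))
  if (n_valid < min_valid_rays) {
    stop(sprintf("only %d of %d rays hit foreground; slice rejected",
                 n_valid, n_rays), call. = FALSE)
  }
  R <- mean(radii, na.rm = TRUE)
  th <- seq(0, 2 * pi, length.out = n_points + 1)[seq_len(n_points)]
  pts <- cbind(center[1] + R * cos(th), center[2] + R * sin(th))
  structure(list(center = as.numeric(center), ray_radii = radii, R = R,
                 points = pts, n_valid = n_valid),
            class = "contour_ring")
}

#' @exportS3Method base::print
print.contour_ring <- function(x, ...) {
  cat(sprintf("<contour_ring> center (%.2f, %.2f), R = %.3f px (%d/%d rays)\n",
              x$center[1], x$center[2], x$R, x$n_valid, length(x$ray_radii)))
  invisible(x)
}

#' Equal-interval contour resampling
#'
#' Keeps every `k`-th contour starting from the first (0-based positions
#' `0, k, 2k, ...`); the last (basal-most) contour is always appended if the
#' stride does not land on it, so the mesh spans the full chamber.
#'
#' @param rings List of contours ordered along the long axis.
#' @param k Sampling interval (>= 1); `k = 1` keeps everything.
#' @return The resampled list; attribute `positions` gives the kept 0-based
#'   positions.
#' @export
resample_contours <- function(rings, k) {
  if (k < 1) stop("sampling interval k must be >= 1", call. = FALSE)
  k <- as.integer(k)
  M <- length(rings)
  pos <- seq(1L, M, by = k)
  if (pos[length(pos)] != M) pos <- c(pos, M)
  out <- rings[pos]
  attr(out, "positions") <- pos - 1L
  out
}

#' Detect which z end of a mask stack is the apex
#'
#' The LV cross-section area shrinks toward the apex; the end with the smaller
#' mean foreground area (over its nearest foreground slices) is called apical.
#'
#' @param centers Tibble from [estimate_centers()].
#' @return `"low_z"` or `"high_z"`.
#' @export
detect_apex_direction <- function(centers) {
  ok <- centers$n_fg > 0
  z <- centers$z[ok]; a <- centers$n_fg[ok]
  n <- length(z)
  h <- max(1L, n %/% 3L)
  lo <- mean(a[order(z)][seq_len(h)])
  hi <- mean(a[order(z)][(n - h + 1):n])
  if (lo < hi) "low_z" else "high_z"
}

#' Build the initialization tube mesh from per-slice contours
#'
#' Stitches the (resampled) contour rings into a tube mesh in mm coordinates:
#' adjacent rings are joined band by band (matching points by angular index),
#' the apical end is capped by a triangle fan to an apex vertex placed one
#' slice beyond the apical ring on the fitted center curve, and the base is
#' left open.
#'
#' @param rings List of `contour_ring`s with a `z` field (slice index),
#'   ordered from apex to base.
#' @param spacing Voxel spacing (mm), length 3.
#' @param apex_center Length-2 `(x, y)` pixel coordinates of the apex vertex.
#' @param apex_z Slice index (0-based, may be fractional) of the apex vertex.
#' @param origin World position of voxel (1,1,1), mm.
#' @return A `tube_mesh` (mm).
#' @export
rings_to_mesh <- function(rings, spacing, apex_center, apex_z,
                          origin = c(0, 0, 0)) {
  M <- length(rings)
  if (M < 2) stop("need at least 2 rings", call. = FALSE)
  N <- nrow(rings[[1]]$points)
  if (!all(vapply(rings, function(r) nrow(r$points), 1L) == N)) {
    stop("rings have mismatched point counts", call. = FALSE)
  }
  rp <- array(0, c(M, N, 3))
  for (r in seq_len(M)) {
    rp[r, , 1] <- origin[1] + (rings[[r]]$points[, 1] - 1) * spacing[1]
    rp[r, , 2] <- origin[2] + (rings[[r]]$points[, 2] - 1) * spacing[2]
    rp[r, , 3] <- origin[3] + rings[[r]]$z * spacing[3]
  }
  apex <- c(origin[1] + (apex_center[1] - 1) * spacing[1],
            origin[2] + (apex_center[2] - 1) * spacing[2],
            origin[3] + apex_z * spacing[3])
  make_tube_mesh(rp, apex)
}

#' Automatic geometric initialization of the LV surface from coarse masks
#'
#' The full initialization pipeline: per-slice foreground centroids, quadratic
#' center-curve correction, 8-ray radius averaging on the corrected centers,
#' equal-interval contour resampling, and tube-mesh reconstruction with an
#' apical cap. The result is the initialization surface the 3D snake refines
#' and is also its spatial-regularization anchor.
#'
#' @param stack A `slice_stack` whose masks are the coarse segmentation.
#' @param k Contour sampling interval along z (default 10).
#' @param n_points Contour points per ring.
#' @param n_rays Rays per slice for radius estimation.
#' @param apex_direction `"auto"` (area-gradient detection), `"low_z"`, or
#'   `"high_z"`.
#' @param min_fg Slices with fewer foreground pixels are skipped as unreliable.
#' @return An object of class `lv_initialization`: `mesh` (a `tube_mesh`),
#'   `rings` (tibble: `z`, `cx`, `cy`, `R`, `n_valid`), `centers` (tibble from
#'   [fit_center_curve()]), `apex_direction`, `basal_z_mm`.
#' @export
initialize_lv_mesh <- function(stack, k = 10, n_points = 36, n_rays = 8,
                               apex_direction = c("auto", "low_z", "high_z"),
                               min_fg = 9) {
  apex_direction <- match.arg(apex_direction)
  centers <- estimate_centers(stack)
  centers <- fit_center_curve(centers, weights = centers$n_fg)
  if (apex_direction == "auto") apex_direction <- detect_apex_direction(centers)
  usable <- centers$n_fg >= min_fg
  zs <- centers$z[usable]
  ord <- order(zs, decreasing = (apex_direction == "high_z"))  # apex first
  zs <- zs[ord]
  rings <- list()
  for (z in zs) {
    i <- match(z, stack$z_index)
    row <- centers[centers$z == z, ]
    ring <- tryCatch(
      estimate_ring(stack$masks[[i]], c(row$cx_fit, row$cy_fit),
                    n_rays = n_rays, n_points = n_points),
      error = function(e) NULL)
    if (!is.null(ring)) {
      ring$z <- z
      rings[[length(rings) + 1]] <- ring
    }
  }
  if (length(rings) < 2) stop("fewer than 2 usable contour rings", call. = FALSE)
  rings <- resample_contours(rings, k)
  cf <- attr(centers, "coef")
  z_apical <- rings[[1]]$z
  dz <- if (apex_direction == "low_z") -1 else 1
  apex_z <- z_apical + dz
  apex_center <- c(sum(cf[, 1] * c(1, apex_z, apex_z^2)),
                   sum(cf[, 2] * c(1, apex_z, apex_z^2)))
  mesh <- rings_to_mesh(rings, stack$spacing, apex_center, apex_z,
                        origin = stack$origin)
  ring_tbl <- dplyr::bind_rows(lapply(rings, function(r) {
    tibble::tibble(z = r$z, cx = r$center[1], cy = r$center[2], R = r$R,
                   n_valid = r$n_valid)
  }))
  basal_z_mm <- stack$origin[3] + rings[[length(rings)]]$z * stack$spacing[3]
  structure(list(mesh = mesh, rings = ring_tbl, centers = centers,
                 apex_direction = apex_direction, basal_z_mm = basal_z_mm,
                 k = k),
            class = "lv_initialization")
}

#' @exportS3Method base::print
print.lv_initialization <- function(x, ...) {
  cat(sprintf("<lv_initialization> %d rings (k = %d), apex toward %s, basal plane %.1f mm\n",
              nrow(x$rings), x$k, x$apex_direction, x$basal_z_mm))
  invisible(x)
}

#' Write the initialization ring table as YAML
#'
#' @param init An `lv_initialization`.
#' @param path Output YAML path.
#' @export
write_ring_table <- function(init, path) {
  yaml::write_yaml(list(
    apex_direction = init$apex_direction,
    basal_z_mm = init$basal_z_mm,
    k = init$k,
    rings = lapply(seq_len(nrow(init$rings)), function(i) {
      r <- init$rings[i, ]
      list(z = r$z, center = c(r$cx, r$cy), R = r$R)
    })), path)
  invisible(path)
}
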