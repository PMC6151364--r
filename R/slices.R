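#' Slice a volume (and mask) into an ordered 2D slice stack
#'
#' Converts a 3D volume into the per-slice currency of the coarse segmentation
#' stage: 2D gray images along z, in ascending z order, with matching binary
#' masks. This is also the data-multiplication step — one volume of Z planes
#' yields Z training samples.
#'
#' @param vol An [volume()].
#' @param mask Optional aligned [label_mask()].
#' @param provenance Identifier recorded on the stack.
#' @return An object of class `slice_stack`: `images` (list of matrices),
#'   `masks` (list or NULL), `z_index` (0-based), `spacing`, `provenance`.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_shape = c(24, 24, 32),
#'                                     cavity_semi_axes = c(6, 6, 12),
#'                                     atrium_enabled = FALSE))
#' st <- slice_volume(ph$volume, ph$mask)
#' length(st$images)
#' @export
slice_volume <- function(vol, mask = NULL, provenance = "volume") {
  stopifnot(inherits(vol, "lv_volume"))
  if (!is.null(mask)) check_aligned(vol, mask)
  d <- dim(vol$data)
  images <- lapply(seq_len(d[3]), function(z) vol$data[, , z])
  masks <- if (is.null(mask)) NULL else
    lapply(seq_len(d[3]), function(z) mask$data[, , z])
  structure(list(images = images, masks = masks,
                 z_index = seq_len(d[3]) - 1L,
                 spacing = vol$spacing, origin = vol$origin,
                 provenance = provenance),
            class = "slice_stack")
}

#' @exportS3Method base::print
print.slice_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("<slice_stack> %d slices of %d x %d (%s masks), from '%s'\n",
              length(x$images), d[1], d[2],
              if (is.null(x$masks)) "no" else "with", x$provenance))
  invisible(x)
}

#' Restack slices into a 3D volume or mask (inverse of slicing)
#'
#' @param stack A `slice_stack` whose `z_index` covers `0:(Z-1)` exactly once.
#' @param what `"image"` or `"mask"`.
#' @return An [volume()] or [label_mask()] with the stack's geometry.
#' @export
restack_slices <- function(stack, what = c("image", "mask")) {
  what <- match.arg(what)
  src <- if (what == "image") stack$images else stack$masks
  if (is.null(src)) stop("stack has no masks to restack", call. = FALSE)
  ord <- order(stack$z_index)
  zi <- stack$z_index[ord]
  if (!identical(as.integer(zi), seq_along(zi) - 1L)) {
    stop("stack z indices do not form a complete volume (augmented stack?)",
         call. = FALSE)
  }
  d2 <- dim(src[[1]])
  a <- array(0, c(d2, length(src)))
  for (k in seq_along(ord)) a[, , k] <- src[[ord[k]]]
  if (what == "mask") label_mask(a, stack$spacing, stack$origin)
  else volume(a, stack$spacing, stack$origin)
}

#' Concatenate slice stacks into one training set
#'
#' @param ... `slice_stack` objects sharing one slice shape.
#' @return A combined `slice_stack`.
#' @export
concat_stacks <- function(...) {
  stacks <- list(...)
  stopifnot(length(stacks) >= 1)
  st <- stacks[[1]]
  for (k in seq_along(stacks)[-1]) {
    s <- stacks[[k]]
    stopifnot(identical(dim(s$images[[1]]), dim(st$images[[1]])))
    st$images <- c(st$images, s$images)
    if (!is.null(st$masks)) st$masks <- c(st$masks, s$masks)
    st$z_index <- c(st$z_index, s$z_index)
  }
  st$provenance <- paste(vapply(stacks, function(s) s$provenance, ""),
                         collapse = "+")
  st
}

#' Replicate a single-channel image into three identical channels
#'
#' Matches the input contract of backbones pretrained on RGB natural images:
#' the gray channel is copied three times.
#'
#' @param img 2D numeric matrix.
#' @return `H x W x 3` array with identical channels.
#' @export
to_three_channel <- function(img) {
  stopifnot(is.matrix(img))
  array(rep(as.numeric(img), 3), c(dim(img), 3))
}

bilinear_sample_2d <- function(img, xs, ys) {
  # zero outside the image; xs/ys are 1-based continuous pixel coordinates.
  # The small tolerance keeps exact rotations (90 degrees etc.) from losing
  # border pixels to floating-point round-off.
  eps <- 1e-9
  nx <- nrow(img); ny <- ncol(img)
  inside <- xs >= 1 - eps & xs <= nx + eps & ys >= 1 - eps & ys <= ny + eps
  xs <- pmin(pmax(xs, 1), nx); ys <- pmin(pmax(ys, 1), ny)
  x0 <- pmin(floor(xs), nx - 1L); y0 <- pmin(floor(ys), ny - 1L)
  x0 <- pmax(x0, 1); y0 <- pmax(y0, 1)
  fx <- xs - x0; fy <- ys - y0
  v00 <- img[cbind(x0, y0)]; v10 <- img[cbind(x0 + 1, y0)]
  v01 <- img[cbind(x0, y0 + 1)]; v11 <- img[cbind(x0 + 1, y0 + 1)]
  out <- (v00 * (1 - fx) + v10 * fx) * (1 - fy) + (v01 * (1 - fx) + v11 * fx) * fy
  out[!inside] <- 0
  out
}

rotate_scale_slice <- function(img, angle_deg, scale, binarize = FALSE) {
  nx <- nrow(img); ny <- ncol(img)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- angle_deg * pi / 180
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  dx <- g$x - cx; dy <- g$y - cy
  # inverse map: rotate by -theta, scale by 1/scale
  xs <- cx + (cos(th) * dx + sin(th) * dy) / scale
  ys <- cy + (-sin(th) * dx + cos(th) * dy) / scale
  vals <- bilinear_sample_2d(img, xs, ys)
  out <- matrix(vals, nx, ny)
  if (binarize) out <- (out >= 0.5) * 1L
  out
}

#' Randomly rotate and rescale a slice stack (data augmentation)
#'
#' Appends `n_augments` randomly transformed copies of every slice; the same
#' geometric transform is applied to a slice and its mask, and masks are
#' re-binarized at 0.5 after bilinear interpolation.
#'
#' @param stack A `slice_stack`.
#' @param n_augments Copies per slice (0 returns the stack unchanged).
#' @param rotation_range Max absolute rotation, degrees (uniform in +/- range).
#' @param scale_range Max relative scale change (uniform in 1 +/- range).
#' @param seed Integer RNG seed.
#' @return An augmented `slice_stack` of `(1 + n_augments) * length` slices.
#' @export
augment_slices <- function(stack, n_augments = 10, rotation_range = 30,
                           scale_range = 0.1, seed = 1L) {
  stopifnot(inherits(stack, "slice_stack"),
            n_augments >= 0, rotation_range >= 0,
            scale_range >= 0, scale_range < 1)
  if (n_augments == 0) return(stack)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(stack$images)
  images <- stack$images
  masks <- stack$masks
  zi <- stack$z_index
  for (k in seq_len(n_augments)) {
    ang <- stats::runif(n, -rotation_range, rotation_range)
    sc <- stats::runif(n, 1 - scale_range, 1 + scale_range)
    for (i in seq_len(n)) {
      images[[length(images) + 1]] <- rotate_scale_slice(stack$images[[i]], ang[i], sc[i])
      if (!is.null(masks)) {
        masks[[length(masks) + 1]] <-
          rotate_scale_slice(stack$masks[[i]], ang[i], sc[i], binarize = TRUE)
      }
      zi <- c(zi, stack$z_index[i])
    }
  }
  structure(list(images = images, masks = masks, z_index = zi,
                 spacing = stack$spacing, origin = stack$origin,
                 provenance = paste0(stack$provenance, "+aug")),
            class = "slice_stack")
}
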