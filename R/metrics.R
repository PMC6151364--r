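#' @name surface-distances
#' @title Surface distance metrics between two surfaces
#'
#' @description
#' `mean_surface_distance()` computes `d_m = dbar(S, S_t) + dbar(S_t, S)`,
#' the sum of the two directed mean nearest-point distances (the printed
#' convention of the benchmark; set `averaged = TRUE` for the averaged
#' convention used by much of the literature). `hausdorff_distance()` computes
#' the standard symmetric Hausdorff distance
#' `d_h = max(max_s min_t |s - t|, max_t min_s |t - s|)`.
#'
#' Surfaces may be given as point matrices (`n x 3`, mm) or as meshes
#' (`tube_mesh` / `ply_mesh`), which are densely resampled with area weighting
#' before measuring.
#'
#' @param s,s_t The evaluated and reference surfaces.
#' @param n_samples Surface sample density used for meshes.
#' @param seed Seed for the area-weighted sampling (fixed default so repeated
#'   evaluations agree).
#' @param averaged Average the two directed means instead of summing.
#' @return Distance in mm.
NULL

as_surface_points <- function(x, n_samples = 5000, seed = 1L) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    if (nrow(x) == 0) stop("empty surface", call. = FALSE)
    return(x)
  }
  if (!is.null(x$vertices) && !is.null(x$faces)) {
    return(sample_surface(x, n_samples, seed = seed))
  }
  stop("cannot interpret object as a surface", call. = FALSE)
}

# per-point nearest-neighbor distances from P to Q, chunked brute force
nn_distances <- function(P, Q, chunk = 512L) {
  q2 <- rowSums(Q^2)
  out <- numeric(nrow(P))
  for (i in seq(1, nrow(P), by = chunk)) {
    idx <- i:min(i + chunk - 1L, nrow(P))
    d2 <- outer(rowSums(P[idx, , drop = FALSE]^2), q2, "+") -
      2 * P[idx, , drop = FALSE] %*% t(Q)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' @rdname surface-distances
#' @export
mean_surface_distance <- function(s, s_t, n_samples = 5000, seed = 1L,
                                  averaged = FALSE) {
  P <- as_surface_points(s, n_samples, seed)
  Q <- as_surface_points(s_t, n_samples, seed + 1L)
  d <- mean(nn_distances(P, Q)) + mean(nn_distances(Q, P))
  if (averaged) d / 2 else d
}

#' @rdname surface-distances
#' @export
hausdorff_distance <- function(s, s_t, n_samples = 5000, seed = 1L) {
  P <- as_surface_points(s, n_samples, seed)
  Q <- as_surface_points(s_t, n_samples, seed + 1L)
  max(max(nn_distances(P, Q)), max(nn_distances(Q, P)))
}

#' Volume of a binary mask in millilitres
#'
#' Foreground voxel count times voxel volume (mm^3), divided by 1000.
#'
#' @param mask A [label_mask()].
#' @return Volume in ml.
#' @export
mask_volume_ml <- function(mask) {
  sum(mask$data > 0) * prod(mask$spacing) / 1000
}

#' Modified Dice dissimilarity D*
#'
#' `D* = 1 - 2 (V intersect V_t) / (V + V_t)` computed by voxel counting:
#' 0 means perfect agreement, 1 disjoint masks.
#'
#' @param mask A [label_mask()] (evaluated segmentation).
#' @param mask_t Reference [label_mask()], aligned with `mask`.
#' @return Dissimilarity in `[0, 1]`.
#' @export
modified_dice <- function(mask, mask_t) {
  check_aligned(mask, mask_t)
  va <- sum(mask$data > 0)
  vb <- sum(mask_t$data > 0)
  if (va + vb == 0) stop("both masks are empty; D* undefined", call. = FALSE)
  vi <- sum(mask$data > 0 & mask_t$data > 0)
  1 - 2 * vi / (va + vb)
}

#' Ejection fraction
#'
#' `EF = (EDV - ESV) / EDV`, the fraction of the end-diastolic volume ejected
#' during systole.
#'
#' @param edv End-diastolic volume (ml), > 0.
#' @param esv End-systolic volume (ml).
#' @return EF as a fraction.
#' @examples
#' ejection_fraction(100, 60)  # 0.4
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) stop("EDV must be > 0", call. = FALSE)
  (edv - esv) / edv
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of estimate minus reference), the sample standard deviation of
#' the paired differences, and the 95% limits of agreement
#' `bias +/- 1.96 sd`.
#'
#' @param estimate,reference Paired numeric vectors (>= 2 pairs).
#' @return An object of class `bland_altman` with fields `bias`, `sd`,
#'   `lower`, `upper`, `n`, and `data` (tibble of pair means and differences).
#' @examples
#' ba <- bland_altman(c(101, 99, 103), c(100, 100, 100))
#' ba$bias
#' @export
bland_altman <- function(estimate, reference) {
  stopifnot(length(estimate) == length(reference))
  if (length(estimate) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- estimate - reference
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 lower = bias - 1.96 * s, upper = bias + 1.96 * s,
                 n = length(d),
                 data = tibble::tibble(mean = (estimate + reference) / 2,
                                       difference = d)),
            class = "bland_altman")
}

#' @exportS3Method base::print
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d bias=%.4g sd=%.4g limits [%.4g, %.4g]\n",
              x$n, x$bias, x$sd, x$lower, x$upper))
  invisible(x)
}

#' Two-class confusion counts
#'
#' `n[i, j]` counts pixels of truth class `i` predicted as class `j`
#' (row/column 1 = background, 2 = foreground). Inputs may be single binary
#' matrices or lists of them (aggregated).
#'
#' @param pred Predicted mask(s).
#' @param truth Ground-truth mask(s) of identical shapes.
#' @return 2 x 2 integer matrix of class `confusion_counts`.
#' @export
confusion_counts <- function(pred, truth) {
  if (is.matrix(pred)) pred <- list(pred)
  if (is.matrix(truth)) truth <- list(truth)
  stopifnot(length(pred) == length(truth))
  n <- matrix(0, 2, 2, dimnames = list(truth = c("bg", "fg"),
                                       pred = c("bg", "fg")))
  for (i in seq_along(pred)) {
    p <- pred[[i]] > 0
    t <- truth[[i]] > 0
    stopifnot(identical(dim(p), dim(t)))
    n[1, 1] <- n[1, 1] + sum(!t & !p)
    n[1, 2] <- n[1, 2] + sum(!t & p)
    n[2, 1] <- n[2, 1] + sum(t & !p)
    n[2, 2] <- n[2, 2] + sum(t & p)
  }
  structure(n, class = c("confusion_counts", "matrix"))
}

#' Pixel-level segmentation metrics
#'
#' From 2 x 2 confusion counts `n[i, j]` with truth class sizes
#' `t_i = sum_j n[i, j]`:
#' `acc = sum_i n_ii / sum_i t_i`;
#' `mean_acc = (sum_i n_ii / t_i) / 2`;
#' `mean_IOU = (1/2) sum_i n_ii / (t_i + sum_j n_ji - n_ii)`.
#' Classes absent from the truth are excluded from the two means with a
#' warning.
#'
#' @param counts A 2 x 2 matrix (rows = truth class, columns = predicted), as
#'   from [confusion_counts()].
#' @return Tibble with columns `acc`, `mean_acc`, `mean_iou`.
#' @examples
#' pixel_metrics(matrix(c(3, 1, 1, 5), 2, byrow = TRUE))
#' @export
pixel_metrics <- function(counts) {
  n <- unclass(counts)
  stopifnot(is.matrix(n), all(dim(n) == 2), all(n >= 0))
  ti <- rowSums(n)
  if (sum(ti) == 0) stop("all-zero confusion counts", call. = FALSE)
  present <- ti > 0
  if (!all(present)) {
    warning("class absent from truth excluded from mean acc / mean IOU")
  }
  acc <- sum(diag(n)) / sum(ti)
  mean_acc <- mean(diag(n)[present] / ti[present])
  iou <- diag(n) / (ti + colSums(n) - diag(n))
  mean_iou <- mean(iou[present])
  tibble::tibble(acc = acc, mean_acc = mean_acc, mean_iou = mean_iou)
}

#' Full segmentation evaluation report
#'
#' Compares an evaluated surface/mask pair against the reference: mean and
#' Hausdorff surface distance, modified Dice, and enclosed volumes.
#'
#' @param mesh,mesh_t Evaluated and reference surfaces (`tube_mesh`).
#' @param mask,mask_t Optional aligned [label_mask()] pair for `D*`.
#' @param n_samples Surface sampling density.
#' @param seed Sampling seed.
#' @return An object of class `metrics_report` (a list): `d_m`, `d_h`,
#'   `dstar` (`NA` without masks), `volume_ml`, `volume_t_ml`.
#' @export
evaluate_segmentation <- function(mesh, mesh_t, mask = NULL, mask_t = NULL,
                                  n_samples = 5000, seed = 1L) {
  dstar <- if (!is.null(mask) && !is.null(mask_t)) {
    modified_dice(mask, mask_t)
  } else NA_real_
  structure(list(
    d_m = mean_surface_distance(mesh, mesh_t, n_samples, seed),
    d_h = hausdorff_distance(mesh, mesh_t, n_samples, seed),
    dstar = dstar,
    volume_ml = enclosed_volume_ml(mesh),
    volume_t_ml = enclosed_volume_ml(mesh_t)),
    class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> d_m=%.3f mm d_h=%.3f mm D*=%s V=%.1f ml (ref %.1f ml)\n",
              x$d_m, x$d_h,
              if (is.na(x$dstar)) "NA" else sprintf("%.4f", x$dstar),
              x$volume_ml, x$volume_t_ml))
  invisible(x)
}

#' Write a metrics report as JSON (and optionally a flat CSV row)
#'
#' @param report A `metrics_report`.
#' @param path Output `.json` path.
#' @param csv_path Optional `.csv` path receiving a one-row table.
#' @export
write_metrics_report <- function(report, path, csv_path = NULL) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(tibble::as_tibble(unclass(report)), csv_path,
                     row.names = FALSE)
  }
  invisible(path)
}
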