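#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fusion FCN fit
#'
#' @param x An `fcn_fit` from [train_network()].
#' @param ... Unused.
#' @return Tibble with one row per iteration: `iteration`, `loss`, `lr`,
#'   `stage`.
#' @exportS3Method generics::tidy
tidy.fcn_fit <- function(x, ...) x$history

#' @rdname tidy.fcn_fit
#' @exportS3Method generics::glance
glance.fcn_fit <- function(x, ...) {
  tibble::tibble(
    iterations = nrow(x$history),
    final_loss = x$history$loss[nrow(x$history)],
    min_loss = min(x$history$loss),
    stage1_iter = x$train_config$stage1_iter,
    n_parameters = n_parameters(x$model))
}

#' @rdname tidy.fcn_fit
#' @exportS3Method ggplot2::autoplot
autoplot.fcn_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$loss,
                               colour = factor(.data$stage))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "weighted cross-entropy loss",
                  colour = "stage") +
    ggplot2::theme_minimal()
}

#' Tidy the energy history of a snake fit
#'
#' @param x A `snake_fit` from [evolve_snake()].
#' @param ... Unused.
#' @return Long tibble: `iteration`, `term`, `energy`.
#' @exportS3Method generics::tidy
tidy.snake_fit <- function(x, ...) {
  tidyr::pivot_longer(
    x$history[, c("iteration", "e_internal_1", "e_internal_2",
                  "e_external", "e_init", "total")],
    -"iteration", names_to = "term", values_to = "energy")
}

#' @rdname tidy.snake_fit
#' @exportS3Method generics::glance
glance.snake_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  tibble::tibble(
    iterations = x$iterations, converged = x$converged,
    total_energy = last$total, e_external = last$e_external,
    e_init = last$e_init, n_clamped = x$n_clamped)
}

#' @rdname tidy.snake_fit
#' @exportS3Method ggplot2::autoplot
autoplot.snake_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$energy,
                               colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "energy") +
    ggplot2::theme_minimal()
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return The per-pair tibble (`mean`, `difference`).
#' @exportS3Method generics::tidy
tidy.bland_altman <- function(x, ...) x$data

#' @rdname tidy.bland_altman
#' @exportS3Method generics::glance
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd = x$sd, lower = x$lower, upper = x$upper,
                 n = x$n)
}

#' @rdname tidy.bland_altman
#' @exportS3Method ggplot2::autoplot
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(object$lower, object$upper),
                        linetype = 2) +
    ggplot2::labs(x = "pair mean", y = "difference (estimate - reference)") +
    ggplot2::theme_minimal()
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return One-row tibble of the evaluation metrics.
#' @exportS3Method generics::tidy
tidy.metrics_report <- function(x, ...) tibble::as_tibble(unclass(x))

#' Plot a volume slice with optional mask and mesh cross-section overlays
#'
#' @param vol An [volume()].
#' @param z 0-based slice index.
#' @param mask Optional aligned [label_mask()] drawn as a contour.
#' @param mesh Optional `tube_mesh` whose vertices within half a slice of the
#'   plane are drawn as points.
#' @return A ggplot object.
#' @export
plot_slice <- function(vol, z, mask = NULL, mesh = NULL) {
  d <- dim(vol$data)
  stopifnot(z >= 0, z < d[3])
  sl <- vol$data[, , z + 1]
  df <- tidyr::expand_grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$value <- as.vector(sl)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "intensity")
  if (!is.null(mask)) {
    dm <- df
    dm$m <- as.vector(mask$data[, , z + 1])
    p <- p + ggplot2::geom_contour(data = dm,
                                   ggplot2::aes(z = .data$m),
                                   breaks = 0.5, colour = "red")
  }
  if (!is.null(mesh)) {
    zmm <- vol$origin[3] + z * vol$spacing[3]
    near <- abs(mesh$vertices[, 3] - zmm) <= vol$spacing[3] / 2
    if (any(near)) {
      pts <- tibble::tibble(
        x = (mesh$vertices[near, 1] - vol$origin[1]) / vol$spacing[1] + 1,
        y = (mesh$vertices[near, 2] - vol$origin[2]) / vol$spacing[2] + 1)
      p <- p + ggplot2::geom_point(data = pts, colour = "cyan", size = 0.8)
    }
  }
  p
}
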