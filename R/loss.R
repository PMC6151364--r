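#' Class-balanced weighted cross-entropy loss
#'
#' Per-pixel two-class cross-entropy in which the foreground (LV) term is
#' weighted by `a = Y- / (Y+ + Y-)` and the background term by `1 - a`, where
#' `Y+` and `Y-` count foreground and background pixels in the ground truth.
#' Because the LV typically occupies a small fraction of a slice, this weights
#' the rare class up and the dominant class down:
#'
#' `loss = -a * sum_fg log P(y=1) - (1 - a) * sum_bg log P(y=0)`
#'
#' Probabilities are clamped at `eps` before the log, so a confident wrong
#' prediction yields a large finite loss, never `NaN`.
#'
#' @param probs Foreground probability `P(y=1)` per pixel: a matrix the shape
#'   of `truth`, or an `H x W x 2` array of class probabilities (channel 1 =
#'   background, channel 2 = foreground) whose channels sum to 1.
#' @param truth Binary ground-truth matrix (1 = LV).
#' @param eps Clamp floor for the log argument.
#' @return An object of class `loss_terms`: `y_plus`, `y_minus`, `a`, `loss`.
#' @examples
#' truth <- matrix(c(1, 0, 0, 0), 2, 2)
#' p <- matrix(c(0.8, 0.4, 0.4, 0.4), 2, 2)
#' weighted_ce_loss(p, truth)$loss  # -0.75 log 0.8 - 0.25 * 3 log 0.6
#' @export
weighted_ce_loss <- function(probs, truth, eps = 1e-12) {
  stopifnot(is.matrix(truth))
  if (is.array(probs) && length(dim(probs)) == 3) {
    if (!all(dim(probs)[1:2] == dim(truth)) || dim(probs)[3] != 2) {
      stop("3D `probs` must be H x W x 2 matching `truth`", call. = FALSE)
    }
    s <- probs[, , 1] + probs[, , 2]
    if (max(abs(s - 1)) > 1e-6) {
      stop("class probabilities must sum to 1 at every pixel", call. = FALSE)
    }
    p1 <- probs[, , 2]
  } else {
    p1 <- probs
    if (!is.matrix(p1) || !all(dim(p1) == dim(truth))) {
      stop("`probs` and `truth` must have the same spatial shape", call. = FALSE)
    }
  }
  if (min(p1) < -1e-9 || max(p1) > 1 + 1e-9) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  fg <- truth > 0
  y_plus <- sum(fg)
  y_minus <- sum(!fg)
  a <- y_minus / (y_plus + y_minus)
  loss <- -a * sum(log(pmax(p1[fg], eps))) -
    (1 - a) * sum(log(pmax(1 - p1[!fg], eps)))
  structure(list(y_plus = y_plus, y_minus = y_minus, a = a, loss = loss),
            class = "loss_terms")
}

#' @exportS3Method base::print
print.loss_terms <- function(x, ...) {
  cat(sprintf("<loss_terms> Y+=%d Y-=%d a=%.4f loss=%.6g\n",
              x$y_plus, x$y_minus, x$a, x$loss))
  invisible(x)
}
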