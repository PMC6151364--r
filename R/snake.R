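#' Parameters of the spatially regularized 3D snake
#'
#' Energy weights and optimizer settings for the deformable surface. The
#' energy of the surface `X` is
#'
#' `E = sum( 1/2 alpha |X'|^2 + 1/2 beta |X''|^2 + delta E_ext(X) + eta |X - X_init|^2 )`
#'
#' with first/second parametric differences realized on the tube mesh (see
#' [internal_forces()]), an image-derived external energy (see
#' [external_field()]), and the spatial regularization term anchoring the
#' surface to its initialization `X_init` — the term that limits the freedom
#' of deformation and prevents boundary leak from the LV into the left atrium.
#' Default weights `alpha = 0.1, beta = 0.2, delta = 0.1, eta = 0.1` are the
#' reference setting; optimizer defaults are package choices.
#'
#' @param alpha First-order (tension) weight.
#' @param beta Second-order (rigidity) weight.
#' @param delta External (image) energy weight.
#' @param eta Spatial-regularization weight; 0 disables the anchor.
#' @param step_size Gradient-descent step (mm per unit force).
#' @param max_iters Iteration cap.
#' @param tol Convergence threshold on mean vertex displacement (mm).
#' @param sigma_ext Gaussian scale of the external field (mm).
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.1, beta = 0.2, delta = 0.1, eta = 0.1,
                         step_size = 0.1, max_iters = 500, tol = 1e-3,
                         sigma_ext = 2) {
  if (any(c(alpha, beta, delta, eta) < 0)) {
    stop("energy weights must be >= 0", call. = FALSE)
  }
  stopifnot(step_size > 0, tol > 0, max_iters >= 1, sigma_ext > 0)
  structure(list(alpha = unname(alpha), beta = unname(beta),
                 delta = unname(delta), eta = unname(eta),
                 step_size = unname(step_size), max_iters = as.integer(max_iters),
                 tol = unname(tol), sigma_ext = unname(sigma_ext)),
            class = "snake_params")
}

#' Image-derived external energy field
#'
#' The classical snake external energy: the negative squared gradient
#' magnitude of the Gaussian-smoothed image, `E_ext = -|grad(G_sigma * I)|^2`,
#' computed in mm-aware coordinates (anisotropic spacing respected) and by
#' default normalized so that `min E_ext = -1`, which makes the `delta` weight
#' independent of the image intensity scale. Energy and force queries at
#' arbitrary (mm) points use trilinear interpolation; the force is the exact
#' spatial derivative of the interpolant, so sampled energies and forces are
#' mutually consistent.
#'
#' @param vol An [volume()].
#' @param sigma_ext Gaussian scale (mm), > 0.
#' @param normalize Scale the field to `[-1, 0]`?
#' @return An object of class `external_field` with the energy [volume()] in
#'   `$energy`.
#' @export
external_field <- function(vol, sigma_ext = 2, normalize = TRUE) {
  if (sigma_ext <= 0) stop("sigma_ext must be > 0", call. = FALSE)
  sm <- gaussian_smooth_volume(vol, sigma_ext)
  g <- volume_gradient(sm)
  e <- -(g$gx$data^2 + g$gy$data^2 + g$gz$data^2)
  scale <- 1
  if (normalize) {
    m <- max(-min(e), 0)
    if (m > 0) {
      scale <- 1 / m
      e <- e * scale
    }
  }
  structure(list(energy = volume(e, vol$spacing, vol$origin),
                 sigma_ext = sigma_ext, scale = scale),
            class = "external_field")
}

#' Sample an external field: energy values and spatial gradient
#'
#' @param field An [external_field()].
#' @param pts `n x 3` matrix of world points (mm).
#' @return List with `value` (length n) and `gradient` (`n x 3`, per mm).
#' @export
sample_external <- function(field, pts) {
  trilinear_core(field$energy, pts)
}

# First- and second-difference operators of the tube mesh, as sparse matrices
# acting on the V x 3 vertex coordinate matrix. Rows of D1: circular
# differences along every ring plus chain differences along each vertical
# (angular-index) chain, the apex terminating every chain. Rows of D2: the
# corresponding second differences. Differences are arc-length weighted:
# first differences are divided by the rest length h of the edge and second
# differences use the uneven-spacing three-point stencil, with rest lengths
# measured on the mesh the operators are built from (the initialization).
# Without this, the vertical ring gap after contour resampling (k slices)
# would make axial tension dominate in-ring tension by the gap ratio. The
# internal energy is 1/2 alpha |D1 X|^2 + 1/2 beta |D2 X|^2, an exact
# quadratic form since the weights stay fixed.
snake_operators <- function(mesh) {
  M <- mesh$n_rings; N <- mesh$n_points
  ri <- mesh$ring_index; apex <- mesh$apex
  X0 <- mesh$vertices
  V <- nrow(X0)
  ip1 <- c(2:N, 1L)
  im1 <- c(N, 1:(N - 1))
  hmin <- 1e-6
  elen <- function(a, b) pmax(sqrt(rowSums((X0[a, , drop = FALSE] -
                                              X0[b, , drop = FALSE])^2)), hmin)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0); nr <- 0L
  add <- function(cidx, v) {
    k <- length(cidx)
    rows <<- c(rows, rep(nr + 1L, k)); cols <<- c(cols, cidx)
    vals <<- c(vals, v); nr <<- nr + 1L
  }
  # D1: ring circular first differences, (X_{i+1} - X_i) / h
  for (r in seq_len(M)) {
    h <- elen(ri[r, ip1], ri[r, ])
    for (i in seq_len(N)) add(c(ri[r, ip1[i]], ri[r, i]), c(1, -1) / h[i])
  }
  # D1: chain differences (apex -> ring1 -> ... -> ringM)
  for (i in seq_len(N)) {
    h <- elen(ri[1, i], apex)
    add(c(ri[1, i], apex), c(1, -1) / h)
    if (M > 1) for (r in seq_len(M - 1)) {
      h <- elen(ri[r + 1, i], ri[r, i])
      add(c(ri[r + 1, i], ri[r, i]), c(1, -1) / h)
    }
  }
  D1 <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nr, V))
  rows <- integer(0); cols <- integer(0); vals <- numeric(0); nr <- 0L
  # uneven-spacing second difference: 2/(h1+h2) * ((X_c - X_b)/h2 - (X_b - X_a)/h1)
  add2 <- function(a, b, cc, h1, h2) {
    s <- 2 / (h1 + h2)
    add(c(a, b, cc), c(s / h1, -s / h1 - s / h2, s / h2))
  }
  # D2: ring circular second differences
  for (r in seq_len(M)) {
    hfwd <- elen(ri[r, ip1], ri[r, ])
    for (i in seq_len(N)) {
      add2(ri[r, im1[i]], ri[r, i], ri[r, ip1[i]], hfwd[im1[i]], hfwd[i])
    }
  }
  # D2: chain second differences, apex as terminal node of every chain
  for (i in seq_len(N)) {
    if (M >= 2) {
      add2(apex, ri[1, i], ri[2, i], elen(ri[1, i], apex),
           elen(ri[2, i], ri[1, i]))
    }
    if (M > 2) for (r in 2:(M - 1)) {
      add2(ri[r - 1, i], ri[r, i], ri[r + 1, i],
           elen(ri[r, i], ri[r - 1, i]), elen(ri[r + 1, i], ri[r, i]))
    }
  }
  D2 <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(nr, V))
  list(D1 = D1, D2 = D2)
}

#' Internal (smoothness) forces of a tube mesh
#'
#' The gradient of the internal energy
#' `1/2 alpha |X'|^2 + 1/2 beta |X''|^2` with the parametric derivatives
#' realized as circular finite differences along each ring and chain
#' differences along the vertical (ring-to-ring) direction; the apex vertex
#' terminates every vertical chain, so its force is the fan-neighborhood
#' aggregate. Equal to `(alpha D1'D1 + beta D2'D2) X`; subtracting it is a
#' descent step on the internal energy.
#'
#' @param mesh A `tube_mesh`.
#' @param alpha,beta Non-negative weights.
#' @return `V x 3` matrix of per-vertex energy gradients.
#' @export
internal_forces <- function(mesh, alpha = 0.1, beta = 0.2) {
  ops <- snake_operators(mesh)
  K <- alpha * Matrix::crossprod(ops$D1) + beta * Matrix::crossprod(ops$D2)
  as.matrix(K %*% mesh$vertices)
}

snake_energy <- function(X, ops, field, X_init, params) {
  d1 <- ops$D1 %*% X
  d2 <- ops$D2 %*% X
  e1 <- 0.5 * params$alpha * sum(d1^2)
  e2 <- 0.5 * params$beta * sum(d2^2)
  e_ext <- if (params$delta > 0 && !is.null(field)) {
    params$delta * sum(sample_external(field, X)$value)
  } else 0
  e_init <- params$eta * sum((X - X_init)^2)
  c(e_internal_1 = e1, e_internal_2 = e2, e_external = e_ext,
    e_init = e_init, total = e1 + e2 + e_ext + e_init)
}

#' Evolve the 3D snake from its initialization mesh
#'
#' Explicit gradient descent `X <- X - tau * grad E` with
#' `grad E = (alpha D1'D1 + beta D2'D2) X + delta grad E_ext(X) + 2 eta (X - X_init)`.
#' Vertices move in full 3D; with `fix_base_plane = TRUE` the basal (last)
#' ring is additionally constrained to its plane (in-plane motion only) —
#' by default the spatial-regularization anchor is what stabilizes the open
#' base axially. Vertices leaving the volume bounds are clamped to the
#' boundary and counted. Iteration stops at `max_iters` or when the mean
#' vertex displacement of a step falls below `tol`.
#'
#' @param mesh_init A `tube_mesh`, the initialization `X_init`.
#' @param vol The intensity [volume()] (used when `delta > 0`).
#' @param params A [snake_params()].
#' @param field Optional precomputed [external_field()]; built from `vol` and
#'   `params$sigma_ext` when missing.
#' @param fix_base_plane Freeze the z coordinate of the basal ring?
#' @return An object of class `snake_fit`: `mesh` (final), `mesh_init`,
#'   `params`, `history` (tibble of per-iteration energy breakdown and mean
#'   displacement), `iterations`, `converged`, `n_clamped`.
#' @export
evolve_snake <- function(mesh_init, vol = NULL, params = snake_params(),
                         field = NULL, fix_base_plane = FALSE) {
  stopifnot(inherits(mesh_init, "tube_mesh"), inherits(params, "snake_params"))
  if (params$delta > 0 && is.null(field)) {
    if (is.null(vol)) stop("delta > 0 requires a volume or external field",
                           call. = FALSE)
    field <- external_field(vol, params$sigma_ext)
  }
  bounds <- if (!is.null(vol)) {
    rbind(vol$origin, vol$origin + (dim(vol$data) - 1) * vol$spacing)
  } else if (!is.null(field)) {
    e <- field$energy
    rbind(e$origin, e$origin + (dim(e$data) - 1) * e$spacing)
  } else NULL
  ops <- snake_operators(mesh_init)
  K <- params$alpha * Matrix::crossprod(ops$D1) +
    params$beta * Matrix::crossprod(ops$D2)
  X_init <- mesh_init$vertices
  X <- X_init
  base_ids <- mesh_init$ring_index[mesh_init$n_rings, ]
  hist <- vector("list", params$max_iters)
  n_clamped <- 0L
  converged <- FALSE
  it <- 0L
  tau <- params$step_size
  en_prev <- snake_energy(X, ops, field, X_init, params)
  while (it < params$max_iters) {
    it <- it + 1L
    grad <- as.matrix(K %*% X) + 2 * params$eta * (X - X_init)
    if (params$delta > 0) {
      grad <- grad + params$delta * sample_external(field, X)$gradient
    }
    if (fix_base_plane) grad[base_ids, 3] <- 0  # basal ring in-plane only
    # backtracking step control: halve tau until the step does not increase
    # the energy, guarding against explicit-Euler instability on degenerate
    # geometry (tau never grows back above step_size)
    repeat {
      X_new <- X - tau * grad
      if (!is.null(bounds)) {
        clamped <- X_new < matrix(bounds[1, ], nrow(X_new), 3, byrow = TRUE) |
          X_new > matrix(bounds[2, ], nrow(X_new), 3, byrow = TRUE)
        if (any(clamped)) {
          for (k in 1:3) {
            X_new[, k] <- pmin(pmax(X_new[, k], bounds[1, k]), bounds[2, k])
          }
        }
      } else clamped <- FALSE
      en <- snake_energy(X_new, ops, field, X_init, params)
      if (all(is.finite(en)) &&
          en[["total"]] <= en_prev[["total"]] + 1e-12 * (1 + abs(en_prev[["total"]]))) {
        break
      }
      tau <- tau / 2
      if (tau < params$step_size * 2^-30) {
        stop(sprintf("snake step collapsed at iteration %d (energy not decreasing)",
                     it), call. = FALSE)
      }
    }
    if (any(clamped)) n_clamped <- n_clamped + sum(rowSums(clamped) > 0)
    disp <- mean(sqrt(rowSums((X_new - X)^2)))
    X <- X_new
    en_prev <- en
    hist[[it]] <- c(iteration = it, en, mean_disp = disp)
    if (disp < params$tol) {
      converged <- TRUE
      break
    }
  }
  history <- tibble::as_tibble(do.call(rbind, hist[seq_len(it)]))
  mesh <- mesh_init
  mesh$vertices <- X
  structure(list(mesh = mesh, mesh_init = mesh_init, params = params,
                 history = history, iterations = it, converged = converged,
                 n_clamped = n_clamped),
            class = "snake_fit")
}

#' @exportS3Method base::print
print.snake_fit <- function(x, ...) {
  cat(sprintf("<snake_fit> %d iterations (%s), total energy %.5g, %d clamped vertices\n",
              x$iterations, if (x$converged) "converged" else "max_iters",
              x$history$total[nrow(x$history)], x$n_clamped))
  invisible(x)
}

#' Count vertices that leaked past the basal plane
#'
#' A vertex counts as leaked when it lies beyond the basal plane — on the
#' atrial side — by more than one slice spacing. Used to quantify LV-to-LA
#' boundary leak of an evolved surface.
#'
#' @param mesh A `tube_mesh` (typically `snake_fit$mesh`).
#' @param basal_plane_z Basal plane position (mm).
#' @param slice_spacing Slice spacing (mm); the tolerance band.
#' @param direction `+1` if the atrium lies at larger z than the base
#'   (default), `-1` otherwise.
#' @return Integer count of leaked vertices.
#' @export
leak_count <- function(mesh, basal_plane_z, slice_spacing = 1, direction = 1) {
  z <- mesh$vertices[, 3]
  if (direction >= 0) {
    sum(z > basal_plane_z + slice_spacing)
  } else {
    sum(z < basal_plane_z - slice_spacing)
  }
}
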