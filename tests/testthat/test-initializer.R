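test_that("slice centers equal the exhaustive foreground centroid", {
  set.seed(21)
  m <- matrix(0L, 40, 40)
  m[10, 20] <- 1L
  st <- structure(list(images = list(m * 1.0, m * 1.0, m * 1.0),
                       masks = list(m, m, m), z_index = 0:2,
                       spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       provenance = "t"), class = "slice_stack")
  cen <- estimate_centers(st)
  expect_equal(cen$cx, rep(10, 3))
  expect_equal(cen$cy, rep(20, 3))
  # random blob: oracle = mean over an explicit pixel enumeration
  blob <- matrix(rbinom(1600, 1, 0.2), 40, 40)
  st$masks <- list(blob, blob, blob)
  cen2 <- estimate_centers(st)
  fg <- which(blob == 1, arr.ind = TRUE)
  expect_equal(cen2$cx[1], mean(fg[, 1]))
  expect_equal(cen2$cy[1], mean(fg[, 2]))
})

test_that("empty slices are flagged and sparse stacks rejected", {
  m0 <- matrix(0L, 16, 16)
  m1 <- m0; m1[5:8, 5:8] <- 1L
  st <- structure(list(images = rep(list(m0 * 1.0), 4),
                       masks = list(m1, m0, m1, m1), z_index = 0:3,
                       spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       provenance = "t"), class = "slice_stack")
  cen <- estimate_centers(st)
  expect_true(is.na(cen$cx[2]))
  expect_equal(cen$n_fg[2], 0L)
  st$masks <- list(m1, m0, m0, m0)
  expect_error(estimate_centers(st), "fewer than 3")
})

test_that("quadratic center correction is exact on nested models", {
  # collinear centers: a line is an exact quadratic fit
  cen <- tibble::tibble(z = 0:6, cx = 2 + 0.5 * (0:6), cy = 10 - 0.25 * (0:6),
                        n_fg = 50L)
  fit <- fit_center_curve(cen)
  expect_equal(fit$cx_fit, cen$cx, tolerance = 1e-10)
  expect_equal(fit$cy_fit, cen$cy, tolerance = 1e-10)
  # exactly 3 centers: quadratic interpolates them exactly
  cen3 <- tibble::tibble(z = c(0, 3, 7), cx = c(1, 5, 2), cy = c(0, 1, 4),
                         n_fg = 10L)
  fit3 <- fit_center_curve(cen3)
  expect_equal(fit3$cx_fit, cen3$cx, tolerance = 1e-9)
  expect_error(fit_center_curve(cen3[c(1, 1, 1), ]), "distinct")
})

test_that("the outlier fit equals the closed-form normal-equations solution", {
  z <- 0:20
  cx <- 0.02 * z^2 + 30
  cx[11] <- cx[11] + 10  # one 10-px outlier
  cen <- tibble::tibble(z = z, cx = cx, cy = 30 + 0 * z, n_fg = 100L)
  fit <- fit_center_curve(cen)
  X <- cbind(1, z, z^2)
  beta <- solve(t(X) %*% X, t(X) %*% cx)
  expect_equal(attr(fit, "coef")[, 1], as.numeric(beta), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$cx_fit, as.numeric(X %*% beta), tolerance = 1e-8)
  # interpolation across a flagged empty interior slice
  cen$cx[5] <- NA; cen$n_fg[5] <- 0L
  fit2 <- fit_center_curve(cen)
  expect_false(is.na(fit2$cx_fit[5]))
})

test_that("8-ray radius estimation recovers discs and matches a marching oracle", {
  m <- matrix(0L, 64, 64)
  ctr <- c(32, 32)
  for (i in 1:64) for (j in 1:64) {
    if ((i - ctr[1])^2 + (j - ctr[2])^2 <= 10^2) m[i, j] <- 1L
  }
  ring <- estimate_ring(m, ctr)
  expect_equal(ring$n_valid, 8)
  # half-voxel discretization bound: a lattice disc of radius 10 has its
  # foreground/background transition at 10.5
  expect_lte(abs(ring$R - 10), 0.5)
  expect_lte(max(abs(ring$ray_radii - 10)), 0.6)
  expect_equal(nrow(ring$points), 36)

  # axis-aligned ellipse, semi-axes 8 and 12: per-ray dense marching oracle
  e <- matrix(0L, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    if (((i - 32) / 8)^2 + ((j - 32) / 12)^2 <= 1) e[i, j] <- 1L
  }
  ring_e <- estimate_ring(e, c(32, 32))
  oracle <- sapply((0:7) * pi / 4, function(th) {
    ts <- seq(0, 30, by = 0.01)
    hit <- ((ts * cos(th)) / 8)^2 + ((ts * sin(th)) / 12)^2 <= 1
    # outermost lattice-rounded crossing, matching the implementation contract
    xs <- 32 + ts * cos(th); ys <- 32 + ts * sin(th)
    inb <- e[cbind(pmin(pmax(round(xs), 1), 64), pmin(pmax(round(ys), 1), 64))] == 1
    max(ts[inb])
  })
  expect_equal(ring_e$R, mean(oracle), tolerance = 0.3)

  expect_error(estimate_ring(matrix(0L, 8, 8), c(4, 4)), "empty")
  expect_error(estimate_ring(m, c(200, 4)), "outside")
})

test_that("spurious islands do not corrupt the ray radii", {
  m <- matrix(0L, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    if ((i - 32)^2 + (j - 32)^2 <= 8^2) m[i, j] <- 1L
  }
  m[50:54, 50:54] <- 1L  # off-target blob on the 45-degree ray
  ring <- estimate_ring(m, c(32, 32))
  expect_lt(abs(ring$R - 8), 0.6)
})

test_that("contour resampling keeps positions 0, k, 2k, ... plus the basal ring", {
  rings <- as.list(1:41)
  out <- resample_contours(rings, 10)
  expect_equal(attr(out, "positions"), c(0L, 10L, 20L, 30L, 40L))
  expect_identical(resample_contours(rings, 1)[1:41], rings)
  out5 <- resample_contours(as.list(1:5), 10)
  expect_equal(attr(out5, "positions"), c(0L, 4L))
  expect_error(resample_contours(rings, 0), "k")
})

test_that("initialization recovers the analytic half-ellipsoid within a voxel", {
  ph <- noiseless_phantom()
  spec <- ph$spec
  st <- slice_volume(ph$volume, ph$mask)
  init <- initialize_lv_mesh(st, k = 10)
  expect_equal(init$apex_direction, "low_z")
  # centers on the analytic axis (pixel coordinates of the axis: center/spacing + 1)
  axis_px <- spec$center_xy / spec$spacing[1:2] + 1
  expect_lt(max(abs(init$rings$cx - axis_px[1])), 1)
  expect_lt(max(abs(init$rings$cy - axis_px[2])), 1)
  # radii match the analytic cross-sections
  r_true <- spec$cavity_semi_axes[1] *
    sqrt(pmax(0, 1 - ((init$rings$z - spec$basal_z) / spec$cavity_semi_axes[3])^2))
  expect_lt(max(abs(init$rings$R - r_true)), 1)
  expect_equal(init$basal_z_mm, spec$basal_z)
  cons <- check_mesh_consistency(init$mesh)
  expect_true(cons$ok)
  expect_equal(euler_characteristic(init$mesh), 1)
})

test_that("center correction beats raw centroids on degraded masks", {
  ph <- default_phantom()
  dm <- degrade_mask(ph$mask, seed = 4)
  st <- slice_volume(ph$volume, dm)
  cen <- fit_center_curve(estimate_centers(st), weights = NULL)
  axis_px <- ph$spec$center_xy / ph$spec$spacing[1:2] + 1
  ok <- cen$n_fg > 0
  rms <- function(x, y) sqrt(mean((x - axis_px[1])^2 + (y - axis_px[2])^2))
  expect_lt(rms(cen$cx_fit[ok], cen$cy_fit[ok]), rms(cen$cx[ok], cen$cy[ok]))
})

test_that("mismatched ring point counts are rejected when meshing", {
  r1 <- estimate_ring(matrix(rep(c(0L, 1L), c(100, 156)), 16, 16), c(8, 8),
                      n_points = 12)
  r2 <- estimate_ring(matrix(rep(c(0L, 1L), c(100, 156)), 16, 16), c(8, 8),
                      n_points = 16)
  r1$z <- 0; r2$z <- 5
  expect_error(rings_to_mesh(list(r1, r2), c(1, 1, 1), c(8, 8), -1),
               "mismatched")
})

test_that("ring tables serialize to YAML", {
  td <- withr::local_tempdir()
  ph <- noiseless_phantom()
  init <- initialize_lv_mesh(slice_volume(ph$volume, ph$mask), k = 10)
  write_ring_table(init, file.path(td, "rings.yaml"))
  y <- yaml::read_yaml(file.path(td, "rings.yaml"))
  expect_equal(length(y$rings), nrow(init$rings))
  expect_equal(y$rings[[1]]$R, init$rings$R[1])
})
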