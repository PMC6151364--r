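test_that("surface distances vanish on identical surfaces and match brute force", {
  set.seed(41)
  P <- matrix(rnorm(300), 100, 3)
  expect_equal(mean_surface_distance(P, P), 0, tolerance = 1e-6)
  expect_equal(hausdorff_distance(P, P), 0, tolerance = 1e-6)
  Q <- matrix(rnorm(300), 100, 3)
  dm_oracle <- brute_directed(P, Q, mean) + brute_directed(Q, P, mean)
  dh_oracle <- max(brute_directed(P, Q, max), brute_directed(Q, P, max))
  expect_equal(mean_surface_distance(P, Q), dm_oracle, tolerance = 1e-12)
  expect_equal(hausdorff_distance(P, Q), dh_oracle, tolerance = 1e-12)
  expect_equal(mean_surface_distance(P, Q, averaged = TRUE), dm_oracle / 2)
})

test_that("concentric spheres give the analytic directed gap and d_m = sum", {
  A <- sphere_points(8000, 10)
  B <- sphere_points(8000, 12)
  dab <- mean(echosnake:::nn_distances(A, B))
  dba <- mean(echosnake:::nn_distances(B, A))
  expect_lt(abs(dab - 2) / 2, 0.01)
  expect_lt(abs(dba - 2) / 2, 0.01)
  expect_lt(abs(mean_surface_distance(A, B) - 4) / 4, 0.01)
})

test_that("a single 5 mm outlier sets the Hausdorff distance", {
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 0.5, 0), c(0, 0.5, 0.5))
  B <- rbind(A, c(6, 0, 0))  # extra point exactly 5 from its nearest neighbor
  expect_equal(hausdorff_distance(B, A), 5)
  expect_equal(hausdorff_distance(A, B), 5)
})

test_that("surface distances are symmetric and rigid-motion invariant", {
  set.seed(43)
  P <- matrix(rnorm(240), 80, 3)
  Q <- matrix(rnorm(240), 80, 3)
  expect_equal(mean_surface_distance(P, Q), mean_surface_distance(Q, P))
  expect_equal(hausdorff_distance(P, Q), hausdorff_distance(Q, P))
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  t0 <- c(3, -2, 7)
  Pr <- sweep(P %*% t(Rz), 2, t0, "+")
  Qr <- sweep(Q %*% t(Rz), 2, t0, "+")
  expect_equal(mean_surface_distance(Pr, Qr), mean_surface_distance(P, Q),
               tolerance = 1e-10)
  expect_equal(hausdorff_distance(Pr, Qr), hausdorff_distance(P, Q),
               tolerance = 1e-10)
  # d_h >= d_m / 2 (each directed mean is bounded by the max)
  expect_gte(hausdorff_distance(P, Q), mean_surface_distance(P, Q) / 2)
})

test_that("modified Dice follows voxel arithmetic and its boundary cases", {
  base <- array(0L, c(10, 10, 10))
  a <- base; a[1:5, 1:5, 1:4] <- 1L        # 100 voxels
  b <- base; b[1:5, 1:5, 3:6] <- 1L        # 100 voxels, 50 shared
  ma <- label_mask(a); mb <- label_mask(b)
  expect_equal(modified_dice(ma, ma), 0)
  dis <- base; dis[8:10, 8:10, 8:10] <- 1L
  expect_equal(modified_dice(ma, label_mask(dis)), 1)
  expect_equal(modified_dice(ma, mb), 1 - 2 * 50 / 200)
  expect_error(modified_dice(label_mask(base), label_mask(base)), "empty")
  # D* = 0 implies identical voxel sets
  expect_true(all(ma$data == ma$data))
})

test_that("ejection fraction reproduces the printed worked example", {
  expect_equal(ejection_fraction(100, 60), 0.4)
  expect_equal(round(ejection_fraction(105, 65), 3), 0.381)
  expect_equal(round(ejection_fraction(103, 57), 4), 0.4466)
  expect_error(ejection_fraction(0, 10), "EDV")
})

test_that("Bland-Altman bias, spread and limits follow the definitions", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$sd, 0)
  ba <- bland_altman(c(11, 9), c(10, 10))  # differences +1, -1
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(2))
  expect_equal(ba$upper - ba$bias, ba$bias - ba$lower)  # symmetric limits
  expect_error(bland_altman(1, 1), "2 pairs")
  expect_equal(glance(ba)$sd, sqrt(2))
})

test_that("pixel metrics reproduce the confusion-matrix arithmetic oracle", {
  n <- matrix(c(3, 1, 1, 5), 2, byrow = TRUE)
  pm <- pixel_metrics(n)
  expect_equal(pm$acc, 0.8)
  expect_equal(pm$mean_acc, (3 / 4 + 5 / 6) / 2)
  expect_equal(pm$mean_iou, 0.5 * (3 / 5 + 5 / 7))
  perfect <- pixel_metrics(matrix(c(7, 0, 0, 3), 2, byrow = TRUE))
  expect_equal(unlist(perfect), c(acc = 1, mean_acc = 1, mean_iou = 1))
  # consistent label swap leaves all three unchanged
  swapped <- pixel_metrics(n[2:1, 2:1])
  expect_equal(swapped, pm)
  expect_warning(pixel_metrics(matrix(c(0, 0, 2, 8), 2, byrow = TRUE)),
                 "absent")
  expect_error(pixel_metrics(matrix(0, 2, 2)), "all-zero")
})

test_that("confusion counts aggregate slices and feed pixel metrics", {
  p <- list(matrix(c(1, 0, 0, 0), 2), matrix(c(1, 1, 0, 0), 2))
  t <- list(matrix(c(1, 0, 0, 1), 2), matrix(c(1, 1, 0, 0), 2))
  n <- confusion_counts(p, t)
  expect_equal(sum(n), 8)
  expect_equal(n[2, 2], 3)  # true fg predicted fg
  expect_equal(n[2, 1], 1)  # the missed fg pixel
  pm <- pixel_metrics(n)
  expect_equal(pm$acc, 7 / 8)
})

test_that("evaluation reports serialize to JSON and CSV", {
  td <- withr::local_tempdir()
  ph <- noiseless_phantom()
  rep <- evaluate_segmentation(ph$mesh, ph$mesh, ph$mask, ph$mask,
                               n_samples = 6000)
  # the two surfaces are resampled independently, so distances are small
  # but not exactly zero; the voxel-overlap D* is exact
  expect_lt(rep$d_m, 1)
  expect_lt(rep$d_h, 3)
  expect_equal(rep$dstar, 0)
  expect_equal(rep$volume_ml, rep$volume_t_ml)
  write_metrics_report(rep, file.path(td, "m.json"), file.path(td, "m.csv"))
  j <- jsonlite::read_json(file.path(td, "m.json"))
  expect_equal(j$d_h, rep$d_h, tolerance = 1e-9)
  expect_equal(nrow(utils::read.csv(file.path(td, "m.csv"))), 1)
})
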