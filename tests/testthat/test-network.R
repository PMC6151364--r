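test_that("forward pass maps 3-channel input to normalized 2-class maps", {
  cfg <- net_config(base_width = 4, depth = 2)
  model <- build_network(cfg, seed = 3)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  fw <- echosnake:::fcn_forward(model, x, train = TRUE)
  expect_equal(dim(fw$scores), c(16, 16, 2, 2))
  pr <- echosnake:::softmax2(fw$scores)
  expect_lt(max(abs(pr[, , 1, ] + pr[, , 2, ] - 1)), 1e-12)
  # non-divisible input is padded and cropped back
  x2 <- array(rnorm(15 * 13 * 3 * 1), c(15, 13, 3, 1))
  fw2 <- echosnake:::fcn_forward(model, x2, train = TRUE)
  expect_equal(dim(fw2$scores), c(15, 13, 2, 1))
})

test_that("analytic backprop matches finite differences of the loss", {
  set.seed(42)
  cfg <- net_config(base_width = 4, depth = 2)
  model <- build_network(cfg, seed = 7)
  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  masks <- list(matrix(rbinom(256, 1, 0.3), 16, 16),
                matrix(rbinom(256, 1, 0.3), 16, 16))
  fw <- echosnake:::fcn_forward(model, x, train = TRUE)
  lg <- echosnake:::batch_loss_grad(fw$scores, masks, 1:2)
  grads <- echosnake:::fcn_backward(model, fw$cache, lg$dscores)
  loss_at <- function(m) {
    f <- echosnake:::fcn_forward(m, x, train = TRUE)
    echosnake:::batch_loss_grad(f$scores, masks, 1:2)$loss
  }
  h <- 1e-5
  for (nm in c("enc1.conv1.W", "str2.res3.conv.W", "str2.res2.bn.gamma",
               "str1.up1.W", "str2.up2.b")) {
    i <- sample(length(model$params[[nm]]), 1)
    mp <- model; mp$params[[nm]][i] <- mp$params[[nm]][i] + h
    mm <- model; mm$params[[nm]][i] <- mm$params[[nm]][i] - h
    fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
    expect_equal(grads[[nm]][i], fd, tolerance = 1e-4)
  }
})

test_that("disabling a skip stream changes the parameter count by exactly that stream", {
  full <- build_network(net_config(base_width = 4, depth = 3,
                                   skip_streams = 1:3), seed = 1)
  reduced <- build_network(net_config(base_width = 4, depth = 3,
                                      skip_streams = 2:3), seed = 1)
  # independent bookkeeping: stream 1 = 1x1 score conv (c1 -> 2) +
  # 4 x [3x3 conv (2 -> 2) + BN(2)] + 1 transposed conv 4x4 (2 -> 2)
  c1 <- 4
  expected <- (1 * 1 * c1 * 2 + 2) + 4 * ((3 * 3 * 2 * 2 + 2) + 4) +
    (4 * 4 * 2 * 2 + 2)
  expect_equal(n_parameters(full) - n_parameters(reduced), expected)
  expect_equal(n_parameters(full, "^str1\\."), expected)
})

test_that("a zero-weight residual module is the identity path", {
  cfg <- net_config(base_width = 4, depth = 2, residual_per_stream = TRUE)
  m1 <- build_network(cfg, seed = 5)
  for (nm in grep("\\.res\\d\\.conv\\.(W|b)$", names(m1$params), value = TRUE)) {
    m1$params[[nm]][] <- 0
  }
  m0 <- build_network(net_config(base_width = 4, depth = 2,
                                 residual_per_stream = FALSE), seed = 5)
  # share every parameter the two topologies have in common
  for (nm in names(m0$params)) m0$params[[nm]] <- m1$params[[nm]]
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3, 1))
  s1 <- echosnake:::fcn_forward(m1, x, train = TRUE)$scores
  s0 <- echosnake:::fcn_forward(m0, x, train = TRUE)$scores
  expect_equal(s1, s0, tolerance = 1e-12)
})

test_that("stage-1 training freezes the backbone bit-exactly", {
  ph <- noiseless_phantom()
  st <- slice_volume(ph$volume, ph$mask)
  st$images <- st$images[14:21]; st$masks <- st$masks[14:21]
  st$z_index <- st$z_index[14:21]
  model <- build_network(net_config(base_width = 4, depth = 2), seed = 2)
  tc <- train_config(lr0 = 1e-4, momentum = 0.9, batch_size = 2,
                     max_iter = 6, stage1_iter = 4, seed = 3)
  fit <- train_network(model, st, tc)
  bb <- backbone_parameters(model)
  expect_identical(fit$stage1_model$params[bb], model$params[bb])
  # and stage 2 does update the backbone
  expect_false(identical(fit$model$params[bb], model$params[bb]))
  # head parameters moved during stage 1
  head <- setdiff(names(model$params), bb)
  expect_false(identical(fit$stage1_model$params[head], model$params[head]))
})

test_that("training is deterministic under a fixed seed", {
  ph <- noiseless_phantom()
  st <- slice_volume(ph$volume, ph$mask)
  st$images <- st$images[16:19]; st$masks <- st$masks[16:19]
  st$z_index <- st$z_index[16:19]
  model <- build_network(net_config(base_width = 4, depth = 2), seed = 2)
  tc <- train_config(lr0 = 1e-4, momentum = 0.9, batch_size = 2,
                     max_iter = 5, stage1_iter = 2, seed = 9)
  f1 <- train_network(model, st, tc)
  f2 <- train_network(model, st, tc)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("prediction preserves slice order and inverts to a 3D mask", {
  ph <- noiseless_phantom()
  st <- slice_volume(ph$volume, ph$mask)
  model <- build_network(net_config(base_width = 4, depth = 2), seed = 2)
  pred <- predict_stack(model, st)
  expect_identical(pred$z_index, st$z_index)
  m3 <- restack_slices(pred, "mask")
  expect_s3_class(m3, "lv_mask")
  expect_equal(dim(m3), dim(ph$mask))
  # constant-input slice yields a single uniform class map
  cst <- st
  cst$images <- list(matrix(0.5, 96, 96))
  cst$masks <- NULL
  cst$z_index <- 0L
  pc <- predict_stack(model, cst)
  # a strided encoder/decoder is shift invariant modulo its pooling stride
  # (2^depth): away from borders, the class map is periodic with period 4
  blk <- pc$masks[[1]][41:56, 41:56]
  expect_identical(blk[1:4, 1:4], blk[5:8, 5:8])
  expect_identical(blk[1:4, 1:4], blk[9:12, 1:4])
})

test_that("training aborts with a diagnostic when the loss diverges", {
  ph <- noiseless_phantom()
  st <- slice_volume(ph$volume, ph$mask)
  st$images <- st$images[16:19]; st$masks <- st$masks[16:19]
  st$z_index <- st$z_index[16:19]
  model <- build_network(net_config(base_width = 4, depth = 2), seed = 2)
  tc <- train_config(lr0 = 50, momentum = 0.99, batch_size = 4,
                     max_iter = 50, stage1_iter = 10, seed = 1)
  expect_error(train_network(model, st, tc), "diverged")
})

test_that("pretrained tensors load by name and shape", {
  model <- build_network(net_config(base_width = 4, depth = 2), seed = 1)
  w <- model$params[["enc1.conv1.W"]]
  w[] <- 1.5
  m2 <- load_pretrained_weights(model, list(`enc1.conv1.W` = w,
                                            bogus = matrix(0, 2, 2)))
  expect_identical(attr(m2, "loaded"), "enc1.conv1.W")
  expect_true(all(m2$params[["enc1.conv1.W"]] == 1.5))
  expect_identical(m2$params[["enc2.conv1.W"]], model$params[["enc2.conv1.W"]])
})
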