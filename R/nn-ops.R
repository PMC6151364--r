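# Minimal CNN primitives on H x W x C x B arrays (column-major, batch last).
# Convolutions go through im2col + one BLAS matmul per layer call; every
# forward returns the cache its backward needs. Sized for desk-scale training
# of the fusion FCN, not for general deep learning.

pad_hw <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  xp[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  xp
}

# im2col: rows ordered (H', W', B), cols ordered (offset di major?, see loop)
im2col <- function(x, k, stride, pad) {
  d <- dim(x)
  xp <- pad_hw(x, pad)
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1L
  Ci <- d[3]; B <- d[4]
  ri <- seq(1L, by = stride, length.out = Ho)
  ci <- seq(1L, by = stride, length.out = Wo)
  X2 <- matrix(0, Ho * Wo * B, k * k * Ci)
  o <- 0L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      blk <- xp[di + ri, dj + ci, , , drop = FALSE]      # Ho x Wo x Ci x B
      blk <- aperm(blk, c(1, 2, 4, 3))                   # rows (Ho,Wo,B), cols Ci
      X2[, o * Ci + seq_len(Ci)] <- matrix(blk, Ho * Wo * B, Ci)
      o <- o + 1L
    }
  }
  list(X2 = X2, Ho = Ho, Wo = Wo, B = B, Ci = Ci, k = k,
       stride = stride, pad = pad, Hi = d[1], Wi = d[2])
}

col2im <- function(dX2, info) {
  k <- info$k; Ci <- info$Ci; p <- info$pad
  Hp <- info$Hi + 2 * p; Wp <- info$Wi + 2 * p
  dxp <- array(0, c(Hp, Wp, Ci, info$B))
  ri <- seq(1L, by = info$stride, length.out = info$Ho)
  ci <- seq(1L, by = info$stride, length.out = info$Wo)
  o <- 0L
  for (dj in 0:(k - 1)) {
    for (di in 0:(k - 1)) {
      blk <- array(dX2[, o * Ci + seq_len(Ci)], c(info$Ho, info$Wo, info$B, Ci))
      blk <- aperm(blk, c(1, 2, 4, 3))
      dxp[di + ri, dj + ci, , ] <- dxp[di + ri, dj + ci, , , drop = FALSE] + blk
      o <- o + 1L
    }
  }
  if (p == 0) dxp else dxp[p + seq_len(info$Hi), p + seq_len(info$Wi), , , drop = FALSE]
}

# weight matrix Wm: (k*k*Ci) x Co, rows ordered like im2col columns
conv_fwd <- function(x, Wm, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  ic <- im2col(x, k, stride, pad)
  out2 <- ic$X2 %*% Wm
  out2 <- sweep(out2, 2, b, "+")
  Co <- ncol(Wm)
  out <- aperm(array(out2, c(ic$Ho, ic$Wo, ic$B, Co)), c(1, 2, 4, 3))
  list(out = out, cache = list(ic = ic, Wm = Wm, Co = Co))
}

conv_bwd <- function(cache, dout) {
  ic <- cache$ic
  d2 <- matrix(aperm(dout, c(1, 2, 4, 3)), ic$Ho * ic$Wo * ic$B, cache$Co)
  dW <- crossprod(ic$X2, d2)
  db <- colSums(d2)
  dx <- col2im(d2 %*% t(cache$Wm), ic)
  list(dx = dx, dW = dW, db = db)
}

# Transposed convolution (learnable 2x upsampling): kernel 4, stride 2, pad 1.
# Forward is the backward-data pass of the corresponding strided convolution;
# gradients follow from the bilinear form <g, W' * x>.
deconv_fwd <- function(x, Wm, b) {
  d <- dim(x)
  Ho <- 2L * d[1]; Wo <- 2L * d[2]
  Ci <- nrow(Wm) %/% 16L  # k = 4
  info <- list(k = 4L, stride = 2L, pad = 1L, Hi = Ho, Wi = Wo,
               Ho = d[1], Wo = d[2], B = d[4], Ci = Ci)
  x2 <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  out <- col2im(x2 %*% t(Wm), info)
  out <- sweep(out, 3, b, "+")
  list(out = out, cache = list(Wm = Wm, x2 = x2, dx_dims = d))
}

deconv_bwd <- function(cache, dout) {
  Wm <- cache$Wm
  r <- conv_fwd(dout, Wm, b = numeric(ncol(Wm)), k = 4L, stride = 2L, pad = 1L)
  dW <- crossprod(r$cache$ic$X2, cache$x2)
  db <- as.numeric(apply(dout, 3, sum))
  list(dx = r$out, dW = dW, db = db)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_bwd <- function(cache, dout) dout * cache

maxpool_fwd <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  a <- x
  dim(a) <- c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4])
  s11 <- a[1, , 1, , , , drop = FALSE]; s21 <- a[2, , 1, , , , drop = FALSE]
  s12 <- a[1, , 2, , , , drop = FALSE]; s22 <- a[2, , 2, , , , drop = FALSE]
  dd <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4])
  s11 <- array(s11, dd); s21 <- array(s21, dd)
  s12 <- array(s12, dd); s22 <- array(s22, dd)
  out <- pmax(s11, s21, s12, s22)
  # ties resolved in fixed order (1, 2, 3, 4) for determinism
  wm <- array(0L, dd)
  wm[s11 == out] <- 1L
  wm[wm == 0L & s21 == out] <- 2L
  wm[wm == 0L & s12 == out] <- 3L
  wm[wm == 0L & s22 == out] <- 4L
  list(out = out, cache = list(wm = wm, d = d))
}

maxpool_bwd <- function(cache, dout) {
  d <- cache$d
  dd <- dim(dout)
  da <- array(0, c(2L, dd[1], 2L, dd[2], dd[3], dd[4]))
  wm <- cache$wm
  da[1, , 1, , , ][wm == 1L] <- dout[wm == 1L]
  da[2, , 1, , , ][wm == 2L] <- dout[wm == 2L]
  da[1, , 2, , , ][wm == 3L] <- dout[wm == 3L]
  da[2, , 2, , , ][wm == 4L] <- dout[wm == 4L]
  dim(da) <- d
  da
}

# Batch normalization over (H, W, B) per channel.
bn_fwd <- function(x, gamma, beta, state, train = TRUE, momentum = 0.1,
                   eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), n, d[3])
  if (train) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu, "-")^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, inv, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  out <- aperm(array(out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(out = out, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = gamma, d = d, n = n,
                    mu = mu, va = va))
}

bn_bwd <- function(cache, dout) {
  d <- cache$d; n <- cache$n
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), n, d[3])
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, cache$gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dxm <- sweep(t1 - t2, 2, cache$inv, "*")
  dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax2 <- function(scores) {
  # scores H x W x 2 x B -> probabilities, stable
  m <- pmax(scores[, , 1, , drop = FALSE], scores[, , 2, , drop = FALSE])
  e1 <- exp(scores[, , 1, , drop = FALSE] - m)
  e2 <- exp(scores[, , 2, , drop = FALSE] - m)
  s <- e1 + e2
  out <- scores
  out[, , 1, ] <- e1 / s
  out[, , 2, ] <- e2 / s
  out
}
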