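#' Configuration of the fusion FCN
#'
#' Describes the feature-fusion fully-convolutional segmenter: a VGG-style
#' convolutional encoder of `depth` pooling stages, plus one skip stream per
#' enabled pooling stage. Each stream reduces its feature map to the two class
#' channels with a 1x1 score convolution, passes it through a residual module
#' (4 convolutional layers of 2 kernels each, 3x3, each followed by batch
#' normalization and ReLU, with an identity shortcut), and upsamples back to
#' full resolution with learnable 2-channel transposed convolutions; the
#' streams are summed (fused) into the final two-class score map. The two
#' deepest streams are always enabled — they form the baseline fusion — and
#' shallower streams can be added to inject low-level features.
#'
#' @param base_width Channels of the first encoder block; stage `s` uses
#'   `base_width * 2^(s-1)` channels.
#' @param depth Number of pooling stages (input is zero-padded to a multiple of
#'   `2^depth` and the output cropped back).
#' @param skip_streams Integer vector of pooling stages routed to the output;
#'   must include the two deepest stages.
#' @param residual_per_stream Include the residual module on each stream?
#' @param n_classes Fixed at 2 (LV, background).
#' @param input_channels Fixed at 3 (gray slice replicated, see
#'   [to_three_channel()]).
#' @return An object of class `net_config`.
#' @export
net_config <- function(base_width = 8, depth = 4,
                       skip_streams = seq_len(depth),
                       residual_per_stream = TRUE,
                       n_classes = 2, input_channels = 3) {
  stopifnot(base_width >= 1, depth >= 2, n_classes == 2, input_channels == 3)
  skip_streams <- sort(unique(as.integer(skip_streams)))
  if (length(skip_streams) == 0 || any(skip_streams < 1 | skip_streams > depth)) {
    stop("skip_streams must be a non-empty subset of 1..depth", call. = FALSE)
  }
  if (!all(c(depth - 1L, depth) %in% skip_streams)) {
    stop("the two deepest pooling stages must always be routed to the output",
         call. = FALSE)
  }
  structure(list(base_width = as.integer(base_width), depth = as.integer(depth),
                 skip_streams = skip_streams,
                 residual_per_stream = isTRUE(residual_per_stream),
                 n_classes = 2L, input_channels = 3L),
            class = "net_config")
}

#' Training schedule for the fusion FCN
#'
#' Defaults follow the reference schedule for the full-scale network: initial
#' learning rate `1e-4` decreased linearly in steps every `decay_every`
#' iterations (`lr(t) = lr0 * (1 - t_dec / max_iter)` with `t_dec` the last
#' decay boundary at or before `t`), momentum 0.99, batch size 256, 10000
#' iterations with the encoder frozen for the first 1000 (stage 1: only the
#' transposed-convolution layers and the residual stream modules learn;
#' stage 2: the whole network is fine-tuned). Toy runs pass smaller values.
#'
#' @param lr0 Initial learning rate.
#' @param decay_every Iterations between learning-rate decrements.
#' @param momentum SGD momentum coefficient.
#' @param batch_size Slices per iteration.
#' @param max_iter Total iterations.
#' @param stage1_iter Iterations with the encoder (backbone) frozen;
#'   `0 < stage1_iter < max_iter`.
#' @param max_grad_norm Clip the global gradient L2 norm at this value
#'   (`Inf` disables); guards small-batch runs against loss spikes.
#' @param seed Integer seed fixing initialization and batch order.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-4, decay_every = 1000, momentum = 0.99,
                         batch_size = 256, max_iter = 10000,
                         stage1_iter = 1000, max_grad_norm = Inf, seed = 1L) {
  stopifnot(lr0 > 0, decay_every >= 1, momentum >= 0, momentum < 1,
            batch_size >= 1, max_iter >= 1, max_grad_norm > 0)
  if (!(stage1_iter > 0 && stage1_iter < max_iter)) {
    stop("need 0 < stage1_iter < max_iter", call. = FALSE)
  }
  structure(list(lr0 = lr0, decay_every = as.integer(decay_every),
                 momentum = momentum, batch_size = as.integer(batch_size),
                 max_iter = as.integer(max_iter),
                 stage1_iter = as.integer(stage1_iter),
                 max_grad_norm = max_grad_norm, seed = as.integer(seed)),
            class = "train_config")
}

stage_channels <- function(cfg) cfg$base_width * 2L^(seq_len(cfg$depth) - 1L)

he_init <- function(k, ci, co) {
  matrix(stats::rnorm(k * k * ci * co, sd = sqrt(2 / (k * k * ci))), k * k * ci, co)
}

#' Build a fusion FCN with randomly initialized weights
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `fusion_fcn` holding a flat named parameter list,
#'   batch-norm running statistics, and per-parameter backbone flags (the
#'   encoder is the backbone frozen during stage-1 training).
#' @examples
#' model <- build_network(net_config(base_width = 4, depth = 2))
#' n_parameters(model)
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  ch <- stage_channels(cfg)
  params <- list()
  backbone <- character()
  ci <- cfg$input_channels
  for (s in seq_len(cfg$depth)) {
    params[[sprintf("enc%d.conv1.W", s)]] <- he_init(3, ci, ch[s])
    params[[sprintf("enc%d.conv1.b", s)]] <- numeric(ch[s])
    params[[sprintf("enc%d.conv2.W", s)]] <- he_init(3, ch[s], ch[s])
    params[[sprintf("enc%d.conv2.b", s)]] <- numeric(ch[s])
    backbone <- c(backbone, sprintf("enc%d.conv%d.%s", s, rep(1:2, each = 2),
                                    c("W", "b")))
    ci <- ch[s]
  }
  state <- list()
  for (s in cfg$skip_streams) {
    params[[sprintf("str%d.score.W", s)]] <- he_init(1, ch[s], 2)
    params[[sprintf("str%d.score.b", s)]] <- numeric(2)
    if (cfg$residual_per_stream) {
      for (j in 1:4) {
        params[[sprintf("str%d.res%d.conv.W", s, j)]] <- he_init(3, 2, 2)
        params[[sprintf("str%d.res%d.conv.b", s, j)]] <- numeric(2)
        params[[sprintf("str%d.res%d.bn.gamma", s, j)]] <- rep(1, 2)
        params[[sprintf("str%d.res%d.bn.beta", s, j)]] <- numeric(2)
        state[[sprintf("str%d.res%d.bn", s, j)]] <- list(mean = numeric(2),
                                                         var = rep(1, 2))
      }
    }
    for (u in seq_len(s)) {
      params[[sprintf("str%d.up%d.W", s, u)]] <- he_init(4, 2, 2)
      params[[sprintf("str%d.up%d.b", s, u)]] <- numeric(2)
    }
  }
  structure(list(cfg = cfg, params = params, state = state,
                 backbone = backbone),
            class = "fusion_fcn")
}

#' @exportS3Method base::print
print.fusion_fcn <- function(x, ...) {
  cat(sprintf("<fusion_fcn> depth %d, base width %d, streams {%s}: %d parameters\n",
              x$cfg$depth, x$cfg$base_width,
              paste(x$cfg$skip_streams, collapse = ","), n_parameters(x)))
  invisible(x)
}

#' Total number of learnable parameters
#' @param model A `fusion_fcn`.
#' @param pattern Optional regular expression restricting to matching names.
#' @export
n_parameters <- function(model, pattern = NULL) {
  nm <- names(model$params)
  if (!is.null(pattern)) nm <- grep(pattern, nm, value = TRUE)
  sum(vapply(model$params[nm], length, 1L))
}

#' Names of backbone (encoder) parameters, frozen during stage-1 training
#' @param model A `fusion_fcn`.
#' @export
backbone_parameters <- function(model) model$backbone

#' Load externally supplied pretrained tensors by name
#'
#' Replaces any parameter whose name and shape match an entry of `tensors`;
#' everything else keeps its current value. This is the transfer-learning hook:
#' weights exported from an externally trained network can seed the encoder.
#'
#' @param model A `fusion_fcn`.
#' @param tensors Named list of numeric arrays.
#' @return The model, with an attribute `loaded` naming the replaced tensors.
#' @export
load_pretrained_weights <- function(model, tensors) {
  loaded <- character()
  for (nm in names(tensors)) {
    if (!is.null(model$params[[nm]]) &&
        length(model$params[[nm]]) == length(tensors[[nm]])) {
      v <- model$params[[nm]]
      v[] <- as.numeric(tensors[[nm]])
      model$params[[nm]] <- v
      loaded <- c(loaded, nm)
    }
  }
  attr(model, "loaded") <- loaded
  model
}

#' Save / load a model (native serialization)
#' @param model A `fusion_fcn`.
#' @param path `.rds` path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Export the flat name-to-tensor weight archive
#'
#' @param model A `fusion_fcn`.
#' @param path `.rds` path receiving the plain named list of arrays.
#' @export
export_weights <- function(model, path) {
  saveRDS(model$params, path)
  invisible(path)
}

pad_to_multiple <- function(x, m) {
  d <- dim(x)
  Hp <- as.integer(ceiling(d[1] / m) * m)
  Wp <- as.integer(ceiling(d[2] / m) * m)
  if (Hp == d[1] && Wp == d[2]) return(list(x = x, H = d[1], W = d[2]))
  xp <- array(0, c(Hp, Wp, d[3], d[4]))
  xp[seq_len(d[1]), seq_len(d[2]), , ] <- x
  list(x = xp, H = d[1], W = d[2])
}

# Forward pass: x is H x W x 3 x B. Returns scores H x W x 2 x B plus the
# cache needed by fcn_backward. BN uses batch statistics when train = TRUE.
fcn_forward <- function(model, x, train = TRUE) {
  cfg <- model$cfg
  p <- model$params
  pd <- pad_to_multiple(x, 2^cfg$depth)
  x <- pd$x
  cache <- list(pad = pd[c("H", "W")], enc = list(), str = list())
  P <- list()
  for (s in seq_len(cfg$depth)) {
    c1 <- conv_fwd(x, p[[sprintf("enc%d.conv1.W", s)]],
                   p[[sprintf("enc%d.conv1.b", s)]], k = 3)
    r1 <- relu_fwd(c1$out)
    c2 <- conv_fwd(r1$out, p[[sprintf("enc%d.conv2.W", s)]],
                   p[[sprintf("enc%d.conv2.b", s)]], k = 3)
    r2 <- relu_fwd(c2$out)
    pl <- maxpool_fwd(r2$out)
    cache$enc[[s]] <- list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                           r2 = r2$cache, pool = pl$cache)
    P[[s]] <- pl$out
    x <- pl$out
  }
  fused <- NULL
  for (s in cfg$skip_streams) {
    sc <- conv_fwd(P[[s]], p[[sprintf("str%d.score.W", s)]],
                   p[[sprintf("str%d.score.b", s)]], k = 1, pad = 0)
    y <- sc$out
    scache <- list(score = sc$cache, res = list(), up = list())
    if (cfg$residual_per_stream) {
      y_in <- y
      for (j in 1:4) {
        cv <- conv_fwd(y, p[[sprintf("str%d.res%d.conv.W", s, j)]],
                       p[[sprintf("str%d.res%d.conv.b", s, j)]], k = 3)
        key <- sprintf("str%d.res%d.bn", s, j)
        bn <- bn_fwd(cv$out, p[[paste0(key, ".gamma")]],
                     p[[paste0(key, ".beta")]], model$state[[key]],
                     train = train)
        model$state[[key]] <- bn$state
        rl <- relu_fwd(bn$out)
        scache$res[[j]] <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
        y <- rl$out
      }
      y <- y + y_in  # identity shortcut
    }
    for (u in seq_len(s)) {
      dc <- deconv_fwd(y, p[[sprintf("str%d.up%d.W", s, u)]],
                       p[[sprintf("str%d.up%d.b", s, u)]])
      scache$up[[u]] <- dc$cache
      y <- dc$out
    }
    cache$str[[as.character(s)]] <- scache
    fused <- if (is.null(fused)) y else fused + y
  }
  scores <- fused[seq_len(pd$H), seq_len(pd$W), , , drop = FALSE]
  cache$full_dim <- dim(fused)
  list(scores = scores, cache = cache, state = model$state)
}

# Backward pass: dscores has the (cropped) score shape; returns flat gradients.
fcn_backward <- function(model, cache, dscores) {
  cfg <- model$cfg
  p <- model$params
  grads <- lapply(model$params, function(v) { v[] <- 0; v })
  dfused <- array(0, cache$full_dim)
  dfused[seq_len(cache$pad$H), seq_len(cache$pad$W), , ] <- dscores
  dP <- vector("list", cfg$depth)
  for (s in cfg$skip_streams) {
    scache <- cache$str[[as.character(s)]]
    dy <- dfused
    for (u in rev(seq_len(s))) {
      r <- deconv_bwd(scache$up[[u]], dy)
      grads[[sprintf("str%d.up%d.W", s, u)]] <- r$dW
      grads[[sprintf("str%d.up%d.b", s, u)]] <- r$db
      dy <- r$dx
    }
    if (cfg$residual_per_stream) {
      dy_in <- dy  # shortcut branch
      for (j in 4:1) {
        dy <- relu_bwd(scache$res[[j]]$relu, dy)
        bb <- bn_bwd(scache$res[[j]]$bn, dy)
        grads[[sprintf("str%d.res%d.bn.gamma", s, j)]] <- bb$dgamma
        grads[[sprintf("str%d.res%d.bn.beta", s, j)]] <- bb$dbeta
        cb <- conv_bwd(scache$res[[j]]$conv, bb$dx)
        grads[[sprintf("str%d.res%d.conv.W", s, j)]] <- cb$dW
        grads[[sprintf("str%d.res%d.conv.b", s, j)]] <- cb$db
        dy <- cb$dx
      }
      dy <- dy + dy_in
    }
    sb <- conv_bwd(scache$score, dy)
    grads[[sprintf("str%d.score.W", s)]] <- sb$dW
    grads[[sprintf("str%d.score.b", s)]] <- sb$db
    dP[[s]] <- if (is.null(dP[[s]])) sb$dx else dP[[s]] + sb$dx
  }
  dnext <- NULL
  for (s in rev(seq_len(cfg$depth))) {
    dpool <- dP[[s]]
    if (!is.null(dnext)) {
      dpool <- if (is.null(dpool)) dnext else dpool + dnext
    }
    if (is.null(dpool)) dpool <- array(0, dim(cache$enc[[s]]$pool$wm))
    dx <- maxpool_bwd(cache$enc[[s]]$pool, dpool)
    dx <- relu_bwd(cache$enc[[s]]$r2, dx)
    cb2 <- conv_bwd(cache$enc[[s]]$c2, dx)
    grads[[sprintf("enc%d.conv2.W", s)]] <- cb2$dW
    grads[[sprintf("enc%d.conv2.b", s)]] <- cb2$db
    dx <- relu_bwd(cache$enc[[s]]$r1, cb2$dx)
    cb1 <- conv_bwd(cache$enc[[s]]$c1, dx)
    grads[[sprintf("enc%d.conv1.W", s)]] <- cb1$dW
    grads[[sprintf("enc%d.conv1.b", s)]] <- cb1$db
    dnext <- cb1$dx
  }
  grads
}

batch_tensor <- function(stack, idx) {
  d2 <- dim(stack$images[[1]])
  x <- array(0, c(d2[1], d2[2], 3, length(idx)))
  for (k in seq_along(idx)) x[, , , k] <- to_three_channel(stack$images[[idx[k]]])
  x
}

# Weighted-CE loss and score gradient for a batch; per-slice balance weight a.
batch_loss_grad <- function(scores, masks, idx, eps = 1e-12) {
  probs <- softmax2(scores)
  B <- length(idx)
  dscores <- array(0, dim(scores))
  total <- 0
  for (k in seq_len(B)) {
    truth <- masks[[idx[k]]]
    fg <- truth > 0
    yp <- sum(fg); ym <- sum(!fg)
    a <- ym / (yp + ym)
    w <- ifelse(fg, a, 1 - a)
    p1 <- probs[, , 2, k]
    p0 <- probs[, , 1, k]
    total <- total - a * sum(log(pmax(p1[fg], eps))) -
      (1 - a) * sum(log(pmax(p0[!fg], eps)))
    # softmax + weighted CE: d/dscore_c = w * (p_c - 1{c = y})
    dscores[, , 1, k] <- w * (p0 - (!fg)) / B
    dscores[, , 2, k] <- w * (p1 - fg) / B
  }
  list(loss = total / B, dscores = dscores)
}

step_lr <- function(t, tc) {
  t_dec <- tc$decay_every * ((t - 1) %/% tc$decay_every)
  tc$lr0 * (1 - t_dec / tc$max_iter)
}

# Replace BN running statistics by statistics aggregated over fresh training
# batches, closing the small-batch train/inference gap before prediction.
recalibrate_bn <- function(model, stack, batch_size, n_batches = 16,
                           seed = 1L) {
  if (length(model$state) == 0) return(model)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(stack$images)
  acc <- lapply(model$state, function(s) list(mean = 0 * s$mean, var = 0 * s$var))
  for (bidx in seq_len(n_batches)) {
    idx <- sample.int(n, min(batch_size, n), replace = batch_size > n)
    fw <- fcn_forward(model, batch_tensor(stack, idx), train = TRUE)
    for (s in model$cfg$skip_streams) {
      scache <- fw$cache$str[[as.character(s)]]
      for (j in seq_along(scache$res)) {
        key <- sprintf("str%d.res%d.bn", s, j)
        acc[[key]]$mean <- acc[[key]]$mean + scache$res[[j]]$bn$mu
        acc[[key]]$var <- acc[[key]]$var + scache$res[[j]]$bn$va
      }
    }
  }
  for (key in names(acc)) {
    model$state[[key]] <- list(mean = acc[[key]]$mean / n_batches,
                               var = acc[[key]]$var / n_batches)
  }
  model
}

#' Train the fusion FCN on a slice stack
#'
#' Two-stage SGD with momentum: during the first `stage1_iter` iterations the
#' encoder (backbone) parameters are frozen and only the skip-stream residual
#' modules, score and transposed-convolution layers are updated; afterwards
#' the whole network is fine-tuned. The learning rate decreases linearly in
#' steps of `decay_every` iterations. Training aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param model A `fusion_fcn` from [build_network()].
#' @param stack A `slice_stack` with masks.
#' @param tc A [train_config()].
#' @return An object of class `fcn_fit`: the trained `model`; `history`, a
#'   tibble with one row per iteration (`iteration`, `loss`, `lr`, `stage`);
#'   and `stage1_model`, the model state at the end of stage 1 (whose backbone
#'   must equal the initial backbone — the freeze contract).
#' @export
train_network <- function(model, stack, tc) {
  stopifnot(inherits(model, "fusion_fcn"), inherits(stack, "slice_stack"),
            inherits(tc, "train_config"))
  if (length(stack$images) == 0) stop("empty slice stack", call. = FALSE)
  if (is.null(stack$masks)) stop("training requires masks", call. = FALSE)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(tc$seed)
  n <- length(stack$images)
  vel <- lapply(model$params, function(v) { v[] <- 0; v })
  stage1_model <- NULL
  hist_loss <- numeric(tc$max_iter)
  hist_lr <- numeric(tc$max_iter)
  frozen <- names(model$params) %in% model$backbone
  for (t in seq_len(tc$max_iter)) {
    idx <- sample.int(n, min(tc$batch_size, n), replace = tc$batch_size > n)
    x <- batch_tensor(stack, idx)
    fw <- fcn_forward(model, x, train = TRUE)
    model$state <- fw$state
    lg <- batch_loss_grad(fw$scores, stack$masks, idx)
    if (!is.finite(lg$loss)) {
      stop(sprintf("training diverged at iteration %d (loss = %s)",
                   t, format(lg$loss)), call. = FALSE)
    }
    grads <- fcn_backward(model, fw$cache, lg$dscores)
    if (is.finite(tc$max_grad_norm)) {
      gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
      if (gn > tc$max_grad_norm) {
        sc <- tc$max_grad_norm / gn
        grads <- lapply(grads, function(g) g * sc)
      }
    }
    lr <- step_lr(t, tc)
    stage1 <- t <= tc$stage1_iter
    for (i in seq_along(model$params)) {
      if (stage1 && frozen[i]) next
      vel[[i]] <- tc$momentum * vel[[i]] - lr * grads[[i]]
      model$params[[i]] <- model$params[[i]] + vel[[i]]
    }
    hist_loss[t] <- lg$loss
    hist_lr[t] <- lr
    if (t == tc$stage1_iter) stage1_model <- model
  }
  model <- recalibrate_bn(model, stack, tc$batch_size, seed = tc$seed + 1L)
  history <- tibble::tibble(
    iteration = seq_len(tc$max_iter), loss = hist_loss, lr = hist_lr,
    stage = ifelse(seq_len(tc$max_iter) <= tc$stage1_iter, 1L, 2L))
  structure(list(model = model, history = history, train_config = tc,
                 stage1_model = stage1_model),
            class = "fcn_fit")
}

#' @exportS3Method base::print
print.fcn_fit <- function(x, ...) {
  cat(sprintf("<fcn_fit> %d iterations, final loss %.5g\n",
              nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Per-slice class probabilities from a trained network
#'
#' @param model A `fusion_fcn` (or an `fcn_fit`, whose model is used).
#' @param stack A `slice_stack`.
#' @param batch_size Slices per forward pass.
#' @return List of `H x W x 2` probability arrays, one per slice.
#' @export
predict_probs <- function(model, stack, batch_size = 16) {
  if (inherits(model, "fcn_fit")) model <- model$model
  n <- length(stack$images)
  out <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- batch_tensor(stack, idx)
    fw <- fcn_forward(model, x, train = FALSE)
    probs <- softmax2(fw$scores)
    for (k in seq_along(idx)) out[[idx[k]]] <- probs[, , , k]
  }
  out
}

#' Predict per-slice masks with a trained network
#'
#' Per-pixel argmax of the two-class probability map, slice order preserved.
#'
#' @inheritParams predict_probs
#' @return The input `slice_stack` with `masks` replaced by predictions.
#' @export
predict_stack <- function(model, stack, batch_size = 16) {
  probs <- predict_probs(model, stack, batch_size)
  stack$masks <- lapply(probs, function(p) (p[, , 2] > p[, , 1]) * 1L)
  stack$provenance <- paste0(stack$provenance, "+fcn")
  stack
}
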