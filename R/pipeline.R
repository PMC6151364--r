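#' Configuration of an end-to-end pipeline run
#'
#' Bundles the stage configurations of the coarse-to-fine pipeline. A single
#' integer seed governs every stochastic stage (phantom speckle, mask
#' degradation, network initialization and batch order, surface sampling);
#' stage seeds are derived from it deterministically.
#'
#' @param phantom A [phantom_spec()].
#' @param net A [net_config()] (used when `mode = "fcn"`).
#' @param train A [train_config()] (used when `mode = "fcn"`).
#' @param snake A [snake_params()].
#' @param k Contour resampling interval along z.
#' @param mode Coarse stage: `"degraded-truth"` degrades the analytic mask
#'   (training-free run); `"fcn"` trains the fusion FCN on the phantom slices
#'   and predicts the coarse masks.
#' @param degrade List of [degrade_mask()] rates for the training-free mode.
#' @param seed Master seed.
#' @param output_dir Artifact directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_spec(),
                       net = net_config(base_width = 8, depth = 3),
                       train = train_config(lr0 = 2e-4, decay_every = 100,
                                            momentum = 0.9, batch_size = 8,
                                            max_iter = 300, stage1_iter = 30,
                                            max_grad_norm = 100),
                       snake = snake_params(),
                       k = 10,
                       mode = c("degraded-truth", "fcn"),
                       degrade = list(dropout_rate = 0.05, blob_rate = 0.1,
                                      boundary_jitter = 1),
                       seed = 1L,
                       output_dir = tempfile("echosnake_run_")) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "phantom_spec"), inherits(net, "net_config"),
            inherits(train, "train_config"), inherits(snake, "snake_params"),
            k >= 1)
  structure(list(phantom = phantom, net = net, train = train, snake = snake,
                 k = as.integer(k), mode = mode, degrade = degrade,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param cfg A [run_config()].
#' @param path YAML path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(list(
    phantom = unclass(cfg$phantom[setdiff(names(cfg$phantom),
                                          c("center_xy", "basal_z"))]),
    net = unclass(cfg$net),
    train = unclass(cfg$train),
    snake = unclass(cfg$snake),
    k = cfg$k, mode = cfg$mode, degrade = cfg$degrade,
    seed = cfg$seed, output_dir = cfg$output_dir), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(phantom = do.call(phantom_spec, y$phantom),
             net = do.call(net_config, y$net),
             train = do.call(train_config, y$train),
             snake = do.call(snake_params, y$snake),
             k = y$k, mode = y$mode, degrade = y$degrade,
             seed = y$seed, output_dir = y$output_dir)
}

#' Rasterize a tube mesh into a binary mask
#'
#' For every z plane of the reference geometry intersecting the mesh, the
#' cross-section polygon is reconstructed by interpolating each vertical
#' vertex chain at that plane and filled by the even-odd rule. Used to compare
#' an evolved surface with voxel ground truth (D*, volumes).
#'
#' @param mesh A `tube_mesh` (mm coordinates).
#' @param ref An [volume()] or [label_mask()] supplying the voxel grid.
#' @return A [label_mask()] on the grid of `ref`.
#' @export
voxelize_tube_mesh <- function(mesh, ref) {
  d <- dim(ref$data)
  out <- array(0L, d)
  M <- mesh$n_rings; N <- mesh$n_points
  # chain i: apex + ring vertices bottom-up in mesh order
  chain_xyz <- lapply(seq_len(N), function(i) {
    ids <- c(mesh$apex, mesh$ring_index[, i])
    mesh$vertices[ids, , drop = FALSE]
  })
  zs <- ref$origin[3] + (seq_len(d[3]) - 1) * ref$spacing[3]
  xs <- ref$origin[1] + (seq_len(d[1]) - 1) * ref$spacing[1]
  ys <- ref$origin[2] + (seq_len(d[2]) - 1) * ref$spacing[2]
  zmin <- min(mesh$vertices[, 3]); zmax <- max(mesh$vertices[, 3])
  for (kz in which(zs >= zmin & zs <= zmax)) {
    z <- zs[kz]
    poly <- matrix(NA_real_, N, 2)
    for (i in seq_len(N)) {
      ch <- chain_xyz[[i]]
      o <- order(ch[, 3])
      zc <- ch[o, 3]
      if (z < zc[1] || z > zc[length(zc)]) next
      poly[i, 1] <- stats::approx(zc, ch[o, 1], xout = z, ties = mean)$y
      poly[i, 2] <- stats::approx(zc, ch[o, 2], xout = z, ties = mean)$y
    }
    if (anyNA(poly)) next
    # even-odd polygon fill over the bounding box
    xr <- which(xs >= min(poly[, 1]) - 1 & xs <= max(poly[, 1]) + 1)
    yr <- which(ys >= min(poly[, 2]) - 1 & ys <= max(poly[, 2]) + 1)
    if (!length(xr) || !length(yr)) next
    px <- poly[, 1]; py <- poly[, 2]
    qx <- c(px[-1], px[1]); qy <- c(py[-1], py[1])
    gx <- rep(xs[xr], times = length(yr))
    gy <- rep(ys[yr], each = length(xr))
    inside <- rep(FALSE, length(gx))
    for (e in seq_len(N)) {
      crosses <- (py[e] > gy) != (qy[e] > gy)
      if (any(crosses)) {
        xint <- px[e] + (gy[crosses] - py[e]) * (qx[e] - px[e]) / (qy[e] - py[e])
        flip <- gx[crosses] < xint
        inside[crosses][flip] <- !inside[crosses][flip]
      }
    }
    blk <- out[xr, yr, kz]
    blk[matrix(inside, length(xr))] <- 1L
    out[xr, yr, kz] <- blk
  }
  label_mask(out, ref$spacing, ref$origin)
}

#' Run the full coarse-to-fine pipeline
#'
#' Executes phantom generation, the coarse stage (fusion FCN or degraded
#' ground truth), geometric initialization, snake refinement, and evaluation,
#' writing every intermediate artifact under `cfg$output_dir` together with a
#' manifest of MD5 content hashes. Identical configuration and seed give an
#' identical metrics report.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress?
#' @return An object of class `pipeline_run`: `report` (`metrics_report`),
#'   `manifest` (tibble of file names and hashes), `init`
#'   (`lv_initialization`), `snake` (`snake_fit`), `coarse_metrics` (pixel
#'   metrics tibble of the coarse stage vs truth), `paths`, `config`.
#' @export
run_pipeline <- function(cfg, verbose = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    say("stage %-10s %6.1f s", name,
        as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  ph <- stage("phantom", {
    spec <- cfg$phantom
    spec$seed <- cfg$seed
    p <- generate_phantom(spec)
    paths$volume <- file.path(cfg$output_dir, "volume.mhd")
    paths$mask <- file.path(cfg$output_dir, "truth_mask.mhd")
    paths$truth_mesh <- file.path(cfg$output_dir, "truth_mesh.ply")
    write_mhd(p$volume, paths$volume)
    write_mhd(p$mask, paths$mask)
    write_ply(p$mesh, paths$truth_mesh)
    p
  })

  truth_stack <- slice_volume(ph$volume, ph$mask, provenance = "phantom")
  fit <- NULL
  coarse_stack <- stage("coarse", {
    if (cfg$mode == "degraded-truth") {
      dm <- degrade_mask(ph$mask,
                         dropout_rate = cfg$degrade$dropout_rate,
                         blob_rate = cfg$degrade$blob_rate,
                         boundary_jitter = cfg$degrade$boundary_jitter,
                         seed = cfg$seed + 1L)
      st <- truth_stack
      st$masks <- lapply(seq_len(dim(dm$data)[3]), function(z) dm$data[, , z])
      st$provenance <- "degraded-truth"
      st
    } else {
      model <- build_network(cfg$net, seed = cfg$seed + 2L)
      tc <- cfg$train
      tc$seed <- cfg$seed + 3L
      fit <- train_network(model, truth_stack, tc)
      utils::write.csv(fit$history,
                       file.path(cfg$output_dir, "train_log.csv"),
                       row.names = FALSE)
      paths$train_log <- file.path(cfg$output_dir, "train_log.csv")
      predict_stack(fit$model, truth_stack)
    }
  })
  paths$coarse_mask <- file.path(cfg$output_dir, "coarse_mask.mhd")
  write_mhd(restack_slices(coarse_stack, "mask"), paths$coarse_mask)
  coarse_metrics <- pixel_metrics(confusion_counts(coarse_stack$masks,
                                                   truth_stack$masks))

  init <- stage("init", {
    ini <- initialize_lv_mesh(coarse_stack, k = cfg$k)
    paths$rings <- file.path(cfg$output_dir, "rings.yaml")
    paths$init_mesh <- file.path(cfg$output_dir, "init.ply")
    write_ring_table(ini, paths$rings)
    write_ply(ini$mesh, paths$init_mesh)
    ini
  })

  snake <- stage("refine", {
    sf <- evolve_snake(init$mesh, ph$volume, cfg$snake)
    paths$final_mesh <- file.path(cfg$output_dir, "final.ply")
    paths$energy_log <- file.path(cfg$output_dir, "energy.csv")
    write_ply(sf$mesh, paths$final_mesh)
    utils::write.csv(sf$history, paths$energy_log, row.names = FALSE)
    sf
  })

  report <- stage("eval", {
    final_mask <- voxelize_tube_mesh(snake$mesh, ph$mask)
    rep <- evaluate_segmentation(snake$mesh, ph$mesh,
                                 mask = final_mask, mask_t = ph$mask,
                                 seed = cfg$seed + 4L)
    paths$metrics <- file.path(cfg$output_dir, "metrics.json")
    write_metrics_report(rep, paths$metrics)
    rep
  })

  files <- unlist(paths)
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest,
                       file.path(cfg$output_dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  structure(list(report = report, manifest = manifest, init = init,
                 snake = snake, fcn = fit, coarse_metrics = coarse_metrics,
                 paths = paths, config = cfg),
            class = "pipeline_run")
}

#' @exportS3Method base::print
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> mode '%s', seed %d\n", x$config$mode,
              x$config$seed))
  print(x$report)
  invisible(x)
}
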