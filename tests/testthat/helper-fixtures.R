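# Shared fixtures, built once per session and cached (phantom generation is
# the slow part of the suite).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_spec <- function(...) {
  phantom_spec(grid_shape = c(32, 32, 40), cavity_semi_axes = c(8, 8, 16),
               wall_thickness = 3, atrium_enabled = FALSE,
               speckle_scale = 0, smoothing_sigma = 0, ...)
}

noiseless_phantom <- function() {
  fixture("noiseless_phantom",
          generate_phantom(phantom_spec(speckle_scale = 0, smoothing_sigma = 0)))
}

default_phantom <- function() {
  fixture("default_phantom", generate_phantom(phantom_spec()))
}

hemisphere_phantom <- function() {
  fixture("hemisphere_phantom",
          generate_phantom(phantom_spec(grid_shape = c(64, 64, 48),
                                        cavity_semi_axes = c(12, 12, 12),
                                        atrium_enabled = FALSE,
                                        speckle_scale = 0, smoothing_sigma = 0,
                                        apex_margin = 8)))
}

# dense uniform-ish sample of a sphere surface (golden-spiral lattice)
sphere_points <- function(n, radius, center = c(0, 0, 0)) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(center[1] + radius * sin(phi) * cos(th),
        center[2] + radius * sin(phi) * sin(th),
        center[3] + radius * cos(phi))
}

# independent O(n^2) nearest-neighbor oracle
brute_directed <- function(P, Q, agg) {
  d <- sapply(seq_len(nrow(P)), function(i) {
    min(sqrt(colSums((t(Q) - P[i, ])^2)))
  })
  agg(d)
}

mean_iou_of <- function(pred_masks, truth_masks) {
  pixel_metrics(confusion_counts(pred_masks, truth_masks))$mean_iou
}
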