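# Shared fixtures built in code. Rendering helpers place cells at exact poses
# and render them noiselessly so geometric expectations are deterministic.

# Render given poses (tibble with x, y, z, axis_*, length_um, width_um) into a
# noiseless stack: capsule rasterization + Gaussian PSF, no noise.
render_poses <- function(poses, field = c(20, 20, 4),
                         voxel = c(0.25, 0.25, 0.25),
                         psf_sigma = 0.2, amplitude = 100) {
  cfg <- list(voxel_size = voxel, psf_sigma = psf_sigma, amplitude = amplitude)
  d <- c(ceiling(field[2] / voxel[2]), ceiling(field[1] / voxel[1]),
         ceiling(field[3] / voxel[3]))
  vol <- array(0, dim = d)
  for (k in seq_len(nrow(poses)))
    vol <- mxnfb:::render_capsule(vol, cfg, poses[k, ])
  vol <- mxnfb:::gauss_smooth_3d(vol, psf_sigma / voxel[c(2, 1, 3)])
  image_stack(vol, voxel_size = voxel, channel = "green")
}

pose <- function(x, y, z, ax = c(1, 0, 0), length_um = 5, width_um = 0.5) {
  ax <- ax / sqrt(sum(ax^2))
  tibble::tibble(x = x, y = y, z = z, axis_x = ax[1], axis_y = ax[2],
                 axis_z = ax[3], length_um = length_um, width_um = width_um)
}

# Minimal rod table for the spatial statistics (no imaging involved).
rod_frame <- function(xyz, axes, class = "rod", replicate = 1L) {
  axes <- axes / sqrt(rowSums(axes^2))
  tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 axis_x = axes[, 1], axis_y = axes[, 2], axis_z = axes[, 3],
                 class = class, replicate = replicate)
}

# Small, fast scene configuration for end-to-end tests.
small_scene_config <- function(seed = 5, ...) {
  scene_config(field = c(30, 30, 5), voxel_size = c(0.25, 0.25, 0.25),
               density = list(r = c(0, 8, 18), value = c(25, 25, 6)),
               seed = seed, ...)
}

# Independent brute-force Otsu oracle: exhaustive between-class-variance
# maximization over all split points of a 256-bin histogram.
brute_force_otsu <- function(vals, n_bins = 256L) {
  rng <- range(vals)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(vals, breaks, all.inside = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  best <- -Inf
  best_k <- 1L
  n <- sum(counts)
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:k])
    n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):n_bins] * mids[(k + 1):n_bins]) / n1
    bcv <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (bcv > best) {
      best <- bcv
      best_k <- k
    }
  }
  breaks[best_k + 1L]
}
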