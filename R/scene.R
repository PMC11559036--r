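#' Configuration for a synthetic NFB scene
#'
#' Describes a two-strain, two-channel volumetric scene emulating the bottom
#' layers of a nascent fruiting body (NFB): cells are placed by a radial
#' density function around the NFB center, rods and transitioning cells are
#' oriented by a nematic field biased toward the local tangential direction,
#' and labeled cells are rendered as spherocylinders (rods / transitioning
#' cells) or spheres (spores) through a Gaussian point-spread function with
#' Poisson shot noise and Gaussian read noise.
#'
#' @param field length-3 numeric, field size in micrometers (x, y, z);
#'   the z span defaults to the 5 um imaged above the well bottom.
#' @param voxel_size length-3 numeric, micrometers per voxel (x, y, z).
#' @param center NFB center (x, y) in micrometers.
#' @param density radial density of all cells (labeled + unlabeled), cells
#'   per 1,000 um^3 as a function of radius in micrometers; either a
#'   function, a single number, or a list with elements `r` and `value`
#'   (piecewise linear, extended flat beyond the last knot).
#' @param n_cells optional fixed total cell count; by default the count is
#'   Poisson with mean given by integrating `density` over the field.
#' @param tangential_kappa concentration of rod/TC axes about the local
#'   tangential direction (nematic von Mises on the doubled angle); `0` =
#'   isotropic in-plane, `Inf` = exactly tangential.
#' @param alignment_strength extra local nematic coupling in `[0, 1)`: each
#'   rod's in-plane angle is shrunk toward the kernel-weighted (sigma 2.5 um)
#'   mean orientation of already-placed rods.
#' @param strain_ratio initial csgA / WT number ratio.
#' @param class_mix named probabilities over
#'   `c("rod", "transitioning", "spore")`, or a list with entries `WT` and
#'   `csgA` for per-strain mixes.
#' @param labeled_fraction fraction of each strain carrying the fluorescent
#'   label (1/2 or 1/4 in the experiments emulated); only labeled cells are
#'   rendered.
#' @param geometry list of class geometry ranges (micrometers):
#'   `rod_length`, `rod_width`, `tc_length`, `tc_width`, `spore_diameter`.
#' @param psf_sigma isotropic Gaussian PSF sigma, micrometers.
#' @param amplitude peak fluorophore intensity added per cell (photons).
#' @param background mean background intensity (photons).
#' @param read_noise Gaussian read noise standard deviation.
#' @param min_separation minimum surface-to-surface separation enforced
#'   between capsules (hard-core placement), micrometers.
#' @param tilt_sd standard deviation (radians) of the out-of-plane tilt of
#'   rod/TC axes.
#' @param max_attempts placement attempts per cell before the scene is
#'   declared density-infeasible.
#' @param seed integer; fixes the scene exactly.
#' @return a `scene_config` list.
#' @export
scene_config <- function(field = c(80, 80, 5),
                         voxel_size = c(0.25, 0.25, 0.25),
                         center = field[1:2] / 2,
                         density = list(r = c(0, 10, 25, 45, 60),
                                        value = c(40, 33, 20, 7, 7)),
                         n_cells = NULL,
                         tangential_kappa = 4,
                         alignment_strength = 0.3,
                         strain_ratio = 1,
                         class_mix = c(rod = 0.55, transitioning = 0.10,
                                       spore = 0.35),
                         labeled_fraction = 0.5,
                         geometry = list(rod_length = c(3, 6),
                                         rod_width = c(0.4, 0.6),
                                         tc_length = c(1.4, 1.8),
                                         tc_width = c(0.8, 0.95),
                                         spore_diameter = c(1.0, 1.6)),
                         psf_sigma = 0.2,
                         amplitude = 120,
                         background = 5,
                         read_noise = 2,
                         min_separation = 0.3,
                         tilt_sd = 0.08,
                         max_attempts = 2000,
                         seed = 1) {
  field <- as.numeric(field)
  stopifnot(length(field) == 3L, all(field > 0),
            length(voxel_size) == 3L, all(voxel_size > 0),
            length(center) == 2L)
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop("`labeled_fraction` must be in (0, 1]", call. = FALSE)
  if (alignment_strength < 0 || alignment_strength >= 1)
    stop("`alignment_strength` must be in [0, 1)", call. = FALSE)
  if (tangential_kappa < 0) stop("`tangential_kappa` must be >= 0", call. = FALSE)
  dens_fn <- as_density_fn(density)
  cfg <- list(field = field, voxel_size = as.numeric(voxel_size),
              center = as.numeric(center), density = density,
              density_fn = dens_fn, n_cells = n_cells,
              tangential_kappa = tangential_kappa,
              alignment_strength = alignment_strength,
              strain_ratio = strain_ratio, class_mix = class_mix,
              labeled_fraction = labeled_fraction, geometry = geometry,
              psf_sigma = psf_sigma, amplitude = amplitude,
              background = background, read_noise = read_noise,
              min_separation = min_separation, tilt_sd = tilt_sd,
              max_attempts = max_attempts, seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

as_density_fn <- function(density) {
  if (is.function(density)) return(density)
  if (is.numeric(density) && length(density) == 1L) {
    force(density)
    return(function(r) rep(density, length(r)))
  }
  if (is.list(density) && !is.null(density$r) && !is.null(density$value)) {
    if (any(density$value < 0)) stop("densities must be >= 0", call. = FALSE)
    return(stats::approxfun(density$r, density$value, rule = 2))
  }
  stop("`density` must be a function, a number, or list(r=, value=)", call. = FALSE)
}

## Expected total cell count: integrate density (cells / 1,000 um^3) over the
## field on a 0.5 um xy grid.
expected_cell_count <- function(cfg) {
  h <- 0.5
  gx <- seq(h / 2, cfg$field[1] - h / 2, by = h)
  gy <- seq(h / 2, cfg$field[2] - h / 2, by = h)
  r <- sqrt(outer(gy - cfg$center[2], gx - cfg$center[1],
                  function(a, b) a^2 + b^2))
  sum(cfg$density_fn(r)) / 1000 * h * h * cfg$field[3]
}

## Vectorized capsule-capsule (segment-segment) distance: one candidate
## segment (p1, p2) against n existing segments (rows of q1, q2).
segseg_dist <- function(p1, p2, q1, q2) {
  eps <- 1e-12
  d1 <- p2 - p1
  d2 <- q2 - q1
  r0 <- matrix(p1, nrow(q1), 3, byrow = TRUE) - q1
  a <- sum(d1 * d1)
  e <- rowSums(d2 * d2)
  f <- rowSums(d2 * r0)
  cc <- as.vector(r0 %*% d1)
  b <- as.vector(d2 %*% d1)
  denom <- a * e - b * b
  s <- ifelse(denom > eps, pmin(pmax((b * f - cc * e) / denom, 0), 1), 0)
  t <- ifelse(e > eps, (b * s + f) / e, 0)
  tl <- pmin(pmax(t, 0), 1)
  redo <- tl != t
  s <- ifelse(redo & a > eps, pmin(pmax((tl * b - cc) / a, 0), 1), s)
  t <- tl
  px <- p1[1] + s * d1[1] - (q1[, 1] + t * d2[, 1])
  py <- p1[2] + s * d1[2] - (q1[, 2] + t * d2[, 2])
  pz <- p1[3] + s * d1[3] - (q1[, 3] + t * d2[, 3])
  sqrt(px * px + py * py + pz * pz)
}

## Nematic von Mises draw on the doubled angle: density proportional to
## exp(kappa * cos(2 * psi)) on (-pi/2, pi/2]; kappa = Inf is the tangential
## delta limit.
rnematic <- function(kappa) {
  if (!is.finite(kappa)) return(0)
  if (kappa <= 0) return(runif(1, -pi / 2, pi / 2))
  repeat {
    psi <- runif(1, -pi / 2, pi / 2)
    if (runif(1) < exp(kappa * (cos(2 * psi) - 1))) return(psi)
  }
}

sample_class_geometry <- function(class, geom) {
  switch(class,
    rod = {
      w <- runif(1, geom$rod_width[1], geom$rod_width[2])
      l <- runif(1, max(geom$rod_length[1], 2.5 * w), geom$rod_length[2])
      c(length = l, width = w)
    },
    transitioning = {
      w <- runif(1, geom$tc_width[1], geom$tc_width[2])
      l <- runif(1, geom$tc_length[1], geom$tc_length[2])
      c(length = l, width = w)
    },
    spore = {
      d <- runif(1, geom$spore_diameter[1], geom$spore_diameter[2])
      c(length = d, width = d)
    },
    stop("unknown class: ", class))
}

per_strain_mix <- function(class_mix) {
  if (is.list(class_mix) && !is.null(class_mix$WT)) {
    list(WT = class_mix$WT[CLASS_LEVELS], csgA = class_mix$csgA[CLASS_LEVELS])
  } else {
    m <- class_mix[CLASS_LEVELS]
    list(WT = m, csgA = m)
  }
}

place_cells <- function(cfg) {
  n <- cfg$n_cells %||% rpois(1, expected_cell_count(cfg))
  mixes <- per_strain_mix(cfg$class_mix)
  p_csga <- cfg$strain_ratio / (1 + cfg$strain_ratio)
  rho_max <- max(cfg$density_fn(seq(0, sqrt(sum(cfg$field[1:2]^2)), by = 0.25)))
  if (n == 0 || rho_max <= 0)
    return(tibble::tibble(cell_id = integer(), x = numeric(), y = numeric(),
                          z = numeric(), axis_x = numeric(), axis_y = numeric(),
                          axis_z = numeric(), length_um = numeric(),
                          width_um = numeric(), class = character(),
                          strain = character(), labeled = logical(),
                          r_um = numeric()))
  out <- vector("list", n)
  ends1 <- matrix(NA_real_, n, 3)
  ends2 <- matrix(NA_real_, n, 3)
  radii <- numeric(n)
  ## previously placed rod/TC doubled-angle vectors, for local alignment
  placed_xy <- matrix(NA_real_, n, 2)
  placed_phi <- rep(NA_real_, n)
  n_oriented <- 0L
  for (i in seq_len(n)) {
    strain <- if (runif(1) < p_csga) "csgA" else "WT"
    cls <- sample(CLASS_LEVELS, 1, prob = mixes[[strain]])
    geomi <- sample_class_geometry(cls, cfg$geometry)
    l <- geomi[["length"]]; w <- geomi[["width"]]
    hl <- (l - w) / 2
    ok <- FALSE
    for (att in seq_len(cfg$max_attempts)) {
      pos <- c(runif(1, 0, cfg$field[1]), runif(1, 0, cfg$field[2]),
               runif(1, w / 2, cfg$field[3] - w / 2))
      r <- sqrt(sum((pos[1:2] - cfg$center)^2))
      if (runif(1) >= cfg$density_fn(r) / rho_max) next
      ## Retry orientations at this accepted position before giving it up:
      ## abandoning crowded positions on the first conflict would deplete
      ## dense regions and bias the realized density below the target.
      n_otry <- if (cls == "spore") 1L else 20L  # spheres are orientation-free
      for (otry in seq_len(n_otry)) {
        if (cls == "spore") {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
        } else {
          tang <- if (r < 1e-9) c(1, 0) else
            c(-(pos[2] - cfg$center[2]), pos[1] - cfg$center[1]) / r
          psi <- rnematic(cfg$tangential_kappa)
          alpha <- atan2(tang[2], tang[1]) + psi
          if (cfg$alignment_strength > 0 && n_oriented > 0 &&
              is.finite(cfg$tangential_kappa)) {
            dx <- placed_xy[seq_len(n_oriented), 1] - pos[1]
            dy <- placed_xy[seq_len(n_oriented), 2] - pos[2]
            wgt <- exp(-(dx^2 + dy^2) / (2 * 2.5^2))
            if (sum(wgt) > 1e-6) {
              phi0 <- placed_phi[seq_len(n_oriented)]
              mu <- atan2(sum(wgt * sin(phi0)), sum(wgt * cos(phi0)))
              v <- (1 - cfg$alignment_strength) * c(cos(2 * alpha), sin(2 * alpha)) +
                   cfg$alignment_strength * c(cos(mu), sin(mu))
              alpha <- atan2(v[2], v[1]) / 2
            }
          }
          zeta <- if (cfg$tilt_sd > 0 && is.finite(cfg$tangential_kappa))
            rnorm(1, 0, cfg$tilt_sd) else 0
          u <- c(cos(zeta) * cos(alpha), cos(zeta) * sin(alpha), sin(zeta))
        }
        e1 <- pos - hl * u
        e2 <- pos + hl * u
        lo <- pmin(e1, e2) - w / 2
        hi <- pmax(e1, e2) + w / 2
        if (lo[1] < 0 || lo[2] < 0 || hi[1] > cfg$field[1] ||
            hi[2] > cfg$field[2])
          next
        if (i > 1) {
          prev <- seq_len(i - 1)
          d <- segseg_dist(e1, e2, ends1[prev, , drop = FALSE],
                           ends2[prev, , drop = FALSE])
          if (any(d < (w + radii[prev] * 2) / 2 + cfg$min_separation)) next
        }
        ok <- TRUE
        break
      }
      if (ok) break
    }
    if (!ok)
      stop("density-infeasible: could not place cell ", i, " after ",
           cfg$max_attempts, " attempts", call. = FALSE)
    ends1[i, ] <- e1
    ends2[i, ] <- e2
    radii[i] <- w / 2
    if (cls != "spore") {
      n_oriented <- n_oriented + 1L
      placed_xy[n_oriented, ] <- pos[1:2]
      placed_phi[n_oriented] <- 2 * atan2(u[2], u[1])
    }
    out[[i]] <- tibble::tibble(
      cell_id = i, x = pos[1], y = pos[2], z = pos[3],
      axis_x = u[1], axis_y = u[2], axis_z = u[3],
      length_um = l, width_um = w, class = cls, strain = strain,
      labeled = runif(1) < cfg$labeled_fraction, r_um = r)
  }
  do.call(rbind, out)
}

## Add one capsule (soft partial-volume indicator * amplitude) into `vol`.
render_capsule <- function(vol, cfg, cell) {
  vs <- cfg$voxel_size
  d <- dim(vol)
  hl <- (cell$length_um - cell$width_um) / 2
  u <- c(cell$axis_x, cell$axis_y, cell$axis_z)
  ctr <- c(cell$x, cell$y, cell$z)
  pad <- cell$width_um / 2 + 3 * cfg$psf_sigma + max(vs)
  lo <- ctr - hl * abs(u) - pad
  hi <- ctr + hl * abs(u) + pad
  ix <- max(1L, floor(lo[1] / vs[1])):min(d[2], ceiling(hi[1] / vs[1]))
  iy <- max(1L, floor(lo[2] / vs[2])):min(d[1], ceiling(hi[2] / vs[2]))
  iz <- max(1L, floor(lo[3] / vs[3])):min(d[3], ceiling(hi[3] / vs[3]))
  px <- (ix - 0.5) * vs[1]
  py <- (iy - 0.5) * vs[2]
  pz <- (iz - 0.5) * vs[3]
  g <- expand.grid(y = py, x = px, z = pz)
  rel <- cbind(g$x - ctr[1], g$y - ctr[2], g$z - ctr[3])
  t <- pmin(pmax(rel %*% u, -hl), hl)
  dd <- sqrt(rowSums((rel - t %*% t(u))^2))
  edge <- mean(vs)
  frac <- pmin(pmax((cell$width_um / 2 - dd) / edge + 0.5, 0), 1)
  add <- array(frac * cfg$amplitude, dim = c(length(iy), length(ix), length(iz)))
  vol[iy, ix, iz] <- vol[iy, ix, iz] + add
  vol
}

#' Generate a synthetic two-channel NFB scene with ground truth
#'
#' Places cells by rejection sampling against the configured radial density
#' (hard-core: no two capsules intersect), draws rod/TC axes from a nematic
#' field biased toward the local tangential direction, renders labeled cells
#' through a Gaussian PSF with Poisson + Gaussian noise, and returns the
#' ground truth for every placed cell. WT labeled cells emit in the green
#' channel, csgA labeled cells in the red channel.
#'
#' @param config a [scene_config()].
#' @param render if `FALSE`, skip image rendering and return poses only
#'   (used for placement-statistics studies).
#' @return a list with elements `cells` (tibble of true poses; only rows with
#'   `labeled == TRUE` are visible in the images), `stacks` (named list of
#'   [image_stack()], `green` and `red`; `NULL` when `render = FALSE`), and
#'   `config`.
#' @export
generate_scene <- function(config, render = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, {
    cells <- place_cells(config)
    stacks <- NULL
    if (render) {
      d <- c(ceiling(config$field[2] / config$voxel_size[2]),
             ceiling(config$field[1] / config$voxel_size[1]),
             ceiling(config$field[3] / config$voxel_size[3]))
      sigma_vox <- config$psf_sigma / config$voxel_size[c(2, 1, 3)]
      stacks <- list()
      for (ch in c("green", "red")) {
        strain <- if (ch == "green") "WT" else "csgA"
        vol <- array(0, dim = d)
        vis <- cells[cells$labeled & cells$strain == strain, , drop = FALSE]
        if (nrow(vis) > 0)
          for (k in seq_len(nrow(vis)))
            vol <- render_capsule(vol, config, vis[k, ])
        vol <- gauss_smooth_3d(vol, sigma_vox)
        lambda <- vol + config$background
        noisy <- rpois(length(lambda), lambda) +
          rnorm(length(lambda), 0, config$read_noise)
        vol <- array(pmax(noisy, 0), dim = d)
        stacks[[ch]] <- image_stack(vol, voxel_size = config$voxel_size,
                                    channel = ch)
      }
    }
    list(cells = cells, stacks = stacks, config = config)
  })
}

#' Write a generated scene to disk
#'
#' Stacks go to `<dir>/scene_green.tif` / `<dir>/scene_red.tif` (with JSON
#' sidecars) and the ground truth to `<dir>/truth.csv`.
#'
#' @param scene result of [generate_scene()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(scene$stacks)) {
    write_stack(scene$stacks$green, file.path(dir, "scene_green.tif"))
    write_stack(scene$stacks$red, file.path(dir, "scene_red.tif"))
  }
  utils::write.csv(scene$cells, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
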