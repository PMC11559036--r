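#' Hessian-eigenvalue enhancement of bright cells
#'
#' Computes a voxelwise "cell-ness" response from the intensity Hessian at a
#' given smoothing scale: the volume is Gaussian-smoothed at `scale`
#' micrometers, the six second derivatives are taken in physical units, and
#' the response is the magnitude of the most-negative Hessian eigenvalue
#' (clipped at zero). Bright tubular and blob-like structures — rods, TCs,
#' and spores — have strongly negative principal curvature and light up;
#' flat background stays near zero.
#'
#' @param stack an [image_stack()].
#' @param scale smoothing scale in micrometers; about half the expected cell
#'   width works well (default 0.25).
#' @return an [image_stack()] carrying the nonnegative response.
#' @export
hessian_enhance <- function(stack, scale = 0.25) {
  stopifnot(inherits(stack, "image_stack"))
  assert_scalar_pos(scale, "scale")
  spacing <- stack$voxel_size[c("y", "x", "z")]
  a <- gauss_smooth_3d(stack$data, scale / spacing)
  h11 <- second_diff(a, 1L, 1L, spacing)
  h22 <- second_diff(a, 2L, 2L, spacing)
  h33 <- second_diff(a, 3L, 3L, spacing)
  h12 <- second_diff(a, 1L, 2L, spacing)
  h13 <- second_diff(a, 1L, 3L, spacing)
  h23 <- second_diff(a, 2L, 3L, spacing)
  lam <- eig_min_sym3(h11, h22, h33, h12, h13, h23)
  out <- stack
  out$data <- array(pmax(-lam, 0), dim = dim(stack$data))
  out
}

center_quarter_mask <- function(d) {
  ny <- d[1]; nx <- d[2]
  y0 <- floor(ny / 4) + 1L; y1 <- y0 + floor(ny / 2) - 1L
  x0 <- floor(nx / 4) + 1L; x1 <- x0 + floor(nx / 2) - 1L
  list(y = y0:y1, x = x0:x1)
}

otsu_from_hist <- function(counts, breaks) {
  n <- sum(counts)
  w0 <- cumsum(counts)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  m0 <- cumsum(counts * mids)
  mt <- m0[length(m0)]
  k <- seq_len(length(counts) - 1L)
  omega0 <- w0[k] / n
  omega1 <- 1 - omega0
  mu0 <- ifelse(w0[k] > 0, m0[k] / w0[k], 0)
  mu1 <- ifelse(n - w0[k] > 0, (mt - m0[k]) / (n - w0[k]), 0)
  bcv <- omega0 * omega1 * (mu0 - mu1)^2
  kbest <- which.max(bcv)  # first maximum on ties
  breaks[kbest + 1L]
}

#' Otsu threshold from the center quarter of each plane
#'
#' Otsu's between-class-variance-maximizing threshold is computed only from
#' voxels in the central rectangle of half the width and half the height of
#' each xy-plane (one quarter of the area), pooled over z into a single
#' 256-bin histogram per stack (or one per plane with
#' `per_plane = TRUE`). The NFB center dominates that region, so the
#' estimate is insensitive to clutter near the image borders; the threshold
#' is then applied to the full volume by [binarize_stack()].
#'
#' @param stack an [image_stack()], normally the response from
#'   [hessian_enhance()].
#' @param n_bins histogram bin count over the observed center-quarter range.
#' @param per_plane compute one threshold per z-plane instead of one per
#'   stack (returned as a vector).
#' @return the threshold(s), on the intensity scale of `stack`.
#' @export
otsu_center_quarter <- function(stack, n_bins = 256L, per_plane = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  m <- center_quarter_mask(dim(stack$data))
  one <- function(vals) {
    rng <- range(vals)
    if (diff(rng) <= 0)
      stop("degenerate histogram: the center quarter is constant (",
           format(rng[1]), "); check that the stack contains structure, or ",
           "enhance it first with hessian_enhance()", call. = FALSE)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    counts <- tabulate(
      pmin(pmax(findInterval(vals, breaks, all.inside = TRUE), 1L), n_bins),
      nbins = n_bins)
    otsu_from_hist(counts, breaks)
  }
  if (per_plane) {
    vapply(seq_len(dim(stack$data)[3]),
           function(k) one(as.vector(stack$data[m$y, m$x, k])), numeric(1))
  } else {
    one(as.vector(stack$data[m$y, m$x, , drop = FALSE]))
  }
}

#' Binarize a stack at a threshold
#'
#' @param stack an [image_stack()].
#' @param threshold scalar (whole stack) or per-plane vector from
#'   [otsu_center_quarter()].
#' @return a logical array, `TRUE` above threshold.
#' @export
binarize_stack <- function(stack, threshold) {
  d <- dim(stack$data)
  if (length(threshold) == 1L) return(stack$data > threshold)
  stopifnot(length(threshold) == d[3])
  stack$data > rep(threshold, each = d[1] * d[2])
}

## Split oversized components with a distance-transform watershed. Markers
## are the 26-connected components of the region deeper than
## `seed_suppression` micrometers from the surface (erosion markers): a
## single cell keeps one connected ridge and stays whole, while two cells
## merged through a thin bright bridge have shallow distance at the neck and
## split there. Voxels then flood to markers in order of decreasing depth.
split_component <- function(labels, dims, comp_ids, edt_sq, seed_suppression) {
  deep <- edt_sq >= seed_suppression^2
  seeds <- cc_label_3d(deep & labels > 0L, dims)
  markers <- integer(length(labels))
  next_label <- max(labels)
  changed <- FALSE
  for (cid in comp_ids) {
    in_comp <- labels == cid
    sids <- setdiff(unique(seeds[in_comp]), 0L)
    if (length(sids) < 2L) next
    for (s in sids) {
      next_label <- next_label + 1L
      markers[in_comp & seeds == s] <- next_label
    }
    changed <- TRUE
  }
  if (!changed) return(labels)
  split_ids <- comp_ids[vapply(comp_ids, function(cid)
    any(markers[labels == cid] > 0L), logical(1))]
  region <- ifelse(labels %in% split_ids, labels, 0L)
  flooded <- marker_flood_3d(edt_sq, markers, region, dims)
  labels[flooded > 0L] <- flooded[flooded > 0L]
  labels
}

#' Extract segmented cells from a binary volume
#'
#' Foreground voxels are grouped into 26-connected 3D components; components
#' below `min_volume` are discarded; components larger than
#' `max_cell_volume` are split by a distance-transform watershed. Per-cell
#' shape features come from the second-moment tensor of the voxel-center
#' positions (regularized by the voxel second moment, so single-voxel cells
#' stay finite and are flagged): extents are `4 * sqrt(eigenvalues)`
#' (full-width convention, sorted descending), the principal axis is the
#' leading eigenvector, elongation is major/minor extent and planarity
#' mid/minor.
#'
#' @param binary logical array (ny, nx, nz) from [binarize_stack()].
#' @param voxel_size micrometers per voxel (x, y, z).
#' @param min_volume minimum cell volume in cubic micrometers.
#' @param split_touching split oversized components (watershed)?
#' @param max_cell_volume volume above which a component is considered a
#'   candidate merger of touching cells.
#' @param response optional numeric array of the enhancement response the
#'   binary mask was thresholded from. When given, oversized components are
#'   split by a watershed on the response with prominence merging: sub-peaks
#'   rising less than `split_h` above their connecting saddle are merged, so
#'   intensity fluctuations within one cell never split it while the deep
#'   valley between two merged cells does.
#' @param split_h prominence threshold for response-based splitting (same
#'   units as `response`); the segmentation threshold itself is a good
#'   choice. Required when `response` is given.
#' @param seed_suppression fallback splitting without `response`: erosion
#'   depth (micrometers) defining distance-transform watershed markers
#'   (connected regions deeper than this from the component surface). Must
#'   exceed the voxel pitch to have any effect (a surface voxel already sits
#'   one pitch deep); the default suits ~0.25 um voxels.
#' @param intensity optional numeric array of raw intensities for per-cell
#'   mean intensity.
#' @param stack_meta optional list of provenance fields (`channel`,
#'   `time_h`, `replicate`, `location`) copied onto every row.
#' @return a tibble, one row per cell: `cell_id`, centroid `x`, `y`, `z`
#'   (um), `axis_x/y/z` (unit principal axis), `len_major`, `len_mid`,
#'   `len_minor` (um), `volume_um3`, `elongation`, `planarity`, `n_voxels`,
#'   `mean_intensity`, `degenerate` flag, plus provenance columns.
#' @export
segment_cells <- function(binary, voxel_size, min_volume = 0.05,
                          split_touching = TRUE, max_cell_volume = 3,
                          response = NULL, split_h = NULL,
                          seed_suppression = 0.3,
                          intensity = NULL, stack_meta = list()) {
  stopifnot(is.logical(binary) || all(binary %in% c(0, 1)))
  voxel_size <- as.numeric(voxel_size)
  names(voxel_size) <- c("x", "y", "z")
  dims <- dim(binary)
  vox_vol <- prod(voxel_size)
  empty <- tibble::tibble(
    cell_id = integer(), x = numeric(), y = numeric(), z = numeric(),
    axis_x = numeric(), axis_y = numeric(), axis_z = numeric(),
    len_major = numeric(), len_mid = numeric(), len_minor = numeric(),
    volume_um3 = numeric(), elongation = numeric(), planarity = numeric(),
    n_voxels = integer(), mean_intensity = numeric(), degenerate = logical())
  if (!any(binary)) return(add_meta(empty, stack_meta))
  labels <- cc_label_3d(as.logical(binary), dims)
  sizes <- tabulate(labels)
  keep <- which(sizes * vox_vol >= min_volume)
  if (length(keep) == 0L) return(add_meta(empty, stack_meta))
  labels[!(labels %in% keep)] <- 0L
  if (split_touching) {
    big <- keep[sizes[keep] * vox_vol > max_cell_volume]
    if (length(big) > 0L) {
      if (!is.null(response)) {
        if (is.null(split_h))
          stop("`split_h` is required when `response` is given", call. = FALSE)
        region <- ifelse(labels %in% big, labels, 0L)
        ws <- persistence_watershed_3d(as.numeric(response), region, dims,
                                       split_h)
        offset <- max(labels)
        labels[ws > 0L] <- offset + ws[ws > 0L]
      } else {
        edt <- edt_sq_3d(labels > 0L, dims, voxel_size[c("y", "x", "z")])
        labels <- split_component(labels, dims, big, edt, seed_suppression)
      }
      sizes <- tabulate(labels)
      small <- which(sizes > 0L & sizes * vox_vol < min_volume)
      if (length(small) > 0L) labels[labels %in% small] <- 0L
    }
  }
  vox <- which(labels > 0L)
  if (length(vox) == 0L) return(add_meta(empty, stack_meta))
  lab <- labels[vox]
  iz <- (vox - 1L) %/% (dims[1] * dims[2])
  rem <- (vox - 1L) - iz * dims[1] * dims[2]
  ix <- rem %/% dims[1]
  iy <- rem - ix * dims[1]
  px <- (ix + 0.5) * voxel_size["x"]
  py <- (iy + 0.5) * voxel_size["y"]
  pz <- (iz + 0.5) * voxel_size["z"]
  ints <- if (!is.null(intensity)) intensity[vox] else rep(NA_real_, length(vox))
  groups <- split(seq_along(vox), lab)
  reg <- diag(voxel_size^2 / 12)
  rows <- lapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    pts <- cbind(px[g], py[g], pz[g])
    ctr <- colMeans(pts)
    degen <- nrow(pts) < 4L
    cv <- if (nrow(pts) > 1L) cov(pts) * (nrow(pts) - 1) / nrow(pts)
          else matrix(0, 3, 3)
    e <- eigen(cv + reg, symmetric = TRUE)
    ext <- 4 * sqrt(pmax(e$values, 0))
    ax <- e$vectors[, 1]
    ax <- ax * sign(ax[which.max(abs(ax))])
    tibble::tibble(
      cell_id = gi, x = ctr[1], y = ctr[2], z = ctr[3],
      axis_x = ax[1], axis_y = ax[2], axis_z = ax[3],
      len_major = ext[1], len_mid = ext[2], len_minor = ext[3],
      volume_um3 = nrow(pts) * vox_vol,
      elongation = ext[1] / ext[3], planarity = ext[2] / ext[3],
      n_voxels = nrow(pts), mean_intensity = mean(ints[g]),
      degenerate = degen)
  })
  add_meta(do.call(rbind, rows), stack_meta)
}

add_meta <- function(df, meta) {
  for (f in c("channel", "strain", "time_h", "replicate", "location"))
    if (!is.null(meta[[f]])) df[[f]] <- meta[[f]]
  df
}

#' Segment one image stack end to end
#'
#' Convenience wrapper: [hessian_enhance()] at `scale`, threshold with
#' [otsu_center_quarter()] on the response, binarize, and extract cells with
#' [segment_cells()] (mean intensities come from the raw stack).
#'
#' @inheritParams hessian_enhance
#' @inheritParams segment_cells
#' @param per_plane_threshold one Otsu threshold per z-plane instead of per
#'   stack.
#' @param ... passed on to [segment_cells()].
#' @return the cell tibble from [segment_cells()], with the stack's
#'   provenance fields attached.
#' @export
segment_stack <- function(stack, scale = 0.25, min_volume = 0.05,
                          per_plane_threshold = FALSE, ...) {
  resp <- hessian_enhance(stack, scale = scale)
  thr <- otsu_center_quarter(resp, per_plane = per_plane_threshold)
  segment_cells(binarize_stack(resp, thr), stack$voxel_size,
                min_volume = min_volume, intensity = stack$data,
                response = resp$data, split_h = mean(thr),
                stack_meta = stack[c("channel", "time_h", "replicate",
                                     "location")], ...)
}
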