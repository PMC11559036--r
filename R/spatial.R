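#' Estimate the radial center of a nascent fruiting body
#'
#' Peak of a Gaussian-kernel-smoothed 2D cell-count field (deterministic).
#' The peak is located as the centroid of the smoothed field's excess over
#' `top_frac` of its maximum (weights `max(f - top_frac * max(f), 0)`): for
#' a sharply peaked field this coincides with the argmax, while for the
#' flat-topped mounds typical of NFBs it is far more stable than the raw
#' argmax, whose position inside a plateau is sample noise.
#'
#' Accuracy scales with the cell count and the density contrast of the
#' core: with thousands of segmented cells per NFB (the regime of real
#' stacks) localization is sub-micrometer, while on sparse scenes of a few
#' hundred cells the sampling error of any peak estimator is 2-4 um.
#'
#' @param cells cell tibble with columns `x`, `y` (micrometers).
#' @param bandwidth kernel standard deviation, micrometers.
#' @param grid_step evaluation grid spacing, micrometers.
#' @param top_frac fraction of the smoothed maximum above which the field
#'   contributes to the peak centroid.
#' @return named numeric `c(x, y)`.
#' @export
find_center <- function(cells, bandwidth = 5, grid_step = 0.5,
                        top_frac = 0.4) {
  n <- nrow(cells)
  if (is.null(n) || n < 1) stop("no cells: cannot locate a center", call. = FALSE)
  if (n == 1) return(c(x = cells$x[1], y = cells$y[1]))
  pad <- 2 * bandwidth
  lims <- c(range(cells$x) + c(-pad, pad), range(cells$y) + c(-pad, pad))
  np <- c(max(32L, ceiling(diff(lims[1:2]) / grid_step)),
          max(32L, ceiling(diff(lims[3:4]) / grid_step)))
  ## MASS::kde2d uses bandwidth / 4 as the Gaussian sd
  k <- MASS::kde2d(cells$x, cells$y, h = 4 * bandwidth, n = np, lims = lims)
  w <- pmax(k$z - top_frac * max(k$z), 0)
  gx <- matrix(k$x, nrow(w), ncol(w))
  gy <- matrix(k$y, nrow(w), ncol(w), byrow = TRUE)
  c(x = sum(gx * w) / sum(w), y = sum(gy * w) / sum(w))
}

radii_from_center <- function(cells, center) {
  sqrt((cells$x - center[1])^2 + (cells$y - center[2])^2)
}

#' Gaussian-kernel neighbor alignment of rods
#'
#' For rod `i` with neighbor rods `j`, alignment is the weighted average of
#' the cosine of the inter-axis angle,
#' `a_i = sum_j w_ij |cos(theta_ij)| / sum_j w_ij`, with Gaussian weights
#' `w_ij = exp(-d_ij^2 / (2 sigma^2))` on centroid distance and the absolute
#' cosine because cell axes are undirected (1 = perfect alignment, 0 =
#' orthogonal). A rod is not its own neighbor. Weights beyond
#' `truncate * sigma` are dropped (< 1e-3 of the peak at the default, which
#' is numerically immaterial); rods with no neighbor inside the truncation
#' radius get `NA` and the count is reported via attribute `n_excluded`.
#'
#' Non-rod cells carry no meaningful axis and are excluded: if `cells` has a
#' `class` column only rows with `class == "rod"` enter; otherwise all rows
#' are treated as rods.
#'
#' @param cells cell tibble with `x`, `y`, `z` and unit axis columns
#'   `axis_x`, `axis_y`, `axis_z`.
#' @param sigma Gaussian kernel sigma, micrometers (2.5 in the analyses this
#'   package reproduces).
#' @param truncate weight support radius in sigmas (`Inf` to disable).
#' @return a tibble of the rods with an `alignment` column appended;
#'   attribute `n_excluded` counts rods without support.
#' @export
neighbor_alignment <- function(cells, sigma = 2.5, truncate = 4) {
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number (Inf allowed)", call. = FALSE)
  rods <- if ("class" %in% names(cells))
    cells[!is.na(cells$class) & cells$class == "rod", , drop = FALSE]
  else cells
  n <- nrow(rods)
  if (n == 0) {
    rods$alignment <- numeric(0)
    return(structure(rods, n_excluded = 0L))
  }
  p <- cbind(rods$x, rods$y, rods$z)
  a <- cbind(rods$axis_x, rods$axis_y, rods$axis_z)
  a <- a / sqrt(rowSums(a^2))
  d2 <- as.matrix(stats::dist(p))^2
  w <- if (is.finite(sigma)) exp(-d2 / (2 * sigma^2)) else matrix(1, n, n)
  if (is.finite(truncate) && is.finite(sigma))
    w[d2 > (truncate * sigma)^2] <- 0
  diag(w) <- 0
  cosab <- pmin(abs(tcrossprod(a)), 1)
  denom <- rowSums(w)
  align <- ifelse(denom > 0, rowSums(w * cosab) / denom, NA_real_)
  rods$alignment <- unname(align)
  structure(rods, n_excluded = sum(denom <= 0))
}

#' Tangential orientation of rods in a nascent fruiting body
#'
#' The cosine of the angle between a rod's in-plane axis and the local
#' circumferential direction of the NFB: 1 = tangent to the circumference,
#' 0 = radial. The axis is projected to the xy-plane and renormalized; the
#' absolute cosine is used because axes are undirected. Rods exactly at the
#' center (radial direction undefined) or with a near-vertical axis
#' (xy-projection norm < 0.1) are excluded with `NA` and counted in
#' attribute `n_excluded`.
#'
#' @inheritParams neighbor_alignment
#' @param center NFB center `c(x, y)`, micrometers.
#' @return a tibble of the rods with an `orientation` column appended.
#' @export
tangential_orientation <- function(cells, center) {
  rods <- if ("class" %in% names(cells))
    cells[!is.na(cells$class) & cells$class == "rod", , drop = FALSE]
  else cells
  n <- nrow(rods)
  if (n == 0) {
    rods$orientation <- numeric(0)
    return(structure(rods, n_excluded = 0L))
  }
  vx <- rods$x - center[1]
  vy <- rods$y - center[2]
  rr <- sqrt(vx^2 + vy^2)
  axy <- sqrt(rods$axis_x^2 + rods$axis_y^2)
  ok <- rr > 1e-9 & axy >= 0.1
  tangent_x <- -vy / rr
  tangent_y <- vx / rr
  o <- abs(rods$axis_x / axy * tangent_x + rods$axis_y / axy * tangent_y)
  o <- pmin(pmax(o, 0), 1)
  o[!ok] <- NA_real_
  rods$orientation <- o
  structure(rods, n_excluded = sum(!ok))
}

## Bayesian-bootstrap posterior of a pooled per-bin statistic.
## reps: list (one element per replicate) of per-draw statistic vectors
## (n_draws each). Replicates are pooled with Dirichlet(1, ..., 1) weights.
bb_pool <- function(rep_draws, n_draws) {
  present <- !vapply(rep_draws, is.null, logical(1))
  if (!any(present)) return(rep(NA_real_, n_draws))
  m <- do.call(cbind, rep_draws[present])
  w <- rdirichlet_unit(n_draws, ncol(m))
  rowSums(w * m)
}

profile_row <- function(draws, estimate) {
  if (all(is.na(draws)))
    return(c(estimate = estimate, median = NA_real_, lo90 = NA_real_,
             hi90 = NA_real_))
  q <- equal_tailed(draws)
  c(estimate = estimate, median = q[2], lo90 = q[1], hi90 = q[3])
}

#' Radial cell-density profile with labeled-fraction correction
#'
#' Per annular bin about the NFB center, the density of labeled cells per
#' 1,000 um^3 (annulus area times the z extent of the imaged volume),
#' multiplied by the reciprocal of the labeled fraction to estimate all
#' cells: doubled for fraction 1/2, quadrupled for 1/4. Posterior medians
#' and 90% equal-tailed credible bands come from Jeffreys Gamma-Poisson
#' draws on the per-replicate bin counts pooled by Bayesian bootstrap
#' (Dirichlet weights) over replicates.
#'
#' @param cells labeled-cell tibble with `x`, `y` (and optionally
#'   `replicate`; single replicate assumed otherwise). Filter by class or
#'   strain before calling to profile a subset.
#' @param center NFB center `c(x, y)`, micrometers.
#' @param bins ascending bin edges, micrometers (default 0-60 in 3 um bins).
#' @param z_extent imaged z span, micrometers.
#' @param labeled_fraction fraction of cells carrying the label, in (0, 1].
#' @param n_draws posterior draws.
#' @param seed integer seed for the posterior draws.
#' @return tibble: `bin_lo`, `bin_mid`, `bin_hi`, `n_cells` (labeled count),
#'   `estimate` (corrected cells per 1,000 um^3), `median`, `lo90`, `hi90`.
#' @export
radial_density <- function(cells, center, bins = seq(0, 60, by = 3),
                           z_extent = 5, labeled_fraction = 0.5,
                           n_draws = 4000, seed = 1) {
  stopifnot(length(bins) >= 2, !is.unsorted(bins))
  if (labeled_fraction <= 0 || labeled_fraction > 1)
    stop("`labeled_fraction` must be in (0, 1]", call. = FALSE)
  vol <- pi * (bins[-1]^2 - bins[-length(bins)]^2) * z_extent
  if (any(vol <= 0)) stop("zero-volume bin", call. = FALSE)
  r <- radii_from_center(cells, center)
  rep_id <- if ("replicate" %in% names(cells)) cells$replicate
    else rep(1L, nrow(cells))
  rep_id <- as.character(rep_id)
  rep_id[is.na(rep_id)] <- "unreplicated"
  reps <- sort(unique(rep_id))
  nb <- length(bins) - 1L
  counts <- vapply(reps, function(rr) {
    tabulate(findInterval(r[rep_id == rr], bins, rightmost.closed = TRUE,
                          all.inside = FALSE), nbins = nb)
  }, numeric(nb))
  counts <- matrix(counts, nrow = nb)
  corr <- 1 / labeled_fraction
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nb), function(b) {
      rep_draws <- lapply(seq_along(reps), function(j) {
        rgamma(n_draws, shape = counts[b, j] + 0.5, rate = 1) / vol[b] * 1000 * corr
      })
      est <- mean(counts[b, ]) / vol[b] * 1000 * corr
      profile_row(bb_pool(rep_draws, n_draws), est)
    })
  })
  out <- do.call(rbind, rows)
  tibble::tibble(bin_lo = bins[-length(bins)], bin_mid = (bins[-1] + bins[-length(bins)]) / 2,
                 bin_hi = bins[-1], n_cells = rowSums(counts),
                 estimate = out[, "estimate"], median = out[, "median"],
                 lo90 = out[, "lo90"], hi90 = out[, "hi90"])
}

#' Binned radial profile of a per-cell statistic
#'
#' Bins per-cell values (e.g. alignment from [neighbor_alignment()] or
#' orientation from [tangential_orientation()]) by radial distance from the
#' center. The point estimate is the plain bin mean; the posterior median
#' and 90% band come from a two-level Bayesian bootstrap (Dirichlet weights
#' over cells within each replicate, then Dirichlet weights over
#' replicates). `NA` values are dropped.
#'
#' @param cells tibble with `x`, `y`, the `value` column, and optionally
#'   `replicate`.
#' @param value name of the value column.
#' @param center NFB center `c(x, y)`.
#' @inheritParams radial_density
#' @return tibble: `bin_lo`, `bin_mid`, `bin_hi`, `n_cells`, `estimate`,
#'   `median`, `lo90`, `hi90`.
#' @export
radial_profile <- function(cells, value, center, bins = seq(0, 60, by = 3),
                           n_draws = 4000, seed = 1) {
  stopifnot(length(bins) >= 2, !is.unsorted(bins))
  v <- cells[[value]]
  keep <- !is.na(v)
  cells <- cells[keep, , drop = FALSE]
  v <- v[keep]
  r <- radii_from_center(cells, center)
  rep_id <- if ("replicate" %in% names(cells)) cells$replicate
    else rep(1L, nrow(cells))
  rep_id <- as.character(rep_id)
  rep_id[is.na(rep_id)] <- "unreplicated"
  reps <- sort(unique(rep_id))
  nb <- length(bins) - 1L
  bin_of <- findInterval(r, bins, rightmost.closed = TRUE)
  withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(nb), function(b) {
      inb <- bin_of == b
      rep_draws <- lapply(reps, function(rr) {
        vals <- v[inb & rep_id == rr]
        if (length(vals) == 0) return(NULL)
        as.vector(rdirichlet_unit(n_draws, length(vals)) %*% vals)
      })
      est <- if (any(inb)) mean(v[inb]) else NA_real_
      c(profile_row(bb_pool(rep_draws, n_draws), est), n = sum(inb))
    })
  })
  out <- do.call(rbind, rows)
  tibble::tibble(bin_lo = bins[-length(bins)],
                 bin_mid = (bins[-1] + bins[-length(bins)]) / 2,
                 bin_hi = bins[-1], n_cells = as.integer(out[, "n"]),
                 estimate = out[, "estimate"], median = out[, "median"],
                 lo90 = out[, "lo90"], hi90 = out[, "hi90"])
}

#' Radial class-by-strain proportion profiles
#'
#' Per bin, the proportion of each (class, strain) pair relative to the
#' combined total of all classes of both strains in that bin; proportions in
#' a bin sum to 1. Credible bands come from per-replicate Dirichlet
#' (counts + 1/2) posterior draws pooled over replicates by Bayesian
#' bootstrap; an empty bin leaves the band spanning the prior.
#'
#' @param cells classified cell tibble with `x`, `y`, `class`, `strain`, and
#'   optionally `replicate`.
#' @inheritParams radial_density
#' @return tibble: `class`, `strain`, `bin_lo`, `bin_mid`, `bin_hi`,
#'   `n_cells` (pair count), `estimate`, `median`, `lo90`, `hi90`.
#' @export
class_proportions <- function(cells, center, bins = seq(0, 60, by = 3),
                              n_draws = 4000, seed = 1) {
  stopifnot(all(c("class", "strain") %in% names(cells)))
  cells <- cells[!is.na(cells$class), , drop = FALSE]
  r <- radii_from_center(cells, center)
  rep_id <- if ("replicate" %in% names(cells)) cells$replicate
    else rep(1L, nrow(cells))
  rep_id <- as.character(rep_id)
  rep_id[is.na(rep_id)] <- "unreplicated"
  reps <- sort(unique(rep_id))
  nb <- length(bins) - 1L
  bin_of <- findInterval(r, bins, rightmost.closed = TRUE)
  pairs <- expand.grid(class = CLASS_LEVELS, strain = STRAIN_LEVELS,
                       stringsAsFactors = FALSE)
  pair_of <- match(paste(cells$class, cells$strain),
                   paste(pairs$class, pairs$strain))
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (b in seq_len(nb)) {
      cnt <- vapply(seq_along(reps), function(j) {
        tabulate(pair_of[bin_of == b & rep_id == reps[j]], nbins = nrow(pairs))
      }, numeric(nrow(pairs)))
      cnt <- matrix(cnt, nrow = nrow(pairs))
      tot <- colSums(cnt)
      ## per-replicate Dirichlet(counts + 1/2) draws of the proportion vector
      draws <- lapply(seq_along(reps), function(j) {
        g <- matrix(rgamma(n_draws * nrow(pairs), shape = cnt[, j] + 0.5, rate = 1),
                    nrow = nrow(pairs))
        sweep(g, 2, colSums(g), "/")
      })
      w <- rdirichlet_unit(n_draws, length(reps))
      pooled <- Reduce(`+`, lapply(seq_along(reps), function(j) {
        sweep(draws[[j]], 2, w[, j], "*")
      }))
      total_all <- sum(cnt)
      for (pidx in seq_len(nrow(pairs))) {
        q <- equal_tailed(pooled[pidx, ])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          class = pairs$class[pidx], strain = pairs$strain[pidx],
          bin_lo = bins[b], bin_mid = (bins[b] + bins[b + 1]) / 2,
          bin_hi = bins[b + 1], n_cells = sum(cnt[pidx, ]),
          estimate = if (total_all > 0) sum(cnt[pidx, ]) / total_all else NA_real_,
          median = q[2], lo90 = q[1], hi90 = q[3])
      }
    }
  })
  do.call(rbind, rows)
}
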