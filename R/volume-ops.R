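## Vectorized 3D array primitives shared by rendering and segmentation.
## Arrays are (ny, nx, nz); axis indices 1 = y, 2 = x, 3 = z.

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

## Shift along one axis with edge replication.
shift_arr <- function(a, s, along) {
  if (s == 0) return(a)
  n <- dim(a)[along]
  idx <- pmin(pmax(seq_len(n) + s, 1L), n)
  switch(along,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

convolve_axis <- function(a, kernel, along) {
  r <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * shift_arr(a, j - 1L - r, along)
  out
}

## Separable Gaussian smoothing; sigma_vox in voxel units, order (y, x, z).
gauss_smooth_3d <- function(a, sigma_vox) {
  for (ax in 1:3)
    if (sigma_vox[ax] > 0)
      a <- convolve_axis(a, gaussian_kernel_1d(sigma_vox[ax]), ax)
  a
}

## Central second differences in physical units; spacing order (y, x, z).
second_diff <- function(a, ax1, ax2, spacing) {
  if (ax1 == ax2) {
    (shift_arr(a, 1L, ax1) - 2 * a + shift_arr(a, -1L, ax1)) / spacing[ax1]^2
  } else {
    (shift_arr(shift_arr(a, 1L, ax1), 1L, ax2) -
     shift_arr(shift_arr(a, 1L, ax1), -1L, ax2) -
     shift_arr(shift_arr(a, -1L, ax1), 1L, ax2) +
     shift_arr(shift_arr(a, -1L, ax1), -1L, ax2)) /
      (4 * spacing[ax1] * spacing[ax2])
  }
}

## Smallest eigenvalue of a field of symmetric 3x3 matrices (closed-form
## trigonometric solution), vectorized over voxels.
eig_min_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  scale <- pmax(abs(a11), abs(a22), abs(a33), abs(a12), abs(a13), abs(a23), 1e-300)
  degenerate <- p < 1e-12 * scale
  psafe <- ifelse(degenerate, 1, p)
  b11 <- (a11 - q) / psafe; b22 <- (a22 - q) / psafe; b33 <- (a33 - q) / psafe
  b12 <- a12 / psafe; b13 <- a13 / psafe; b23 <- a23 / psafe
  detb <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  lam_min <- q + 2 * p * cos(phi + 2 * pi / 3)
  ifelse(degenerate, q, lam_min)
}
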