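test_that("alignment endpoints: parallel rods score 1, orthogonal rods 0", {
  par <- rod_frame(rbind(c(0, 0, 0), c(0, 1, 0)),
                   rbind(c(1, 0, 0), c(1, 0, 0)))
  a <- neighbor_alignment(par, sigma = 2.5)
  expect_equal(a$alignment, c(1, 1))
  ort <- rod_frame(rbind(c(0, 0, 0), c(0, 1, 0)),
                   rbind(c(1, 0, 0), c(0, 1, 0)))
  a2 <- neighbor_alignment(ort, sigma = 2.5)
  expect_equal(a2$alignment, c(0, 0))
})

test_that("a rod between a parallel and an orthogonal neighbor scores 1/2", {
  fr <- rod_frame(rbind(c(0, 0, 0), c(2.5, 0, 0), c(0, 2.5, 0)),
                  rbind(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0)))
  a <- neighbor_alignment(fr, sigma = 2.5)
  expect_equal(a$alignment[1], 0.5)  # equal weights at equal distance
})

test_that("infinite sigma reduces to the unweighted mean absolute cosine", {
  withr::with_seed(19, {
    n <- 25
    xyz <- matrix(runif(3 * n, 0, 30), ncol = 3)
    axes <- matrix(rnorm(3 * n), ncol = 3)
  })
  fr <- rod_frame(xyz, axes)
  a <- neighbor_alignment(fr, sigma = Inf)
  axes_u <- axes / sqrt(rowSums(axes^2))
  manual <- vapply(seq_len(n), function(i) {
    mean(abs(axes_u[-i, , drop = FALSE] %*% axes_u[i, ]))
  }, numeric(1))
  expect_equal(a$alignment, manual, tolerance = 1e-12)
})

test_that("alignment and orientation are invariant to rotation, flips, shifts", {
  withr::with_seed(27, {
    n <- 30
    xyz <- cbind(runif(n, 10, 50), runif(n, 10, 50), runif(n, 0, 5))
    axes <- matrix(rnorm(3 * n), ncol = 3)
    flip <- sample(c(-1, 1), n, replace = TRUE)
  })
  center <- c(30, 30)
  fr <- rod_frame(xyz, axes)
  a0 <- neighbor_alignment(fr, sigma = 2.5)$alignment
  o0 <- tangential_orientation(fr, center)$orientation
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy_r <- sweep(xyz[, 1:2], 2, center) %*% t(R)
  xyz_r <- cbind(sweep(xy_r, 2, center + c(12, -7), "+"), xyz[, 3])
  axes_r <- cbind(axes[, 1:2] %*% t(R), axes[, 3]) * flip
  fr_r <- rod_frame(xyz_r, axes_r)
  expect_equal(neighbor_alignment(fr_r, sigma = 2.5)$alignment, a0,
               tolerance = 1e-9)
  expect_equal(tangential_orientation(fr_r, center + c(12, -7))$orientation,
               o0, tolerance = 1e-9)
})

test_that("rods without kernel support are excluded with a logged count", {
  fr <- rod_frame(rbind(c(0, 0, 0), c(100, 0, 0)),
                  rbind(c(1, 0, 0), c(1, 0, 0)))
  a <- neighbor_alignment(fr, sigma = 2.5, truncate = 4)
  expect_true(all(is.na(a$alignment)))
  expect_identical(attr(a, "n_excluded"), 2L)
})

test_that("orientation endpoints and exclusions follow the definition", {
  tang <- rod_frame(matrix(c(10, 0, 0), 1), matrix(c(0, 1, 0), 1))
  expect_equal(tangential_orientation(tang, c(0, 0))$orientation, 1)
  rad <- rod_frame(matrix(c(10, 0, 0), 1), matrix(c(1, 0, 0), 1))
  expect_equal(tangential_orientation(rad, c(0, 0))$orientation, 0)
  ## 60 degrees from the tangent, in plane: cos 60 = 0.5
  deg60 <- rod_frame(matrix(c(10, 0, 0), 1),
                     matrix(c(sin(pi / 3), cos(pi / 3), 0), 1))
  expect_equal(tangential_orientation(deg60, c(0, 0))$orientation, 0.5,
               tolerance = 1e-12)
  excl <- rod_frame(rbind(c(0, 0, 0), c(5, 0, 0)),
                    rbind(c(1, 0, 0), c(0.05, 0, 1)))
  o <- tangential_orientation(excl, c(0, 0))
  expect_true(all(is.na(o$orientation)))  # at center; near-vertical
  expect_identical(attr(o, "n_excluded"), 2L)
})

test_that("density obeys the doubling and quadrupling correction rules", {
  ## annulus 4-8 um with z extent 5: volume = pi * (64 - 16) * 5 = 753.98;
  ## rescale z extent so the annulus volume is exactly 1,000 um^3
  z_ext <- 1000 / (pi * (8^2 - 4^2))
  cells <- tibble::tibble(x = rep(6, 10), y = 0, z = 0)
  d2 <- radial_density(cells, c(0, 0), bins = c(0, 4, 8), z_extent = z_ext,
                       labeled_fraction = 0.5)
  expect_equal(d2$estimate[2], 20)
  d4 <- radial_density(cells, c(0, 0), bins = c(0, 4, 8), z_extent = z_ext,
                       labeled_fraction = 0.25)
  expect_equal(d4$estimate[2], 40)
  expect_equal(d2$estimate[1], 0)
  expect_true(all(d2$lo90 <= d2$median & d2$median <= d2$hi90))
})

test_that("summed density times bin volume recovers the labeled count", {
  withr::with_seed(33, {
    cells <- tibble::tibble(x = runif(200, 0, 40), y = runif(200, 0, 40),
                            z = runif(200, 0, 5))
  })
  center <- c(20, 20)
  bins <- seq(0, 30, by = 3)
  prof <- radial_density(cells, center, bins = bins, z_extent = 5,
                         labeled_fraction = 0.5)
  vol <- pi * (bins[-1]^2 - bins[-length(bins)]^2) * 5
  recovered <- sum(prof$estimate * vol / 1000 * 0.5)
  r <- sqrt((cells$x - 20)^2 + (cells$y - 20)^2)
  expect_equal(recovered, sum(r <= 30))
})

test_that("class proportions are relative to all classes of both strains", {
  cells <- tibble::tibble(
    x = c(5, 5.2, 5.4, 5.6), y = 0, z = 0,
    class = c("rod", "rod", "rod", "spore"),
    strain = c("WT", "WT", "WT", "csgA"))
  pr <- class_proportions(cells, c(0, 0), bins = c(0, 10))
  est <- function(cl, s) pr$estimate[pr$class == cl & pr$strain == s]
  expect_equal(est("rod", "WT"), 0.75)
  expect_equal(est("spore", "csgA"), 0.25)
  expect_equal(sum(pr$estimate), 1)
  ## single class, single strain: proportion 1, everything else 0
  solo <- tibble::tibble(x = 5, y = 0, z = 0, class = "spore", strain = "WT")
  pr2 <- class_proportions(solo, c(0, 0), bins = c(0, 10))
  expect_equal(pr2$estimate[pr2$class == "spore" & pr2$strain == "WT"], 1)
  expect_equal(sum(pr2$estimate), 1)
})

test_that("an empty bin leaves the proportion band spanning the prior", {
  cells <- tibble::tibble(x = 25, y = 0, z = 0, class = "rod", strain = "WT")
  pr <- class_proportions(cells, c(0, 0), bins = c(0, 10, 20, 30), seed = 4)
  empty <- pr[pr$bin_lo == 0 & pr$class == "rod" & pr$strain == "WT", ]
  expect_true(is.na(empty$estimate))
  expect_gt(empty$hi90 - empty$lo90, 0.3)  # wide: prior-dominated
})

test_that("the center estimator hits symmetric, single, and synthetic cases", {
  sym <- tibble::tibble(
    x = 50 + c(-5, 5, 0, 0, -3, 3, -1, 1), y = 50 + c(0, 0, -5, 5, 3, -3, 0, 0))
  expect_equal(unname(find_center(sym)), c(50, 50), tolerance = 1)
  one <- tibble::tibble(x = 12.3, y = 45.6)
  expect_equal(unname(find_center(one)), c(12.3, 45.6))
  expect_error(find_center(tibble::tibble(x = numeric(), y = numeric())),
               "no cells")
  ## dense NFB-like fixture: localization error at a few hundred labeled
  ## cells is sampling-limited at a few micrometers (sub-micrometer accuracy
  ## needs the thousands of cells of real stacks)
  for (s in c(41, 44)) {
    cfg <- scene_config(density = list(r = c(0, 10, 20, 60),
                                       value = c(45, 20, 5, 5)),
                        n_cells = 1000, seed = s)
    sc <- generate_scene(cfg, render = FALSE)
    ctr <- find_center(sc$cells[sc$cells$labeled, ])
    expect_lt(sqrt(sum((ctr - cfg$center)^2)), 5)
  }
})

test_that("profile values respect their declared ranges on synthetic scenes", {
  sc <- generate_scene(small_scene_config(seed = 55), render = FALSE)
  cells <- sc$cells
  center <- sc$config$center
  al <- neighbor_alignment(cells, sigma = 2.5)
  expect_true(all(al$alignment >= 0 & al$alignment <= 1, na.rm = TRUE))
  o <- tangential_orientation(cells, center)
  expect_true(all(o$orientation >= 0 & o$orientation <= 1, na.rm = TRUE))
  dens <- radial_density(cells[cells$labeled, ], center,
                         bins = seq(0, 15, 3), labeled_fraction = 0.5)
  expect_true(all(dens$estimate >= 0))
  expect_true(all(dens$lo90 <= dens$median & dens$median <= dens$hi90))
  pr <- class_proportions(cells, center, bins = seq(0, 15, 5))
  sums <- tapply(pr$estimate, pr$bin_lo, sum)
  expect_true(all(abs(sums - 1) < 1e-9, na.rm = TRUE))
})
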