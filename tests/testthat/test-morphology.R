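# Build a morphology model by hand (no fitting) for analytic posterior checks.
manual_model <- function(means, covs, weights, classes) {
  structure(list(means = means, covariances = covs, weights = weights,
                 classes = classes, features = rownames(means),
                 loglik = NA_real_, n = 0L, k = length(classes), seed = 0L),
            class = "morphology_model")
}

test_that("a rendered sphere has near-unit elongation", {
  st <- render_poses(pose(8, 8, 2, length_um = 1.5, width_um = 1.5),
                     field = c(16, 16, 4))
  cells <- segment_cells(st$data > 30, st$voxel_size)
  expect_identical(nrow(cells), 1L)
  expect_gte(cells$elongation, 1.0)
  expect_lte(cells$elongation, 1.2)
})

test_that("a rendered 5 x 0.5 um spherocylinder is strongly elongated", {
  st <- render_poses(pose(8, 8, 2, ax = c(1, 0.3, 0), length_um = 5,
                          width_um = 0.5), field = c(16, 16, 4))
  cells <- segment_cells(st$data > 30, st$voxel_size)
  expect_identical(nrow(cells), 1L)
  expect_gt(cells$elongation, 4)
})

test_that("features are stable to within 5% under 2x finer voxel pitch", {
  ## a spore-sized sphere: several voxels across, so voxel-counting volume
  ## has converged (a 2-voxel-wide rod's volume is still pitch-limited)
  feats <- c("log_volume", "elongation", "planarity")
  sp <- pose(8, 8, 2, length_um = 1.5, width_um = 1.5)
  fc <- extract_features(segment_cells(
    render_poses(sp, field = c(16, 16, 4), voxel = rep(0.25, 3))$data > 30,
    rep(0.25, 3)), feats)
  ff <- extract_features(segment_cells(
    render_poses(sp, field = c(16, 16, 4), voxel = rep(0.125, 3))$data > 30,
    rep(0.125, 3)), feats)
  expect_equal(exp(fc[1, "log_volume"]), exp(ff[1, "log_volume"]),
               tolerance = 0.05 * exp(fc[1, "log_volume"]))
  expect_equal(fc[1, "elongation"], ff[1, "elongation"],
               tolerance = 0.05 * fc[1, "elongation"])
  ## elongation of a rod is likewise pitch-stable
  p <- pose(8, 8, 2, ax = c(1, 1, 0), length_um = 4, width_um = 0.5)
  ec <- extract_features(segment_cells(
    render_poses(p, field = c(16, 16, 4), voxel = rep(0.25, 3))$data > 30,
    rep(0.25, 3)), feats)
  ef <- extract_features(segment_cells(
    render_poses(p, field = c(16, 16, 4), voxel = rep(0.125, 3))$data > 30,
    rep(0.125, 3)), feats)
  expect_equal(ec[1, "elongation"], ef[1, "elongation"],
               tolerance = 0.05 * ec[1, "elongation"])
})

sim_clusters <- function(n_per = 200, seed = 14) {
  ## well-separated classes in (log_volume, elongation, planarity):
  ## between-mean distances >= 6 within-cluster SDs
  withr::with_seed(seed, {
    mk <- function(mu, sd) cbind(rnorm(n_per, mu[1], sd), rnorm(n_per, mu[2], sd),
                                 rnorm(n_per, mu[3], sd))
    x <- rbind(mk(c(0.5, 9, 1.3), 0.3), mk(c(-0.2, 3, 1.5), 0.3),
               mk(c(0.1, 1.1, 1.05), 0.3))
  })
  colnames(x) <- c("log_volume", "elongation", "planarity")
  list(x = x, labels = rep(c("rod", "transitioning", "spore"), each = n_per),
       means = rbind(c(0.5, 9, 1.3), c(-0.2, 3, 1.5), c(0.1, 1.1, 1.05)),
       sd = 0.3)
}

test_that("the mixture recovers well-separated clusters almost perfectly", {
  cl <- sim_clusters()
  model <- fit_morphology_model(cl$x, k = 3, seed = 1)
  ## recovered means within 0.5 within-cluster SD of the truth
  for (i in 1:3) {
    cls <- c("rod", "transitioning", "spore")[i]
    j <- which(model$classes == cls)
    expect_lt(sqrt(sum((model$means[, j] - cl$means[i, ])^2)), 0.5 * cl$sd * 3)
  }
  cells <- tibble::as_tibble(as.data.frame(cl$x))
  cells$volume_um3 <- exp(cl$x[, "log_volume"])
  pred <- classify_cells(cells, model)
  expect_gte(mean(pred$class == cl$labels), 0.99)
})

test_that("k = 1 reduces to the sample mean and MLE covariance", {
  withr::with_seed(2, x <- matrix(rnorm(240), ncol = 3))
  colnames(x) <- c("log_volume", "elongation", "planarity")
  model <- fit_morphology_model(x, k = 1, seed = 1)
  expect_equal(as.vector(model$means), colMeans(x), tolerance = 1e-8,
               ignore_attr = TRUE)
  n <- nrow(x)
  expect_equal(unname(model$covariances[[1]]), unname(cov(x) * (n - 1) / n),
               tolerance = 1e-6)
})

test_that("duplicating every observation leaves the fit unchanged", {
  cl <- sim_clusters(n_per = 80)
  m1 <- fit_morphology_model(cl$x, k = 3, seed = 1)
  m2 <- fit_morphology_model(rbind(cl$x, cl$x), k = 3, seed = 1)
  expect_equal(m1$means, m2$means, tolerance = 1e-3)
  expect_equal(m1$weights, m2$weights, tolerance = 1e-3)
})

test_that("fitting needs enough cells and finite features", {
  x <- sim_clusters(n_per = 5)$x  # 15 < 10 * k
  expect_error(fit_morphology_model(x, k = 3), "at least 30")
  x2 <- sim_clusters()$x
  x2[1, 1] <- Inf
  expect_error(fit_morphology_model(x2, k = 3), "finite")
})

test_that("posterior rows sum to one and component means give confident calls", {
  cl <- sim_clusters()
  model <- fit_morphology_model(cl$x, k = 3, seed = 1)
  at_means <- tibble::tibble(
    volume_um3 = exp(model$means["log_volume", ]),
    elongation = model$means["elongation", ],
    planarity = model$means["planarity", ])
  pred <- classify_cells(at_means, model)
  post <- as.matrix(pred[, c("p_rod", "p_transitioning", "p_spore")])
  expect_equal(rowSums(post), rep(1, 3), tolerance = 1e-9)
  expect_identical(pred$class, model$classes)  # row j sits at component j's mean
  expect_true(all(apply(post, 1, max) > 0.9))
})

test_that("an exactly ambiguous cell ties 50/50 and breaks toward rod", {
  d <- 3
  mu <- matrix(c(0, 0, 0, 4, 0, 0, 100, 100, 100), nrow = d)
  rownames(mu) <- c("log_volume", "elongation", "planarity")
  covs <- replicate(3, diag(d), simplify = FALSE)
  model <- manual_model(mu, covs, weights = c(0.45, 0.45, 0.10),
                        classes = c("rod", "transitioning", "spore"))
  midpoint <- tibble::tibble(volume_um3 = exp(2), elongation = 0, planarity = 0)
  pred <- classify_cells(midpoint, model)
  expect_equal(pred$p_rod, 0.5, tolerance = 1e-9)
  expect_equal(pred$p_transitioning, 0.5, tolerance = 1e-9)
  expect_identical(pred$class, "rod")
})

test_that("refits with different seeds agree after class mapping", {
  cl <- sim_clusters()
  m1 <- fit_morphology_model(cl$x, k = 3, seed = 1)
  m2 <- fit_morphology_model(cl$x, k = 3, seed = 999)
  cells <- tibble::tibble(volume_um3 = exp(cl$x[, 1]),
                          elongation = cl$x[, 2], planarity = cl$x[, 3])
  expect_identical(classify_cells(cells, m1)$class,
                   classify_cells(cells, m2)$class)
  el <- function(m) m$means["elongation", match(c("rod", "transitioning",
                                                  "spore"), m$classes)]
  expect_true(all(diff(el(m1)) < 0))  # rod > transitioning > spore, always
})

test_that("cells with non-finite features are flagged, not classified", {
  cl <- sim_clusters()
  model <- fit_morphology_model(cl$x, k = 3, seed = 1)
  cells <- tibble::tibble(volume_um3 = c(exp(0.5), 0), elongation = c(9, 2),
                          planarity = c(1.3, 1.5))  # volume 0 -> -Inf log
  expect_message(pred <- classify_cells(cells, model), "unclassified")
  expect_identical(pred$class[2], NA_character_)
  expect_false(is.na(pred$class[1]))
})

test_that("the model serializes to JSON and back without loss", {
  cl <- sim_clusters()
  model <- fit_morphology_model(cl$x, k = 3, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_morphology_model(model, path)
  back <- read_morphology_model(path)
  expect_equal(back$means, model$means, tolerance = 1e-12)
  expect_equal(back$covariances, model$covariances, tolerance = 1e-12)
  expect_identical(back$classes, model$classes)
  cells <- tibble::tibble(volume_um3 = exp(cl$x[, 1]),
                          elongation = cl$x[, 2], planarity = cl$x[, 3])
  expect_identical(classify_cells(cells, model)$class,
                   classify_cells(cells, back)$class)
})
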