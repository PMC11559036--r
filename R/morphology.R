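#' Shape features for morphology classification
#'
#' Default feature space: log volume, log elongation (major/minor extent),
#' and planarity (mid/minor extent). Elongation enters on the log scale
#' because the rod class's linear elongations are strongly right-skewed
#' (ratios of lengths to widths), which tempts a Gaussian mixture into
#' splitting the rod cluster instead of separating transitioning cells from
#' spores; the log is near-symmetric per class. Cells flagged degenerate by
#' the segmenter already carry regularized moments, so their features are
#' finite.
#'
#' @param cells cell tibble from [segment_cells()].
#' @param features character vector of feature names; each must be
#'   `"log_volume"`, `"elongation"`, `"log_elongation"`, `"planarity"`, or a
#'   column of `cells`.
#' @return a numeric matrix, one row per cell, with column names.
#' @export
extract_features <- function(cells,
                             features = c("log_volume", "log_elongation",
                                          "planarity")) {
  cols <- lapply(features, function(f) {
    switch(f,
           log_volume = log(cells$volume_um3),
           elongation = cells$elongation,
           log_elongation = log(cells$elongation),
           planarity = cells$planarity,
           if (f %in% names(cells)) cells[[f]]
           else stop("unknown feature: ", f, call. = FALSE))
  })
  m <- do.call(cbind, cols)
  colnames(m) <- features
  m
}

#' Fit the three-class Gaussian mixture morphology model
#'
#' Fits a `k`-component full-covariance Gaussian mixture to the feature
#' matrix via EM (`mclust` machinery) and, for `k = 3`, maps components to
#' classes by descending mean elongation: rod > transitioning > spore. A fit
#' in which two components tie on mean elongation is an error, never a
#' silent relabeling.
#'
#' For `k = 3` the EM is seeded from a morphology-informed partition
#' (elongation cut points at the spore and rod class boundaries, 1.35 and
#' 2.5) rather than agglomerative or random starts: unsupervised
#' maximum-likelihood selection reliably prefers splitting the broad rod
#' cluster over separating the small transitioning-cell class, and the
#' informed start keeps EM in the biologically meaningful optimum while
#' remaining fully deterministic.
#'
#' @param x feature matrix from [extract_features()] (an `elongation` or
#'   `log_elongation` column is required when `k = 3`).
#' @param k number of mixture components (3 = rod / transitioning / spore).
#' @param seed recorded in the model metadata (and applied around the fit).
#' @return a `morphology_model`: per-component `means` (features x k),
#'   `covariances` (list), `weights`, `classes` (component -> class),
#'   `features`, `loglik`, `n`, `seed`.
#' @export
fit_morphology_model <- function(x, k = 3, seed = 1) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  if (nrow(x) < 10 * k)
    stop("need at least ", 10 * k, " cells to fit ", k, " components",
         call. = FALSE)
  ctrl <- mclust::emControl(tol = c(1e-8, 1e-8))
  efeat <- intersect(c("elongation", "log_elongation"), colnames(x))
  fit <- withr::with_seed(as.integer(seed), {
    if (k == 3 && length(efeat) > 0) {
      el <- x[, efeat[1]]
      cuts <- if (efeat[1] == "log_elongation") log(c(1.35, 2.5)) else
        c(1.35, 2.5)
      grp <- 1L + findInterval(el, cuts)  # 1 spore-like, 2 TC-like, 3 rod-like
      if (length(unique(grp)) < 3)
        grp <- 1L + findInterval(el, stats::quantile(el, c(1, 2) / 3),
                                 all.inside = TRUE)
      z0 <- mclust::unmap(grp)
      f <- tryCatch(mclust::meVVV(data = x, z = z0, control = ctrl),
                    error = function(e) NULL)
      if (is.null(f) || !is.finite(f$loglik)) {
        ## sparse classes make an unregularized covariance singular; refit
        ## with the conjugate (regularizing) prior
        f <- tryCatch(mclust::meVVV(data = x, z = z0, control = ctrl,
                                    prior = mclust::priorControl()),
                      error = function(e) NULL)
      }
      f
    } else {
      mn <- if (k > 1) "VVV" else "XXX"
      tryCatch(mclust::Mclust(x, G = k, modelNames = mn, control = ctrl,
                              verbose = FALSE),
               error = function(e) NULL)
    }
  })
  if (is.null(fit) || is.null(fit$parameters) || !is.finite(fit$loglik))
    stop("mixture fit failed to converge; add cells or rescale features",
         call. = FALSE)
  mu <- fit$parameters$mean
  if (is.null(dim(mu))) mu <- matrix(mu, ncol = k)
  rownames(mu) <- colnames(x)
  sig <- fit$parameters$variance$sigma
  if (is.null(sig)) {
    sig <- array(fit$parameters$variance$Sigma, dim = c(ncol(x), ncol(x), 1))
  }
  covs <- lapply(seq_len(k), function(j) {
    s <- sig[, , j]
    dimnames(s) <- list(colnames(x), colnames(x))
    s
  })
  w <- fit$parameters$pro %||% 1
  classes <- paste0("component_", seq_len(k))
  if (k == 3) {
    efeat <- intersect(c("elongation", "log_elongation"), rownames(mu))
    if (length(efeat) == 0)
      stop("k = 3 class mapping requires an `elongation` or ",
           "`log_elongation` feature", call. = FALSE)
    el <- mu[efeat[1], ]
    if (anyDuplicated(el) || any(!is.finite(el)))
      stop("cannot map components to classes: mean elongations are tied or ",
           "non-finite; refit with different features", call. = FALSE)
    classes[order(el, decreasing = TRUE)] <- CLASS_LEVELS
  }
  structure(list(means = mu, covariances = covs, weights = w,
                 classes = classes, features = colnames(x),
                 loglik = fit$loglik, n = nrow(x), k = k,
                 seed = as.integer(seed)),
            class = "morphology_model")
}

#' @export
print.morphology_model <- function(x, ...) {
  cat(sprintf("<morphology_model> k = %d, n = %d, logLik = %.2f\n",
              x$k, x$n, x$loglik))
  cat("components:", paste(sprintf("%s (w = %.2f)", x$classes, x$weights),
                           collapse = ", "), "\n")
  invisible(x)
}

log_dmvnorm <- function(x, mu, sigma) {
  ch <- chol(sigma)
  d <- length(mu)
  z <- backsolve(ch, t(x) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - d / 2 * log(2 * pi)
}

#' Classify cells with a fitted morphology model
#'
#' Each cell is assigned the argmax-posterior class; full class posteriors
#' are attached as `p_<class>` columns. Exact posterior ties break by the
#' fixed class order rod < transitioning < spore. Cells with non-finite
#' features are flagged unclassified (`class` = `NA`) and their count
#' reported via a message.
#'
#' @param cells cell tibble from [segment_cells()].
#' @param model a [fit_morphology_model()] result.
#' @return `cells` with columns `class`, `p_rod`, `p_transitioning`,
#'   `p_spore` added (for `k = 3`; generic component names otherwise).
#' @export
classify_cells <- function(cells, model) {
  stopifnot(inherits(model, "morphology_model"))
  x <- extract_features(cells, model$features)
  ok <- apply(is.finite(x), 1, all)
  lp <- matrix(-Inf, nrow(x), model$k)
  for (j in seq_len(model$k))
    lp[ok, j] <- log(model$weights[j]) +
      log_dmvnorm(x[ok, , drop = FALSE], model$means[, j],
                  model$covariances[[j]])
  ord <- order(match(model$classes, CLASS_LEVELS))
  lp <- lp[, ord, drop = FALSE]
  cls <- model$classes[ord]
  post <- matrix(NA_real_, nrow(x), model$k)
  label <- rep(NA_character_, nrow(x))
  if (any(ok)) {
    lpo <- lp[ok, , drop = FALSE]
    e <- exp(lpo - apply(lpo, 1, max))
    post[ok, ] <- e / rowSums(e)
    label[ok] <- cls[apply(post[ok, , drop = FALSE], 1, which.max)]
  }
  if (any(!ok))
    message(sum(!ok), " cell(s) with non-finite features left unclassified")
  cells$class <- label
  for (j in seq_along(cls)) cells[[paste0("p_", cls[j])]] <- post[, j]
  cells
}

#' Serialize / restore a morphology model as JSON
#'
#' @param model a `morphology_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored model (read).
#' @export
write_morphology_model <- function(model, path) {
  stopifnot(inherits(model, "morphology_model"))
  doc <- list(schema = "mxnfb-morphology-model/1",
              features = model$features, k = model$k,
              classes = model$classes, weights = model$weights,
              means = lapply(seq_len(model$k), function(j) model$means[, j]),
              covariances = lapply(model$covariances, as.vector),
              loglik = model$loglik, n = model$n, seed = model$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_morphology_model
#' @export
read_morphology_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "mxnfb-morphology-model/1"))
    stop("not a morphology model file: ", path, call. = FALSE)
  d <- length(doc$features)
  mu <- if (is.matrix(doc$means)) t(doc$means)  # simplified: rows = components
        else matrix(unlist(doc$means), nrow = d, ncol = doc$k)
  rownames(mu) <- doc$features
  cov_rows <- if (is.matrix(doc$covariances))
    lapply(seq_len(doc$k), function(j) doc$covariances[j, ])
  else doc$covariances
  covs <- lapply(cov_rows, function(v) {
    s <- matrix(unlist(v), d, d)
    dimnames(s) <- list(doc$features, doc$features)
    s
  })
  structure(list(means = mu, covariances = covs, weights = doc$weights,
                 classes = doc$classes, features = doc$features,
                 loglik = doc$loglik, n = doc$n, k = doc$k, seed = doc$seed),
            class = "morphology_model")
}
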