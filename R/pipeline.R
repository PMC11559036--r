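#' Assemble and validate a pipeline run configuration
#'
#' A run analyses one experiment: several biological replicates imaged at
#' several times poststarvation, either synthetic (scenes generated on the
#' fly with known ground truth) or from TIFF stacks on disk. All analysis
#' parameters default to the values of the study design this package
#' emulates: alignment kernel sigma 2.5 um, analysis radius 60 um, radial
#' bins of 3 um from 0 to 60, z extent 5 um, density correction from the
#' labeled fraction.
#'
#' @param seed master seed; every stage derives its own seed from it.
#' @param scene list of arguments for [scene_config()] shared by all frames
#'   (per-frame seeds are derived); `NULL` when `inputs` is given.
#' @param replicates number of biological replicates (synthetic mode).
#' @param times time points in hours poststarvation (synthetic mode).
#' @param class_mix_by_time optional named list (names = times) of class-mix
#'   vectors, letting spores accumulate over the series.
#' @param inputs instead of `scene`: a list of frames, each a list with
#'   `green`, `red` (TIFF paths), `replicate`, `time_h`, and optionally
#'   `voxel_size`, `location`.
#' @param initial_ratio initial csgA/WT mix ratio.
#' @param labeled_fraction labeled fraction (density correction is its
#'   reciprocal).
#' @param sigma alignment kernel sigma, micrometers.
#' @param radius analysis radius, micrometers.
#' @param bins radial bin edges, micrometers.
#' @param z_extent imaged z span, micrometers.
#' @param scale Hessian smoothing scale, micrometers.
#' @param min_volume segmentation minimum volume, cubic micrometers.
#' @param n_draws posterior draws for all estimates.
#' @return a validated `run_config`.
#' @export
run_config <- function(seed = 1, scene = list(), replicates = 2,
                       times = c(30, 42), class_mix_by_time = NULL,
                       inputs = NULL, initial_ratio = 1,
                       labeled_fraction = 0.5, sigma = 2.5, radius = 60,
                       bins = seq(0, 60, by = 3), z_extent = 5,
                       scale = 0.25, min_volume = 0.05, n_draws = 4000) {
  cfg <- structure(as.list(environment()), class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (!is.null(cfg$inputs)) {
    for (fr in cfg$inputs) {
      for (ch in c("green", "red")) {
        path <- fr[[ch]]
        if (is.null(path) || !file.exists(path))
          stop("input stack missing on disk: ", path %||% paste0("<no ", ch, ">"),
               call. = FALSE)
        if (is.null(fr$voxel_size) && !file.exists(paste0(path, ".json")))
          stop("voxel size unavailable for ", path,
               ": no sidecar and no `voxel_size` override", call. = FALSE)
      }
      if (is.null(fr$replicate) || is.null(fr$time_h))
        stop("every input frame needs `replicate` and `time_h`", call. = FALSE)
    }
  } else {
    if (length(cfg$times) < 1) stop("no time points", call. = FALSE)
    if (cfg$replicates < 1) stop("need >= 1 replicate", call. = FALSE)
  }
  if (cfg$labeled_fraction <= 0 || cfg$labeled_fraction > 1)
    stop("`labeled_fraction` must be in (0, 1]", call. = FALSE)
  stopifnot(cfg$sigma > 0, cfg$radius > 0, !is.unsorted(cfg$bins))
  invisible(cfg)
}

pipeline_frames <- function(cfg) {
  if (!is.null(cfg$inputs)) return(cfg$inputs)
  frames <- list()
  for (r in seq_len(cfg$replicates)) for (t in cfg$times) {
    frames[[length(frames) + 1L]] <- list(replicate = r, time_h = t)
  }
  frames
}

frame_stacks <- function(cfg, frame, frame_idx) {
  if (!is.null(cfg$inputs)) {
    lapply(c(green = "green", red = "red"), function(ch)
      read_stack(frame[[ch]], voxel_size = frame$voxel_size, channel = ch,
                 time_h = frame$time_h, replicate = frame$replicate,
                 location = frame$location %||% NA_character_))
  } else {
    args <- cfg$scene
    args$labeled_fraction <- args$labeled_fraction %||% cfg$labeled_fraction
    if (!is.null(cfg$class_mix_by_time)) {
      mix <- cfg$class_mix_by_time[[as.character(frame$time_h)]]
      if (!is.null(mix)) args$class_mix <- mix
    }
    args$seed <- derive_seed(cfg$seed, frame_idx)
    sc <- generate_scene(do.call(scene_config, args))
    for (ch in names(sc$stacks)) {
      sc$stacks[[ch]]$time_h <- frame$time_h
      sc$stacks[[ch]]$replicate <- frame$replicate
      sc$stacks[[ch]]$location <- "NFB"
    }
    sc$stacks
  }
}

#' Run the full analysis pipeline
#'
#' Stages run in order — segment, classify, profiles, counts, infer — and
#' communicate only through the documented file schemas in `out_dir`, so a
#' rerun with the same configuration and master seed reproduces
#' byte-identical outputs. Any stage failure aborts with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty `out_dir`.
#' @return `out_dir`, invisibly; see `manifest.json` there for the file
#'   inventory, checksums, seeds, and parameters used.
#' @export
run_pipeline <- function(cfg, out_dir, force = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  validate_run_config(cfg)
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir,
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  paths <- list(cells = file.path(out_dir, "cells.csv"),
                model = file.path(out_dir, "model.json"),
                classified = file.path(out_dir, "cells_classified.csv"),
                centers = file.path(out_dir, "centers.csv"),
                profiles = file.path(out_dir, "profiles.csv"),
                counts = file.path(out_dir, "counts.csv"),
                estimates = file.path(out_dir, "estimates.csv"),
                summary = file.path(out_dir, "summary.json"))

  stage("segment", {
    frames <- pipeline_frames(cfg)
    all_cells <- list()
    for (i in seq_along(frames)) {
      stacks <- frame_stacks(cfg, frames[[i]], i)
      for (ch in c("green", "red")) {
        cells <- segment_stack(stacks[[ch]], scale = cfg$scale,
                               min_volume = cfg$min_volume)
        cells$strain <- if (ch == "green") "WT" else "csgA"
        all_cells[[length(all_cells) + 1L]] <- cells
      }
    }
    write_table(do.call(rbind, all_cells), paths$cells, "cells")
  })

  stage("classify", {
    cells <- read_table(paths$cells, "cells")
    model <- fit_morphology_model(extract_features(cells), k = 3,
                                  seed = derive_seed(cfg$seed, 9001))
    write_morphology_model(model, paths$model)
    write_table(classify_cells(cells, read_morphology_model(paths$model)),
                paths$classified, "cells")
  })

  stage("profiles", {
    cells <- read_table(paths$classified, "cells")
    frames <- unique(cells[, c("replicate", "time_h")])
    centers <- do.call(rbind, lapply(seq_len(nrow(frames)), function(i) {
      sub <- cells[cells$replicate == frames$replicate[i] &
                   cells$time_h == frames$time_h[i], ]
      ctr <- find_center(sub)
      tibble::tibble(replicate = frames$replicate[i],
                     time_h = frames$time_h[i], x = ctr["x"], y = ctr["y"])
    }))
    utils::write.csv(centers, paths$centers, row.names = FALSE)
    prof <- list()
    seed_p <- derive_seed(cfg$seed, 9002)
    for (t in sort(unique(cells$time_h))) {
      sub <- cells[cells$time_h == t, ]
      ## express every frame in center-relative coordinates so replicates pool
      sub2 <- sub
      for (i in seq_len(nrow(centers))) {
        pick <- sub$replicate == centers$replicate[i] & sub$time_h == centers$time_h[i]
        sub2$x[pick] <- sub$x[pick] - centers$x[i]
        sub2$y[pick] <- sub$y[pick] - centers$y[i]
      }
      origin <- c(0, 0)
      dens <- radial_density(sub2, origin, bins = cfg$bins,
                             z_extent = cfg$z_extent,
                             labeled_fraction = cfg$labeled_fraction,
                             n_draws = cfg$n_draws, seed = seed_p)
      dens$statistic <- "density"; dens$time_h <- t
      al <- neighbor_alignment(sub2, sigma = cfg$sigma)
      alp <- radial_profile(al, "alignment", origin, bins = cfg$bins,
                            n_draws = cfg$n_draws, seed = seed_p)
      alp$statistic <- "alignment"; alp$time_h <- t
      or <- tangential_orientation(sub2, origin)
      orp <- radial_profile(or, "orientation", origin, bins = cfg$bins,
                            n_draws = cfg$n_draws, seed = seed_p)
      orp$statistic <- "orientation"; orp$time_h <- t
      pr <- class_proportions(sub2, origin, bins = cfg$bins,
                              n_draws = cfg$n_draws, seed = seed_p)
      pr$statistic <- "proportion"; pr$time_h <- t
      base_cols <- c("statistic", "time_h", "bin_lo", "bin_mid", "bin_hi",
                     "n_cells", "estimate", "median", "lo90", "hi90")
      for (d in list(dens, alp, orp)) {
        d$class <- NA_character_; d$strain <- NA_character_
        prof[[length(prof) + 1L]] <- d[, c(base_cols, "class", "strain")]
      }
      prof[[length(prof) + 1L]] <- pr[, c(base_cols, "class", "strain")]
    }
    write_table(do.call(rbind, prof), paths$profiles, "profiles")
  })

  stage("counts", {
    cells <- read_table(paths$classified, "cells")
    centers <- utils::read.csv(paths$centers)
    counts <- count_cells(cells, centers, radius = cfg$radius)
    write_table(counts, paths$counts, "counts")
  })

  stage("infer", {
    counts <- read_table(paths$counts, "counts")
    seed_i <- derive_seed(cfg$seed, 9003)
    est_rows <- list()
    for (t in sort(unique(counts$time_h))) {
      sub <- counts[counts$time_h == t, ]
      by_rep <- function(strain) vapply(sort(unique(sub$replicate)),
        function(r) sum(sub$count[sub$replicate == r & sub$strain == strain]),
        numeric(1))
      est <- ratio_posterior(by_rep("csgA"), by_rep("WT"),
                             initial_ratio = cfg$initial_ratio,
                             direction = "less", n_draws = cfg$n_draws,
                             seed = seed_i)
      est_rows[[length(est_rows) + 1L]] <- tibble::tibble(
        quantity = "ratio_all_classes", strain = "csgA/WT", time_h = t,
        measure = NA_character_, median = est$median, lo90 = est$lo90,
        hi90 = est$hi90, p = est$p_exc)
    }
    rates <- NULL
    if (length(unique(counts$time_h)) >= 2) {
      rates <- estimate_rates(counts, n_draws = cfg$n_draws, seed = seed_i,
                              correction = 1 / cfg$labeled_fraction)
      s <- rates$summary
      est_rows[[length(est_rows) + 1L]] <- tibble::tibble(
        quantity = "rate", strain = s$strain, time_h = s$midpoint_h,
        measure = s$measure, median = s$median, lo90 = s$lo90, hi90 = s$hi90,
        p = NA_real_)
    }
    est <- do.call(rbind, est_rows)
    utils::write.csv(est, paths$estimates, row.names = FALSE)
    summ <- list(schema = "mxnfb-summary/1", seed = cfg$seed,
                 n_draws = cfg$n_draws, initial_ratio = cfg$initial_ratio)
    if (!is.null(rates) && all(STRAIN_LEVELS %in% names(rates$draws))) {
      summ$p_sporulation_csga_gt_wt <- compare_rates(rates, "csgA", "WT",
                                                     measure = "sporulation")$p
      summ$p_disappearance_wt_gt_csga <- compare_rates(rates, "WT", "csgA",
                                                       measure = "disappearance")$p
    }
    jsonlite::write_json(summ, paths$summary, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  files <- sort(basename(unlist(paths)))
  manifest <- list(
    schema = "mxnfb-manifest/1",
    package_version = as.character(utils::packageVersion("mxnfb")),
    master_seed = cfg$seed,
    stage_seeds = list(scene = "derive_seed(seed, frame index)",
                       classify = derive_seed(cfg$seed, 9001),
                       profiles = derive_seed(cfg$seed, 9002),
                       infer = derive_seed(cfg$seed, 9003)),
    parameters = cfg[c("sigma", "radius", "bins", "z_extent", "scale",
                       "min_volume", "labeled_fraction", "initial_ratio",
                       "n_draws")],
    config_md5 = digest_config(cfg),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

digest_config <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg[sort(names(cfg))], file = tmp)
  unname(tools::md5sum(tmp))
}
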