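#' Parameters for the two-strain cell-fate simulator
#'
#' Per strain and 6-h interval, rods/TCs face two competing fates: conversion
#' to a spore (sporulation) and disappearance (lysis or exit from the NFB).
#' Spores are permanent. Rates are per-capita exponential hazards (h^-1) by
#' default; `semantics = "absolute"` instead treats them as absolute count
#' changes per hour (the deterministic reading of per-interval rate plots).
#'
#' @param initial_rods_tc named numeric (`WT`, `csgA`): rods + TCs at `t0`.
#' @param initial_spores named numeric (`WT`, `csgA`): spores at `t0`.
#' @param sporulation per-strain hazard (h^-1): a named list of per-interval
#'   vectors, or a named numeric recycled across intervals.
#' @param disappearance as `sporulation`, for the disappearance hazard.
#' @param t0 first time point, hours poststarvation.
#' @param interval_h interval length in hours.
#' @param n_intervals number of intervals simulated.
#' @param semantics `"per_capita"` (stochastic exponential race) or
#'   `"absolute"` (deterministic counts per hour).
#' @param seed integer seed.
#' @return a `fate_params` list.
#' @export
fate_params <- function(initial_rods_tc = c(WT = 1000, csgA = 1000),
                        initial_spores = c(WT = 0, csgA = 0),
                        sporulation = c(WT = 0.04, csgA = 0.06),
                        disappearance = c(WT = 0.03, csgA = 0.015),
                        t0 = 24, interval_h = 6, n_intervals = 3,
                        semantics = c("per_capita", "absolute"),
                        seed = 1) {
  semantics <- match.arg(semantics)
  as_mat <- function(x, name) {
    if (is.list(x)) x <- do.call(cbind, x[STRAIN_LEVELS])
    else x <- matrix(rep(x[STRAIN_LEVELS], each = n_intervals), ncol = 2,
                     dimnames = list(NULL, STRAIN_LEVELS))
    if (any(is.na(x)) || any(x < 0))
      stop("`", name, "` must be named (WT, csgA) nonnegative rates", call. = FALSE)
    x
  }
  if (any(initial_rods_tc < 0) || any(initial_spores < 0))
    stop("initial counts must be >= 0", call. = FALSE)
  structure(list(initial_rods_tc = initial_rods_tc[STRAIN_LEVELS],
                 initial_spores = initial_spores[STRAIN_LEVELS],
                 sporulation = as_mat(sporulation, "sporulation"),
                 disappearance = as_mat(disappearance, "disappearance"),
                 t0 = t0, interval_h = interval_h, n_intervals = n_intervals,
                 semantics = semantics, seed = as.integer(seed)),
            class = "fate_params")
}

#' Closed-form transition probabilities of the two-hazard exponential race
#'
#' Over an interval of length `dt`, a rod/TC with sporulation hazard `hs` and
#' disappearance hazard `hd` (h^-1) converts with probability
#' `hs / (hs + hd) * (1 - exp(-(hs + hd) dt))`, disappears with the analogous
#' `hd` share, and otherwise remains.
#'
#' @param hs,hd nonnegative hazards (h^-1); `Inf` allowed.
#' @param dt interval length (h).
#' @return named numeric `c(spore, gone, stay)`, summing to 1.
#' @export
fate_transition_probs <- function(hs, hd, dt) {
  hs <- unname(hs)
  hd <- unname(hd)
  stopifnot(hs >= 0, hd >= 0, dt > 0)
  tot <- hs + hd
  if (tot == 0) return(c(spore = 0, gone = 0, stay = 1))
  if (is.infinite(tot)) {
    share <- if (is.infinite(hs) && is.infinite(hd)) 0.5
             else if (is.infinite(hs)) 1 else 0
    return(c(spore = share, gone = 1 - share, stay = 0))
  }
  p <- 1 - exp(-tot * dt)
  c(spore = hs / tot * p, gone = hd / tot * p, stay = exp(-tot * dt))
}

#' Simulate per-strain cell-fate count trajectories
#'
#' Stochastic per-cell transitions over successive intervals (multinomial
#' draws from [fate_transition_probs()]), yielding monotone trajectories:
#' spores nondecreasing, rods+TCs nonincreasing.
#'
#' @param params a [fate_params()].
#' @return a tibble with columns `strain`, `time_h`, `rods_tc`, `spores`,
#'   `disappeared` (cumulative), one row per strain and time point.
#' @export
simulate_fates <- function(params) {
  stopifnot(inherits(params, "fate_params"))
  withr::with_seed(params$seed, {
    rows <- list()
    for (strain in STRAIN_LEVELS) {
      rt <- params$initial_rods_tc[[strain]]
      sp <- params$initial_spores[[strain]]
      gone <- 0
      rows[[length(rows) + 1L]] <- tibble::tibble(
        strain = strain, time_h = params$t0, rods_tc = rt, spores = sp,
        disappeared = gone)
      for (k in seq_len(params$n_intervals)) {
        hs <- params$sporulation[k, strain]
        hd <- params$disappearance[k, strain]
        if (params$semantics == "per_capita") {
          p <- fate_transition_probs(hs, hd, params$interval_h)
          draw <- rmultinom(1, size = rt, prob = p)
          sp <- sp + draw["spore", 1]
          gone <- gone + draw["gone", 1]
          rt <- draw["stay", 1]
        } else {
          ds <- min(hs * params$interval_h, rt)
          dg <- min(hd * params$interval_h, rt - ds)
          sp <- sp + ds
          gone <- gone + dg
          rt <- rt - ds - dg
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          strain = strain, time_h = params$t0 + k * params$interval_h,
          rods_tc = rt, spores = sp, disappeared = gone)
      }
    }
    do.call(rbind, rows)
  })
}
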