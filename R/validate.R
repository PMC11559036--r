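#' Match detected cells to ground truth one-to-one
#'
#' Greedy nearest-first one-to-one matching of detected cell centroids to
#' true cell centroids, accepting pairs closer than `max_dist`. Used to
#' validate segmentation against the synthetic generator's truth.
#'
#' @param truth tibble with `x`, `y`, `z` (e.g. the labeled subset of
#'   [generate_scene()]'s `cells`).
#' @param detected tibble with `x`, `y`, `z` from [segment_cells()].
#' @param max_dist maximum centroid distance for a match, micrometers.
#' @return list: `matches` (tibble `truth_row`, `detected_row`, `dist`),
#'   `recall` (matched / true), `false_positives` (unmatched detections),
#'   `fp_rate` (unmatched detections / detections).
#' @export
match_cells <- function(truth, detected, max_dist = 1) {
  nt <- nrow(truth); nd <- nrow(detected)
  if (nt == 0 || nd == 0)
    return(list(matches = tibble::tibble(truth_row = integer(),
                                         detected_row = integer(),
                                         dist = numeric()),
                recall = if (nt == 0) NA_real_ else 0,
                false_positives = nd,
                fp_rate = if (nd == 0) NA_real_ else 1))
  d2 <- outer(truth$x, detected$x, "-")^2 + outer(truth$y, detected$y, "-")^2 +
    outer(truth$z, detected$z, "-")^2
  d <- sqrt(d2)
  used_t <- logical(nt); used_d <- logical(nd)
  ti <- integer(); di <- integer(); dd <- numeric()
  for (k in order(d)) {
    if (d[k] > max_dist) break
    i <- (k - 1L) %% nt + 1L
    j <- (k - 1L) %/% nt + 1L
    if (used_t[i] || used_d[j]) next
    used_t[i] <- used_d[j] <- TRUE
    ti <- c(ti, i); di <- c(di, j); dd <- c(dd, d[k])
  }
  list(matches = tibble::tibble(truth_row = ti, detected_row = di, dist = dd),
       recall = length(ti) / nt,
       false_positives = nd - length(di),
       fp_rate = (nd - length(di)) / nd)
}
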