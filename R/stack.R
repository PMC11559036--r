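#' Volumetric image stack
#'
#' Container for one fluorescence channel of a confocal z-stack: an intensity
#' volume with physical voxel dimensions and acquisition metadata. Volumes
#' use `dim = c(ny, nx, nz)`; `voxel_size` is named `c(x, y, z)` in
#' micrometers.
#'
#' @param data numeric array, `dim = c(ny, nx, nz)`, intensities >= 0.
#' @param voxel_size numeric length-3, micrometers per voxel along x, y, z.
#' @param channel channel id (e.g. `"green"`, `"red"`).
#' @param time_h hours poststarvation, or `NA`.
#' @param replicate biological replicate id, or `NA`.
#' @param location one of `"NFB"`, `"proximal"`, `"distal"`, `"biofilm"`, or `NA`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size, channel = NA_character_,
                        time_h = NA_real_, replicate = NA_integer_,
                        location = NA_character_) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (ny, nx, nz)", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive numbers (x, y, z) in micrometers",
         call. = FALSE)
  if (any(data < 0, na.rm = TRUE))
    stop("intensities must be >= 0", call. = FALSE)
  names(voxel_size) <- c("x", "y", "z")
  if (!is.na(location) &&
      !location %in% c("NFB", "proximal", "distal", "biofilm"))
    stop("unknown location tag: ", location, call. = FALSE)
  structure(
    list(data = data, voxel_size = voxel_size, channel = channel,
         time_h = time_h, replicate = replicate, location = location),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_stack> %d x %d x %d voxels (%.3g x %.3g x %.3g um), channel %s, t = %s h\n",
    d[2], d[1], d[3], d[2] * x$voxel_size["x"], d[1] * x$voxel_size["y"],
    d[3] * x$voxel_size["z"], x$channel, format(x$time_h)))
  invisible(x)
}

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored as 32-bit floating point, one z-slice per page.
#' Voxel size and acquisition metadata, which plain TIFF cannot carry, go to
#' `<path>.json` next to the image. [read_stack()] restores both.
#'
#' @param stack an [image_stack()].
#' @param path output path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- dim(stack$data)[3]
  ## TIFF float samples live in [0, 1]; rescale and record the factor
  scale <- max(stack$data, 1)
  pages <- lapply(seq_len(nz),
                  function(k) stack$data[, , k, drop = TRUE] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(schema = "mxnfb-stack/1",
               voxel_size_um = as.list(stack$voxel_size),
               intensity_scale = scale,
               channel = stack$channel, time_h = stack$time_h,
               replicate = stack$replicate, location = stack$location)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' Voxel size comes from the JSON sidecar written by [write_stack()], or from
#' `voxel_size` if supplied (the override wins). Reading fails immediately if
#' neither source provides it.
#'
#' @param path TIFF path.
#' @param voxel_size optional length-3 numeric (x, y, z) micrometers,
#'   overriding the sidecar.
#' @inheritParams image_stack
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size = NULL, channel = NULL, time_h = NULL,
                       replicate = NULL, location = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  vol <- array(unlist(pages, use.names = FALSE),
               dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!is.null(meta$intensity_scale)) vol <- vol * meta$intensity_scale
  vs <- voxel_size %||% unlist(meta$voxel_size_um)[c("x", "y", "z")]
  if (is.null(vs) || length(vs) != 3L || any(is.na(vs)))
    stop("voxel size missing: supply `voxel_size` or a `", basename(sidecar),
         "` sidecar with field `voxel_size_um`", call. = FALSE)
  image_stack(vol, voxel_size = vs,
              channel = channel %||% meta$channel %||% NA_character_,
              time_h = time_h %||% meta$time_h %||% NA_real_,
              replicate = replicate %||% meta$replicate %||% NA_integer_,
              location = location %||% meta$location %||% NA_character_)
}
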