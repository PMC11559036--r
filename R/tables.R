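## Versioned CSV schemas for inter-stage contracts. Every table is written
## with a `schema` comment-free header column so mixed-language consumers can
## validate what they read.

SCHEMAS <- list(
  cells = "mxnfb-cells/1",
  counts = "mxnfb-counts/1",
  profiles = "mxnfb-profiles/1"
)

#' Write / read a schema-versioned table
#'
#' CSV round trips preserve records exactly (`read_table(write_table(x))`
#' equals `x` up to numeric printing at 15 significant digits). The schema
#' id is stored in a `schema` column on every row and checked on read.
#'
#' @param df a tibble/data.frame.
#' @param path CSV path.
#' @param schema one of `"cells"`, `"counts"`, `"profiles"`.
#' @return `path` (write) or the tibble without the schema column (read).
#' @export
write_table <- function(df, path, schema) {
  tag <- SCHEMAS[[schema]]
  if (is.null(tag)) stop("unknown schema: ", schema, call. = FALSE)
  df <- as.data.frame(df)
  df$schema <- if (nrow(df)) tag else character(0)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  if (!nrow(df)) {
    ## keep the schema recoverable for empty tables
    writeLines(c(readLines(path, n = 1L), paste0("#schema=", tag)), path)
  }
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema) {
  tag <- SCHEMAS[[schema]]
  if (is.null(tag)) stop("unknown schema: ", schema, call. = FALSE)
  lines <- readLines(path, n = 2L)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df)) {
    if (!"schema" %in% names(df) || !all(df$schema == tag))
      stop(path, " does not carry schema ", tag, call. = FALSE)
  } else if (length(lines) > 1L && startsWith(lines[2L], "#schema=")) {
    if (!identical(sub("^#schema=", "", lines[2L]), tag))
      stop(path, " does not carry schema ", tag, call. = FALSE)
  }
  df$schema <- NULL
  tibble::as_tibble(df)
}

#' Count classified cells within the analysis radius
#'
#' Tallies classified cells within `radius` of the NFB center per
#' replicate, time point, location, strain, and class — the count table
#' feeding [ratio_posterior()] and [estimate_rates()]. Zero-count
#' combinations of observed (replicate, time, location) frames with all
#' strains and classes are filled in explicitly.
#'
#' @param cells classified cell tibble (needs `x`, `y`, `class`, `strain`;
#'   optional `replicate`, `time_h`, `location`).
#' @param centers either a single `c(x, y)` used for all frames, or a tibble
#'   with `replicate`, `time_h`, `x`, `y`.
#' @param radius analysis radius, micrometers.
#' @return tibble: `replicate`, `time_h`, `location`, `strain`, `class`,
#'   `count`.
#' @export
count_cells <- function(cells, centers, radius = 60) {
  if (!all(c("class", "strain") %in% names(cells)))
    stop("`cells` needs `class` and `strain` columns (classify first; tag ",
         "each channel's cells with its strain)", call. = FALSE)
  cells <- cells[!is.na(cells$class), , drop = FALSE]
  for (f in c("replicate", "time_h", "location"))
    if (!f %in% names(cells)) cells[[f]] <- NA
  frames <- unique(cells[, c("replicate", "time_h", "location")])
  rows <- list()
  for (i in seq_len(nrow(frames))) {
    fr <- frames[i, ]
    sel <- (cells$replicate %in% fr$replicate) &
      (cells$time_h %in% fr$time_h) & (cells$location %in% fr$location)
    sub <- cells[sel, , drop = FALSE]
    ctr <- if (is.data.frame(centers)) {
      m <- centers[centers$replicate %in% fr$replicate &
                   centers$time_h %in% fr$time_h, , drop = FALSE]
      if (nrow(m) == 0) stop("no center for replicate ", fr$replicate,
                             " at ", fr$time_h, " h", call. = FALSE)
      c(m$x[1], m$y[1])
    } else centers
    inside <- radii_from_center(sub, ctr) <= radius
    for (strain in STRAIN_LEVELS) for (cls in CLASS_LEVELS) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = fr$replicate, time_h = fr$time_h, location = fr$location,
        strain = strain, class = cls,
        count = sum(inside & sub$strain == strain & sub$class == cls))
    }
  }
  do.call(rbind, rows)
}
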