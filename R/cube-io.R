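# Cube and frame persistence: multi-page 32-bit float TIFF stacks plus a JSON
# sidecar (<path>.json) holding stage/band/timestamp metadata. The TIFF writer
# stores values in [0, 1], so values are divided by a recorded positive scale
# factor on write and multiplied back on read.

tiff_scale <- function(x) {
  m <- suppressWarnings(max(x, na.rm = TRUE))
  if (!is.finite(m) || m <= 1) 1 else m
}

#' Write / read a data cube
#'
#' Persists a [data_cube()] as a 16-page 32-bit float TIFF stack with a JSON
#' sidecar (`<path>.json`) recording stage, band ids, timestamp and the
#' intensity scale factor.
#'
#' @param cube a [data_cube()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `write_cube` returns `path` invisibly; `read_cube` returns the
#'   reconstructed [data_cube()].
#' @export
write_cube <- function(cube, path) {
  sc <- tiff_scale(cube$values)
  pages <- lapply(seq_len(dim(cube$values)[3]),
                  function(b) cube$values[, , b] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(kind = "data_cube", stage = cube$stage,
               band_ids = cube$band_ids, timestamp = cube$timestamp,
               scale = sc, dim = dim(cube$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  vals <- array(NA_real_, meta$dim)
  for (b in seq_along(pages)) vals[, , b] <- pages[[b]] * meta$scale
  data_cube(vals, stage = meta$stage, band_ids = meta$band_ids,
            timestamp = meta$timestamp)
}

#' Write / read a raw mosaic frame
#'
#' Persists a [raw_mosaic_frame()] as a single-page 32-bit float TIFF with a
#' JSON sidecar holding the filter layout, exposure count, timestamp and
#' intensity scale.
#'
#' @param frame a [raw_mosaic_frame()].
#' @param path output TIFF path.
#' @return `write_frame` returns `path` invisibly; `read_frame` returns the
#'   reconstructed [raw_mosaic_frame()].
#' @export
write_frame <- function(frame, path) {
  sc <- tiff_scale(frame$values)
  tiff::writeTIFF(frame$values / sc, path, bits.per.sample = 32L,
                  compression = "none")
  meta <- list(kind = "raw_mosaic_frame",
               pattern = as.integer(frame$layout$pattern),
               origin = frame$layout$origin,
               exposure_count = frame$exposure_count,
               timestamp = frame$timestamp, scale = sc,
               dim = dim(frame$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- tiff::readTIFF(path) * meta$scale
  raw_mosaic_frame(vals,
                   layout = filter_layout(matrix(meta$pattern, 4, 4),
                                          origin = meta$origin),
                   exposure_count = meta$exposure_count,
                   timestamp = meta$timestamp)
}
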