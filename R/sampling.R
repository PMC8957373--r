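#' Region of interest
#'
#' Half-open pixel rectangle `[row0, row1) x [col0, col1)` in binned-cube
#' coordinates (0-based corners, consistent with the pixel (0,0)-at-top-left
#' convention used throughout).
#'
#' @param row0,row1,col0,col1 integer corners, `row0 < row1`, `col0 < col1`.
#' @param label optional quadrant label.
#' @return An object of class `roi`.
#' @export
roi <- function(row0, row1, col0, col1, label = "") {
  if (row1 <= row0 || col1 <= col0) stopf("ROI rectangle must be non-empty")
  structure(list(row0 = as.integer(row0), row1 = as.integer(row1),
                 col0 = as.integer(col0), col1 = as.integer(col1),
                 label = label),
            class = "roi")
}

roi_area <- function(r) (r$row1 - r$row0) * (r$col1 - r$col0)

roi_check <- function(r, cube) {
  d <- dim(cube$values)
  if (r$row0 < 0 || r$col0 < 0 || r$row1 > d[1] || r$col1 > d[2])
    stopf("ROI [%d,%d)x[%d,%d) exceeds cube bounds %d x %d",
          r$row0, r$row1, r$col0, r$col1, d[1], d[2])
}

#' Spectrum set
#'
#' A set of mean-normalised 16-channel spectra with per-spectrum metadata
#' (target SO2 in percent, subject id, provocation, timestamp, error weight,
#' split assignment).
#'
#' @param spectra N x 16 numeric matrix; each row must have mean 1 (use
#'   [normalize_spectrum()]).
#' @param meta data frame with N rows; recognised columns include
#'   `target_so2`, `subject_id`, `provocation`, `timestamp_s`, `weight`,
#'   `split`, `true_so2`.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(spectra, meta = NULL) {
  spectra <- as.matrix(spectra)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(nrow(spectra)))
  if (nrow(meta) != nrow(spectra)) stopf("meta rows must match spectra rows")
  structure(list(spectra = spectra, meta = meta), class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum set: %d spectra x %d channels; meta: %s\n",
              nrow(x$spectra), ncol(x$spectra),
              paste(names(x$meta), collapse = ", ")))
  invisible(x)
}

#' Number of spectra in a set
#' @param set a [spectrum_set()].
#' @return Integer count.
#' @export
n_spectra <- function(set) nrow(set$spectra)

#' Combine spectrum sets
#' @param ... [spectrum_set()] objects with identical channel counts and meta
#'   columns.
#' @return A single combined [spectrum_set()].
#' @export
bind_spectra <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !inherits(sets[[1]], "spectrum_set"))
    sets <- sets[[1]]
  spectrum_set(do.call(rbind, lapply(sets, `[[`, "spectra")),
               do.call(rbind, lapply(sets, `[[`, "meta")))
}

#' Subset a spectrum set
#' @param set a [spectrum_set()].
#' @param idx logical or integer row index.
#' @return The row-subsetted [spectrum_set()].
#' @export
subset_spectra <- function(set, idx) {
  spectrum_set(set$spectra[idx, , drop = FALSE],
               set$meta[idx, , drop = FALSE])
}

#' Mean-intensity normalisation of spectra
#'
#' Divides each 16-channel spectrum by its mean so that absolute intensity
#' (illumination, distance, exposure) cancels and only spectral shape remains.
#'
#' @param x a 16-vector or an N x 16 matrix of nonnegative intensities with
#'   strictly positive row means.
#' @return Same shape as `x`, each row with mean exactly 1.
#' @export
normalize_spectrum <- function(x) {
  if (is.null(dim(x))) {
    m <- mean(x)
    if (!is.finite(m) || m <= 0) stopf("spectrum mean must be positive")
    return(x / m)
  }
  m <- rowMeans(x)
  if (any(!is.finite(m) | m <= 0)) stopf("every spectrum mean must be positive")
  x / m
}

#' Randomly sample pixel spectra from an ROI
#'
#' Draws `n` distinct pixels uniformly without replacement from the ROI of a
#' reflectance cube and returns their mean-normalised spectra. Sampling is
#' reproducible under `seed` and independent across cubes when distinct seeds
#' are supplied.
#'
#' @param cube a reflectance [data_cube()].
#' @param roi an [roi()] with area >= `n`.
#' @param n number of pixels (default 10).
#' @param seed RNG seed for the draw.
#' @return A [spectrum_set()] with meta columns `pixel_row`, `pixel_col`
#'   (0-based) and `timestamp_s` copied from the cube.
#' @export
sample_roi_pixels <- function(cube, roi, n = 10L, seed = 1L) {
  if (cube$stage != "reflectance") stopf("sampling expects a reflectance cube")
  roi_check(roi, cube)
  if (roi_area(roi) < n)
    stopf("ROI area %d smaller than requested sample size %d", roi_area(roi), n)
  rows <- roi$row0:(roi$row1 - 1L)
  cols <- roi$col0:(roi$col1 - 1L)
  grid <- expand.grid(r = rows, c = cols)
  pick <- with_seed(seed, sample.int(nrow(grid), n))
  sel <- grid[pick, ]
  spec <- t(vapply(seq_len(n),
                   function(i) cube$values[sel$r[i] + 1L, sel$c[i] + 1L, ],
                   numeric(dim(cube$values)[3])))
  spectrum_set(normalize_spectrum(spec),
               data.frame(pixel_row = sel$r, pixel_col = sel$c,
                          timestamp_s = cube$timestamp))
}

#' ROI mean spectrum
#'
#' Per-band mean reflectance over all ROI pixels, then mean-intensity
#' normalised. Used when comparing against methods that operate on the ROI
#' average rather than individual pixels.
#'
#' @inheritParams sample_roi_pixels
#' @return A mean-normalised 16-vector.
#' @export
roi_mean_spectrum <- function(cube, roi) {
  if (cube$stage != "reflectance") stopf("expects a reflectance cube")
  roi_check(roi, cube)
  block <- cube$values[(roi$row0 + 1L):roi$row1, (roi$col0 + 1L):roi$col1, ,
                       drop = FALSE]
  normalize_spectrum(apply(block, 3, mean))
}

#' Foreground mask from mean reflectance
#'
#' Flags pixels whose mean reflectance across the 16 bands exceeds a
#' threshold, separating the imaged limb from a dark background for pixelwise
#' mapping.
#'
#' @param cube a reflectance [data_cube()].
#' @param threshold mean-reflectance threshold; pixels strictly above it are
#'   kept.
#' @return A logical rows x cols matrix.
#' @export
mask_foreground <- function(cube, threshold = 0.05) {
  if (cube$stage != "reflectance") stopf("expects a reflectance cube")
  mask <- rowMeans(matrix(cube$values, prod(dim(cube$values)[1:2]),
                          dim(cube$values)[3])) > threshold
  mask <- matrix(mask, dim(cube$values)[1], dim(cube$values)[2])
  if (!any(mask)) warning("foreground mask is empty")
  mask
}

#' Pair spectra with the reference trace
#'
#' Assigns each spectrum the reference SO2 sample nearest in time to its cube
#' timestamp (ties resolved to the earlier reference sample). With a 1-Hz
#' reference, pairing error is at most 0.5 s.
#'
#' @param set a [spectrum_set()] with a `timestamp_s` meta column.
#' @param trace data frame with columns `t` (s) and `so2_ref` (%).
#' @return `set` with a `target_so2` meta column filled in.
#' @export
pair_reference <- function(set, trace) {
  if (!"timestamp_s" %in% names(set$meta)) stopf("set lacks timestamp_s")
  idx <- nearest_index(set$meta$timestamp_s, trace$t)
  set$meta$target_so2 <- trace$so2_ref[idx]
  set
}

# Index of the element of `grid` nearest to each x; ties go to the earlier
# grid point.
nearest_index <- function(x, grid) {
  vapply(x, function(xi) {
    d <- abs(grid - xi)
    which(d <= min(d) + 1e-12)[1]
  }, integer(1))
}
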