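#' Filter mosaic layout
#'
#' Describes the repeating 4x4 pattern of spectral filters overlaid on the
#' sensor. Each of the 16 bands appears exactly once in the pattern; tiling
#' the pattern over the sensor assigns every pixel to exactly one band.
#'
#' @param pattern 4x4 integer matrix containing each band id 1..16 exactly
#'   once. `pattern[i, j]` is the band sensed at pattern position (i, j).
#' @param origin length-2 integer vector: (row, col) offset (0-based, each in
#'   0..3) of the pattern's top-left relative to sensor pixel (1, 1).
#' @return An object of class `filter_layout`.
#' @export
filter_layout <- function(pattern = matrix(1:16, 4, 4, byrow = TRUE),
                          origin = c(0L, 0L)) {
  pattern <- matrix(as.integer(pattern), 4, 4)
  if (!identical(sort(as.integer(pattern)), 1:16))
    stopf("layout pattern must contain each band id 1..16 exactly once")
  origin <- as.integer(origin)
  if (length(origin) != 2 || any(origin < 0) || any(origin > 3))
    stopf("layout origin must be two offsets in 0..3")
  structure(list(pattern = pattern, origin = origin), class = "filter_layout")
}

# Band id at sensor pixel (r, c), vectorised; 1-based pixel coordinates.
layout_band_at <- function(layout, r, c) {
  pr <- ((as.vector(r) - 1 - layout$origin[1]) %% 4) + 1
  pc <- ((as.vector(c) - 1 - layout$origin[2]) %% 4) + 1
  layout$pattern[cbind(pr, pc)]
}

# Native sample positions of band b on an nr x nc sensor: list of row and
# column index vectors (the 4-strided lattice where band b is measured).
layout_native_idx <- function(layout, band, nr, nc) {
  pos <- which(layout$pattern == band, arr.ind = TRUE)
  r0 <- ((pos[1, 1] - 1 + layout$origin[1]) %% 4) + 1
  c0 <- ((pos[1, 2] - 1 + layout$origin[2]) %% 4) + 1
  list(rows = seq.int(r0, nr, by = 4L), cols = seq.int(c0, nc, by = 4L))
}

#' Raw mosaic frame
#'
#' One (possibly snapshot-summed) exposure of the mosaic sensor: a single
#' intensity plane in which each pixel saw exactly one spectral band, as
#' dictated by the filter layout.
#'
#' @param values numeric matrix (rows x cols) of nonnegative intensities in
#'   arbitrary digital units. Both dimensions must be divisible by 4.
#' @param layout a [filter_layout()].
#' @param exposure_count number of summed snapshots represented (default 16).
#' @param timestamp acquisition time in seconds.
#' @return An object of class `raw_mosaic_frame`.
#' @export
raw_mosaic_frame <- function(values, layout = filter_layout(),
                             exposure_count = 16L, timestamp = 0) {
  values <- as.matrix(values)
  if (any(dim(values) %% 4 != 0))
    stopf("frame dimensions must be divisible by 4 (got %d x %d)",
          nrow(values), ncol(values))
  if (!all(is.finite(values)))
    stopf("frame values must be finite")
  structure(list(values = values, layout = layout,
                 exposure_count = as.integer(exposure_count),
                 timestamp = timestamp),
            class = "raw_mosaic_frame")
}

#' @export
print.raw_mosaic_frame <- function(x, ...) {
  cat(sprintf("raw mosaic frame: %d x %d px, %d summed snapshot(s), t = %.3f s\n",
              nrow(x$values), ncol(x$values), x$exposure_count, x$timestamp))
  invisible(x)
}

#' Multispectral data cube
#'
#' @param values numeric array rows x cols x 16.
#' @param stage one of `"demosaiced"`, `"binned"`, `"reflectance"`.
#' @param band_ids integer vector of the 16 band ids (plane order).
#' @param timestamp acquisition time in seconds.
#' @return An object of class `data_cube`.
#' @export
data_cube <- function(values, stage = c("demosaiced", "binned", "reflectance"),
                      band_ids = 1:16, timestamp = 0) {
  stage <- match.arg(stage)
  if (length(dim(values)) != 3 || dim(values)[3] != length(band_ids))
    stopf("cube must be rows x cols x %d", length(band_ids))
  if (stage == "reflectance" && any(values < 0, na.rm = TRUE))
    stopf("reflectance values must be >= 0")
  structure(list(values = values, stage = stage,
                 band_ids = as.integer(band_ids), timestamp = timestamp),
            class = "data_cube")
}

#' @export
print.data_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("data cube: %d x %d x %d, stage = %s, t = %.3f s\n",
              d[1], d[2], d[3], x$stage, x$timestamp))
  invisible(x)
}

#' Dark-correct a raw frame
#'
#' Subtracts a dark reference frame pixelwise and clamps negatives at zero
#' (intensities are physical; clamping avoids negative reflectance
#' downstream).
#'
#' @param frame,dark [raw_mosaic_frame()] objects of identical dimensions and
#'   layout.
#' @return The corrected `raw_mosaic_frame` (metadata of `frame` preserved).
#' @export
dark_correct <- function(frame, dark) {
  if (!identical(dim(frame$values), dim(dark$values)))
    stopf("frame and dark dimensions differ (%s vs %s)",
          paste(dim(frame$values), collapse = "x"),
          paste(dim(dark$values), collapse = "x"))
  out <- frame
  out$values <- pmax(frame$values - dark$values, 0)
  out
}

#' Sum consecutive snapshots
#'
#' Elementwise sum of repeated exposures of the same scene, reducing relative
#' noise by roughly the square root of the number of snapshots.
#'
#' @param frames nonempty list of [raw_mosaic_frame()] with equal shapes.
#' @return A `raw_mosaic_frame` with `exposure_count` set to the number of
#'   frames and the first frame's timestamp.
#' @export
sum_snapshots <- function(frames) {
  if (length(frames) == 0) stopf("cannot sum an empty list of frames")
  d <- dim(frames[[1]]$values)
  acc <- matrix(0, d[1], d[2])
  for (f in frames) {
    if (!identical(dim(f$values), d)) stopf("snapshot dimensions differ")
    acc <- acc + f$values
  }
  out <- frames[[1]]
  out$values <- acc
  out$exposure_count <- length(frames)
  out
}

# Dense 1-D bilinear interpolation operator: n x length(native) matrix M such
# that M %*% samples interpolates the 4-strided native samples to all n
# positions. Exact at native positions; border positions replicate the
# nearest native sample; interior weights are convex (sum to 1).
interp_operator <- function(n, native) {
  k <- length(native)
  M <- matrix(0, n, k)
  idx <- findInterval(seq_len(n), native)
  for (i in seq_len(n)) {
    j <- idx[i]
    if (j < 1) {
      M[i, 1] <- 1
    } else if (j >= k) {
      M[i, k] <- 1
    } else {
      a <- native[j]; b <- native[j + 1]
      w <- (i - a) / (b - a)
      M[i, j] <- 1 - w
      M[i, j + 1] <- w
    }
  }
  M
}

#' Demosaic by weighted bilinear interpolation
#'
#' Reconstructs a full-resolution plane per band from that band's sparse
#' native samples. Per band, the native samples form a 4-strided lattice;
#' interpolation is separable bilinear with weights normalised to sum to one,
#' replicating the nearest native sample beyond the lattice border. The
#' kernel is interpolating: native positions are returned unchanged, and
#' affine intensity ramps are reconstructed exactly at interior pixels.
#'
#' @param frame a dark-corrected [raw_mosaic_frame()].
#' @return A full-resolution [data_cube()] with `stage = "demosaiced"`.
#' @export
demosaic_wbi <- function(frame) {
  v <- frame$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr < 4 || nc < 4) stopf("frame smaller than one full mosaic tile")
  out <- array(NA_real_, c(nr, nc, 16))
  for (b in 1:16) {
    nat <- layout_native_idx(frame$layout, b, nr, nc)
    samp <- v[nat$rows, nat$cols, drop = FALSE]
    Mr <- interp_operator(nr, nat$rows)
    Mc <- interp_operator(nc, nat$cols)
    out[, , b] <- Mr %*% samp %*% t(Mc)
  }
  data_cube(out, stage = "demosaiced", timestamp = frame$timestamp)
}

#' Spatially bin a cube
#'
#' Averages non-overlapping `factor` x `factor` blocks per band. The mean
#' (rather than the sum) keeps the intensity scale independent of the binning
#' factor; the global per-band mean is conserved exactly.
#'
#' @param cube a [data_cube()] with `stage = "demosaiced"`.
#' @param factor integer block size (default 4); both spatial dimensions must
#'   be divisible by it.
#' @return A [data_cube()] with `stage = "binned"`.
#' @export
bin_spatial <- function(cube, factor = 4L) {
  if (cube$stage != "demosaiced")
    stopf("bin_spatial expects a demosaiced cube (got stage '%s')", cube$stage)
  d <- dim(cube$values)
  if (any(d[1:2] %% factor != 0))
    stopf("cube dimensions %d x %d not divisible by factor %d", d[1], d[2], factor)
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  out <- array(NA_real_, c(nr, nc, d[3]))
  gr <- rep(seq_len(nr), each = factor)
  gc <- rep(seq_len(nc), each = factor)
  for (b in seq_len(d[3])) {
    tmp <- rowsum(cube$values[, , b], gr) / factor      # nr x (nc*factor)
    out[, , b] <- t(rowsum(t(tmp), gc) / factor)        # nr x nc
  }
  data_cube(out, stage = "binned", band_ids = cube$band_ids,
            timestamp = cube$timestamp)
}

#' White-normalise a cube
#'
#' Elementwise ratio of a binned measurement cube to a binned white-reference
#' cube, converting digital intensities to dimensionless reflectance.
#'
#' @param cube,white binned [data_cube()]s of identical shape; `white` must be
#'   strictly positive everywhere.
#' @return A [data_cube()] with `stage = "reflectance"`.
#' @export
white_normalize <- function(cube, white) {
  if (cube$stage != "binned" || white$stage != "binned")
    stopf("white_normalize expects binned cubes")
  if (!identical(dim(cube$values), dim(white$values)))
    stopf("cube and white shapes differ")
  bad <- which(apply(white$values <= 0, 3, any))
  if (length(bad) > 0)
    stopf("white reference contains non-positive values in band(s) %s",
          paste(cube$band_ids[bad], collapse = ", "))
  data_cube(cube$values / white$values, stage = "reflectance",
            band_ids = cube$band_ids, timestamp = cube$timestamp)
}

#' Full preprocessing chain
#'
#' Dark correction, weighted bilinear demosaicing, spatial binning, and white
#' normalization, in that order. The white frame is passed through the same
#' dark-correct/demosaic/bin chain before the ratio is taken.
#'
#' @param frame,dark,white [raw_mosaic_frame()]s (measurement, dark reference,
#'   white reference).
#' @param bin_factor spatial binning factor (default 4).
#' @return A reflectance [data_cube()] with dimensions `dim(frame)/bin_factor`.
#' @export
preprocess_frame <- function(frame, dark, white, bin_factor = 4L) {
  m <- bin_spatial(demosaic_wbi(dark_correct(frame, dark)), bin_factor)
  w <- bin_spatial(demosaic_wbi(dark_correct(white, dark)), bin_factor)
  white_normalize(m, w)
}
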