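test_that("dark correction subtracts pixelwise and clamps at zero", {
  f <- const_frame(100)
  d <- const_frame(10)
  expect_equal(dark_correct(f, d)$values, matrix(90, 8, 8))
  expect_equal(dark_correct(const_frame(5), d)$values, matrix(0, 8, 8))
  expect_error(dark_correct(f, const_frame(1, nr = 12)), "dimensions")
  # metadata preserved
  f$timestamp <- 3.5
  expect_equal(dark_correct(f, d)$timestamp, 3.5)
})

test_that("snapshot summation is elementwise and reduces relative noise", {
  f <- const_frame(2)
  s <- sum_snapshots(rep(list(f), 16))
  expect_equal(s$values, matrix(32, 8, 8))
  expect_equal(s$exposure_count, 16L)
  expect_error(sum_snapshots(list()), "empty")

  # Monte-Carlo: SD of a 2-frame sum of iid noise is ~ sigma * sqrt(2)
  set.seed(42)
  sds <- replicate(200, {
    a <- raw_mosaic_frame(matrix(100 + rnorm(64, 0, 3), 8, 8))
    b <- raw_mosaic_frame(matrix(100 + rnorm(64, 0, 3), 8, 8))
    sd(sum_snapshots(list(a, b))$values)
  })
  expect_equal(mean(sds), 3 * sqrt(2), tolerance = 0.05)
})

test_that("demosaicing is sample-preserving and exact on constants", {
  lay <- filter_layout()
  f <- const_frame(7, nr = 16, nc = 16, layout = lay)
  cube <- demosaic_wbi(f)
  expect_equal(dim(cube$values), c(16L, 16L, 16L))
  for (b in 1:16) expect_equal(cube$values[, , b], matrix(7, 16, 16))

  # random frame: every band equals the raw frame at its native positions
  set.seed(7)
  f <- raw_mosaic_frame(matrix(runif(16 * 16, 10, 50), 16, 16), layout = lay)
  cube <- demosaic_wbi(f)
  for (b in 1:16) {
    nat <- oximap:::layout_native_idx(lay, b, 16, 16)
    expect_equal(cube$values[nat$rows, nat$cols, b],
                 f$values[nat$rows, nat$cols])
  }
  bad <- structure(list(values = matrix(0, 3, 4), layout = lay,
                        exposure_count = 1L, timestamp = 0),
                   class = "raw_mosaic_frame")
  expect_error(demosaic_wbi(bad), "tile")
})

test_that("demosaicing reconstructs affine ramps exactly at interior pixels", {
  # a linear ramp v(r, c) = 2 r + 3 c + 5 on the full sensor; bilinear
  # interpolation of 4-strided samples must reproduce it between native
  # samples (border replication breaks affinity only outside the lattice hull)
  lay <- filter_layout()
  nr <- 24; nc <- 24
  ramp <- outer(1:nr, 1:nc, function(r, c) 2 * r + 3 * c + 5)
  cube <- demosaic_wbi(raw_mosaic_frame(ramp, layout = lay))
  for (b in c(1, 6, 16)) {
    nat <- oximap:::layout_native_idx(lay, b, nr, nc)
    rr <- min(nat$rows):max(nat$rows)
    cc <- min(nat$cols):max(nat$cols)
    expect_equal(cube$values[rr, cc, b], ramp[rr, cc], tolerance = 1e-12)
  }
})

test_that("demosaicing kernel weights are convex within each cell", {
  # one nonzero native sample on an 8x8 frame: interpolated values enumerate
  # the kernel; total weight over each enclosing 1-D cell must be convex and
  # the 2-D weights must equal the product of the 1-D weights
  lay <- filter_layout()
  b <- lay$pattern[1, 1]
  v <- matrix(0, 8, 8)
  nat <- oximap:::layout_native_idx(lay, b, 8, 8)
  v[nat$rows[1], nat$cols[1]] <- 1
  cube <- demosaic_wbi(raw_mosaic_frame(v, layout = lay))
  plane <- cube$values[, , b]
  # brute-force oracle: separable hat function centred on the native sample
  w1 <- function(i, native, j) { # weight of native[j] at position i
    k <- findInterval(i, native)
    if (k < 1) return(as.numeric(j == 1))
    if (k >= length(native)) return(as.numeric(j == length(native)))
    if (j == k) return(1 - (i - native[k]) / (native[k + 1] - native[k]))
    if (j == k + 1) return((i - native[k]) / (native[k + 1] - native[k]))
    0
  }
  oracle <- outer(1:8, 1:8, Vectorize(function(r, c)
    w1(r, nat$rows, 1) * w1(c, nat$cols, 1)))
  expect_equal(plane, oracle, tolerance = 1e-12)
  expect_true(all(plane >= 0 & plane <= 1))
})

test_that("spatial binning averages blocks and conserves the global mean", {
  set.seed(3)
  v <- array(runif(8 * 8 * 16), c(8, 8, 16))
  cube <- data_cube(v, stage = "demosaiced")
  binned <- bin_spatial(cube, 4)
  expect_equal(dim(binned$values), c(2L, 2L, 16L))
  # loop oracle
  for (b in 1:16) for (i in 1:2) for (j in 1:2)
    expect_equal(binned$values[i, j, b],
                 mean(v[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j), b]))
  for (b in 1:16)
    expect_equal(mean(binned$values[, , b]), mean(v[, , b]), tolerance = 1e-14)

  const <- bin_spatial(data_cube(array(2.5, c(8, 8, 16)), stage = "demosaiced"))
  expect_true(all(const$values == 2.5))
  expect_error(bin_spatial(data_cube(array(1, c(6, 8, 16)), stage = "demosaiced"), 4),
               "divisible")
  expect_error(bin_spatial(binned), "demosaiced")
})

test_that("white normalization is an elementwise ratio with guarded zeros", {
  v <- array(runif(4 * 4 * 16, 1, 2), c(4, 4, 16))
  cube <- data_cube(v, stage = "binned")
  expect_true(all(white_normalize(cube, cube)$values == 1))
  zero <- data_cube(array(0, c(4, 4, 16)), stage = "binned")
  expect_true(all(white_normalize(zero, cube)$values == 0))
  bad <- v; bad[1, 1, 5] <- 0
  expect_error(white_normalize(cube, data_cube(bad, stage = "binned")),
               "band\\(s\\) 5")
})

test_that("cube and frame containers round-trip through TIFF + sidecar", {
  dir <- withr::local_tempdir()
  v <- array(runif(8 * 8 * 16, 0, 3), c(8, 8, 16))
  cube <- data_cube(v, stage = "reflectance", timestamp = 12.5)
  p <- file.path(dir, "cube.tif")
  write_cube(cube, p)
  back <- read_cube(p)
  expect_equal(back$values, v, tolerance = 1e-6)
  expect_equal(back$stage, "reflectance")
  expect_equal(back$timestamp, 12.5)

  f <- raw_mosaic_frame(matrix(runif(64, 0, 4000), 8, 8), timestamp = 2)
  pf <- file.path(dir, "frame.tif")
  write_frame(f, pf)
  fb <- read_frame(pf)
  expect_equal(fb$values, f$values, tolerance = 1e-4)
  expect_equal(fb$layout$pattern, f$layout$pattern)
})

test_that("noiseless rendered frames round-trip to band reflectance", {
  # homogeneous arm (heterogeneity 0), zero sensor noise: the preprocessing
  # chain must recover sensor_response / white_response at arm-interior
  # pixels to numerical precision
  sp <- subject_params(5)
  bank <- filter_bank(2)
  meas <- render_measurement(sp, "arterial", bank = bank, times = c(0, 200),
                             dims = c(32, 32),
                             noise = list(sensor_sd = 0, heterogeneity = 0))
  cube <- preprocess_frame(meas$frames[[2]], meas$dark, meas$white)
  expect_equal(dim(cube$values), c(8L, 8L, 16L))
  so2 <- meas$timecourse$so2[2] / 100
  f_rbc <- meas$timecourse$f_rbc[2]
  expected <- sensor_response(
    forward_reflectance(list(L = sp$L, f_rbc = f_rbc, mel = sp$mel,
                             scat = sp$scat), so2, bank$lambda), bank) /
    white_response(bank)
  # interior pixels: inside the arm with the full 3x3 neighbourhood inside
  # too (demosaicing draws on diagonal neighbours as well)
  m <- meas$mask
  interior <- which(vapply(1:64, function(k) {
    i <- (k - 1) %% 8 + 1; j <- (k - 1) %/% 8 + 1
    i > 1 && i < 8 && j > 1 && j < 8 && all(m[(i - 1):(i + 1), (j - 1):(j + 1)])
  }, logical(1)))
  expect_gt(length(interior), 3)
  for (k in interior) {
    i <- (k - 1) %% 8 + 1; j <- (k - 1) %/% 8 + 1
    expect_equal(cube$values[i, j, ], as.numeric(expected), tolerance = 1e-6)
  }
})
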