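# Helper: wrap plain matrices into a trainable spectrum set.
make_set <- function(X, y, w = rep(1, length(y))) {
  spectrum_set(X, data.frame(target_so2 = y, weight = w))
}

test_that("initialization is seeded, layer-aware and counts parameters", {
  a <- init_ann(3, seed = 10)
  b <- init_ann(3, seed = 10)
  c <- init_ann(3, seed = 11)
  expect_identical(a$W1, b$W1)
  expect_identical(a$b1, b$b1)
  expect_false(identical(a$W1, c$W1))
  # parameter count (16 + 1) * H + (H + 1) = 55 for H = 3
  expect_equal(oximap:::n_params(a), 55L)
  expect_equal(length(oximap:::pack_params(a)), 55L)
  expect_error(init_ann(0), "n_hidden")
})

test_that("forward pass matches a hand computation for H = 1", {
  m <- init_ann(1, seed = 1)
  m$W1 <- matrix(seq(-0.8, 0.7, length.out = 16), 1, 16)
  m$b1 <- 0.3
  m$W2 <- matrix(1.4, 1, 1)
  m$b2 <- -0.2
  m$input_scaling <- list(center = rep(1, 16), half = rep(0.5, 16))
  m$target_scaling <- list(center = 50, half = 50)
  x <- seq(0.7, 1.3, length.out = 16)
  xs <- (x - 1) / 0.5
  hand <- (1.4 * tanh(sum(m$W1 * xs) + 0.3) - 0.2) * 50 + 50
  expect_equal(ann_forward(m, x), hand, tolerance = 1e-12)

  # constant network mapping to 50%
  m$W1[] <- 0; m$b1 <- 0; m$W2[] <- 0; m$b2 <- 0
  X <- matrix(runif(5 * 16), 5)
  expect_equal(ann_forward(m, X), rep(50, 5))

  # batch forward equals per-row forward
  m2 <- init_ann(4, seed = 2)
  m2$target_scaling <- list(center = 50, half = 50)
  X <- matrix(runif(8 * 16, 0.5, 1.5), 8)
  expect_equal(ann_forward(m2, X),
               vapply(1:8, function(i) ann_forward(m2, X[i, ]), numeric(1)))
  expect_error(ann_forward(m2, matrix(1, 2, 9)), "expects")
})

test_that("LM step approaches Gauss-Newton and gradient descent limits", {
  set.seed(6)
  J <- matrix(rnorm(30), 10, 3)
  r <- rnorm(10)
  JtJ <- crossprod(J); Jtr <- crossprod(J, r)
  gn <- solve(JtJ, Jtr)
  expect_equal(oximap:::lm_step(JtJ, Jtr, 1e-12), gn, tolerance = 1e-8)
  big <- oximap:::lm_step(JtJ, Jtr, 1e12)
  # direction aligns with the (negative) gradient, magnitude ~ |g| / mu
  expect_equal(big * 1e12, Jtr, tolerance = 1e-3)
})

test_that("splits are seeded 70/15/15 at the spectrum level", {
  cfg <- training_config(seed = 3)
  s1 <- assign_splits(1000, cfg)
  s2 <- assign_splits(1000, cfg)
  expect_identical(s1, s2)
  expect_equal(as.integer(table(s1)), c(700L, 150L, 150L))
  expect_false(identical(s1, assign_splits(1000, training_config(seed = 4))))
})

test_that("LM training solves a near-linear regression to high precision", {
  set.seed(8)
  X <- matrix(runif(4000 * 16, 0.5, 1.5), 4000)
  y <- 30 * X[, 1] + 20
  m <- train_lm(init_ann(1, seed = 1), make_set(X, y), training_config(seed = 1))
  expect_lt(sqrt(m$loss_pct2[["val"]]), 0.1)
  expect_lt(sqrt(m$loss_pct2[["train"]]), 0.1)
})

test_that("training reduces the loss and respects sample weights", {
  set.seed(9)
  X <- matrix(runif(3000 * 16, 0.5, 1.5), 3000)
  y <- 40 * X[, 2] + 10 * X[, 5] + 10
  # corrupt a block of targets but zero their weights: the fit must ignore them
  w <- rep(1, 3000)
  bad <- 1:400
  y_bad <- y
  y_bad[bad] <- y[bad] + 70
  w[bad] <- 0
  m <- train_lm(init_ann(2, seed = 3), make_set(X, y_bad, w),
                training_config(seed = 2))
  pred <- ann_forward(m, X)
  expect_lt(sqrt(mean((pred[-bad] - y[-bad])^2)), 1)
  expect_gt(sqrt(mean((pred[bad] - y_bad[bad])^2)), 30)

  # training loss at the returned model <= loss at initialization
  init <- init_ann(2, seed = 3)
  init$input_scaling <- m$input_scaling
  init$target_scaling <- m$target_scaling
  expect_lte(m$loss_pct2[["train"]],
             mean((ann_forward(init, X) - y_bad)^2))
})

test_that("uniform weights reproduce unweighted training exactly", {
  set.seed(10)
  X <- matrix(runif(1500 * 16, 0.5, 1.5), 1500)
  y <- 25 * X[, 3] + 30 + rnorm(1500, 0, 2)
  cfg_w <- training_config(seed = 5)
  cfg_u <- training_config(seed = 5, sample_weights = FALSE)
  mw <- train_lm(init_ann(2, seed = 7), make_set(X, y), cfg_w)
  mu <- train_lm(init_ann(2, seed = 7), make_set(X, y), cfg_u)
  expect_equal(mw$W1, mu$W1)
  expect_equal(mw$b2, mu$b2)
})

test_that("pixelwise mapping applies the network per foreground pixel", {
  m <- init_ann(1, seed = 1)
  m$input_scaling <- list(center = rep(1, 16), half = rep(0.5, 16))
  m$target_scaling <- list(center = 50, half = 50)
  spec <- runif(16, 0.4, 1.2)
  cube <- uniform_cube(spec, nr = 8, nc = 8)
  map <- predict_map(m, cube)
  expect_equal(dim(map), c(8L, 8L))
  expect_equal(unique(as.vector(map)), ann_forward(m, normalize_spectrum(spec)))

  mask <- matrix(FALSE, 8, 8); mask[2, 3] <- TRUE
  map2 <- predict_map(m, cube, mask)
  expect_equal(sum(!is.na(map2)), 1L)
  expect_warning(predict_map(m, cube, matrix(FALSE, 8, 8)), "empty")

  # full-size map (order-of-magnitude runtime check only: must not be pathological)
  big <- data_cube(array(runif(512 * 272 * 16, 0.2, 1), c(512, 272, 16)),
                   stage = "reflectance")
  t0 <- Sys.time()
  mb <- predict_map(init_ann(3, seed = 2), big)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_equal(dim(mb), c(512L, 272L))
  expect_true(all(is.finite(mb)))
})

test_that("model serialization round-trips predictions", {
  set.seed(11)
  X <- matrix(runif(900 * 16, 0.5, 1.5), 900)
  y <- 20 * X[, 1] + 40
  m <- train_lm(init_ann(2, seed = 4), make_set(X, y), training_config(seed = 1))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ann.json")
  write_ann(m, p)
  back <- read_ann(p)
  expect_equal(ann_forward(back, X[1:20, ]), ann_forward(m, X[1:20, ]),
               tolerance = 1e-12)
})
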