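#' Training configuration for Levenberg-Marquardt
#'
#' Defaults mirror the standard behaviour of shallow-network toolboxes: random
#' 70/15/15 train/validation/test split at the spectrum level, early stopping
#' after 6 consecutive validation failures, damping schedule mu0 = 1e-3
#' (x0.1 on accepted steps, x10 on rejected steps, ceiling 1e10) and a
#' gradient floor of 1e-7.
#'
#' @param split_fractions train/validation/test fractions summing to 1.
#' @param max_epochs maximum number of accepted LM iterations.
#' @param max_val_failures consecutive validation-loss increases tolerated
#'   before stopping.
#' @param mu0,mu_dec,mu_inc,mu_max LM damping: initial value, decrease factor
#'   on success, increase factor on failure, and ceiling.
#' @param min_grad stop when the infinity norm of the loss gradient falls
#'   below this.
#' @param sample_weights logical; use per-sample error weights if present.
#' @param seed RNG seed governing the split assignment.
#' @return A list of class `training_config`.
#' @export
training_config <- function(split_fractions = c(0.70, 0.15, 0.15),
                            max_epochs = 1000L, max_val_failures = 6L,
                            mu0 = 1e-3, mu_dec = 0.1, mu_inc = 10,
                            mu_max = 1e10, min_grad = 1e-7,
                            sample_weights = TRUE, seed = 1L) {
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stopf("split fractions must sum to 1")
  if (any(c(mu0, mu_dec, mu_inc, mu_max) <= 0))
    stopf("LM damping parameters must be positive")
  structure(list(split_fractions = split_fractions,
                 max_epochs = as.integer(max_epochs),
                 max_val_failures = as.integer(max_val_failures),
                 mu0 = mu0, mu_dec = mu_dec, mu_inc = mu_inc, mu_max = mu_max,
                 min_grad = min_grad, sample_weights = isTRUE(sample_weights),
                 seed = seed),
            class = "training_config")
}

# Affine scaling map to [-1, 1]: x_s = (x - center) / half.
fit_scaling <- function(x) {
  lo <- apply(as.matrix(x), 2, min)
  hi <- apply(as.matrix(x), 2, max)
  half <- (hi - lo) / 2
  half[half == 0] <- 1  # constant feature: map to 0 rather than divide by 0
  list(center = (hi + lo) / 2, half = half)
}

apply_scaling <- function(sc, x) sweep(sweep(as.matrix(x), 2, sc$center), 2, sc$half, "/")
invert_scaling <- function(sc, xs) sweep(sweep(as.matrix(xs), 2, sc$half, "*"), 2, sc$center, "+")

#' Initialise a shallow 16-H-1 network
#'
#' Layer-width-aware random initialisation in the Nguyen-Widrow style: hidden
#' weight rows are drawn randomly, rescaled to magnitude
#' `0.7 * H^(1/n_in)` with biases spreading the active regions of the tanh
#' units across the input range; output weights are small uniform draws.
#' Distinct seeds give distinct parameter sets.
#'
#' @param n_hidden number of tanh hidden units (>= 1).
#' @param seed RNG seed.
#' @param n_input number of inputs (default 16 spectral channels).
#' @return An object of class `ann_model` with untrained scaling (identity
#'   until [train_lm()] fits it on the training split).
#' @export
init_ann <- function(n_hidden, seed = 1L, n_input = 16L) {
  if (n_hidden < 1) stopf("n_hidden must be >= 1")
  with_seed(seed, {
    W1 <- matrix(stats::runif(n_hidden * n_input, -1, 1), n_hidden, n_input)
    norms <- sqrt(rowSums(W1^2))
    beta <- 0.7 * n_hidden^(1 / n_input)
    W1 <- W1 * beta / norms
    b1 <- beta * seq(-1, 1, length.out = max(n_hidden, 2))[seq_len(n_hidden)] *
      sign(stats::runif(n_hidden) - 0.5)
    W2 <- matrix(stats::runif(n_hidden, -0.5, 0.5), 1, n_hidden)
    b2 <- stats::runif(1, -0.5, 0.5)
    structure(list(n_hidden = as.integer(n_hidden),
                   n_input = as.integer(n_input),
                   W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                   input_scaling = NULL, target_scaling = NULL,
                   seed = seed, history = NULL),
              class = "ann_model")
  })
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("shallow ANN: %d -> %d (tanh) -> 1%s\n", x$n_input, x$n_hidden,
              if (is.null(x$history)) " (untrained)" else
                sprintf(", trained %d epochs", nrow(x$history))))
  invisible(x)
}

n_params <- function(model) {
  model$n_hidden * model$n_input + model$n_hidden + model$n_hidden + 1L
}

pack_params <- function(m) c(as.vector(m$W1), m$b1, as.vector(m$W2), m$b2)

unpack_params <- function(m, theta) {
  H <- m$n_hidden; In <- m$n_input
  i <- 0
  m$W1 <- matrix(theta[seq_len(H * In)], H, In); i <- H * In
  m$b1 <- theta[i + seq_len(H)]; i <- i + H
  m$W2 <- matrix(theta[i + seq_len(H)], 1, H); i <- i + H
  m$b2 <- theta[i + 1]
  m
}

# Forward pass in scaled units. X_s: N x n_input (already input-scaled).
forward_scaled <- function(model, X_s) {
  A <- tanh(X_s %*% t(model$W1) + matrix(model$b1, nrow(X_s), model$n_hidden,
                                         byrow = TRUE))
  drop(A %*% t(model$W2)) + model$b2
}

#' Network predictions in percent SO2
#'
#' Applies the fitted input scaling, the tanh hidden layer and the linear
#' output, then inverts the target scaling back to percent. Outputs are not
#' clipped to `[0, 100]`: the reference itself takes slightly out-of-range
#' values and clipping would bias agreement statistics.
#'
#' @param model a trained [init_ann()] / [train_lm()] model.
#' @param X N x 16 matrix (or 16-vector) of mean-normalised spectra.
#' @return Numeric vector of N predictions (%).
#' @export
ann_forward <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  if (ncol(X) != model$n_input)
    stopf("input has %d columns; model expects %d", ncol(X), model$n_input)
  X_s <- if (is.null(model$input_scaling)) X else
    apply_scaling(model$input_scaling, X)
  y_s <- forward_scaled(model, X_s)
  if (is.null(model$target_scaling)) y_s else
    drop(invert_scaling(model$target_scaling, matrix(y_s)))
}

# Jacobian of scaled predictions w.r.t. packed parameters. Returns list with
# yhat (N) and J (N x P), columns ordered as pack_params.
forward_jacobian <- function(model, X_s) {
  N <- nrow(X_s); H <- model$n_hidden; In <- model$n_input
  Z <- X_s %*% t(model$W1) + matrix(model$b1, N, H, byrow = TRUE)
  A <- tanh(Z)
  dA <- 1 - A^2                              # N x H
  yhat <- drop(A %*% t(model$W2)) + model$b2
  G <- dA * matrix(model$W2, N, H, byrow = TRUE)  # N x H: dy/dz_h
  J <- matrix(0, N, n_params(model))
  # dW1[h, j] columns come first, in column-major order of W1 (h fastest)
  for (j in seq_len(In))
    J[, (j - 1) * H + seq_len(H)] <- G * X_s[, j]
  J[, H * In + seq_len(H)] <- G          # b1
  J[, H * In + H + seq_len(H)] <- A      # W2
  J[, H * In + 2 * H + 1] <- 1           # b2
  list(yhat = yhat, J = J)
}

# One LM parameter update: solve (J'J + mu I) delta = J'r for residuals
# r = sqrt(w) (y - yhat) and J the residual Jacobian d r / d theta = -sqrt(w) dyhat.
# Exposed internally so the mu -> 0 (Gauss-Newton) and mu -> Inf (gradient
# descent) limits can be verified directly.
lm_step <- function(JtJ, Jtr, mu) {
  solve(JtJ + mu * diag(nrow(JtJ)), Jtr)
}

weighted_mse <- function(y, yhat, w) sum(w * (y - yhat)^2) / sum(w)

#' Assign 70/15/15 splits
#'
#' Random spectrum-level assignment to train/validation/test in the given
#' fractions, reproducible under the config seed.
#'
#' @param n number of spectra.
#' @param cfg a [training_config()].
#' @return Factor of length `n` with levels `train`, `val`, `test`.
#' @export
assign_splits <- function(n, cfg) {
  n_tr <- round(cfg$split_fractions[1] * n)
  n_va <- round(cfg$split_fractions[2] * n)
  lab <- rep(c("train", "val", "test"),
             c(n_tr, n_va, n - n_tr - n_va))
  with_seed(derive_seed(cfg$seed, 101), factor(sample(lab), levels = c("train", "val", "test")))
}

#' Train a shallow network by Levenberg-Marquardt
#'
#' Minimises the weighted mean-square error on the training split. Each
#' epoch forms the residual Jacobian analytically, solves the damped normal
#' equations, and adapts the damping `mu` (decrease on accepted steps,
#' increase on rejections). Training stops on `max_val_failures` consecutive
#' validation-loss increases, on `max_epochs`, on the gradient floor, or when
#' `mu` exceeds its ceiling; the returned model is the one with the best
#' validation loss. Input and target scalings to `[-1, 1]` are fitted on the
#' training split.
#'
#' @param model an [init_ann()] model.
#' @param data a [spectrum_set()] whose meta has `target_so2` and (if
#'   `cfg$sample_weights`) `weight`.
#' @param cfg a [training_config()].
#' @return The trained `ann_model`, with `history` (per-epoch mu and
#'   train/validation loss in scaled units), `split` assignment and
#'   `loss_pct2` (weighted MSE per split, in %^2).
#' @export
train_lm <- function(model, data, cfg = training_config()) {
  X <- data$spectra
  y <- data$meta$target_so2
  if (is.null(y) || any(!is.finite(y))) stopf("data lacks finite target_so2")
  w <- if (cfg$sample_weights) {
    if (is.null(data$meta$weight)) stopf("sample_weights = TRUE but no weight column")
    data$meta$weight
  } else rep(1, length(y))
  split <- assign_splits(length(y), cfg)
  if (length(y) < 10 * n_params(model))
    warning(sprintf(
      "only %d spectra for %d parameters; >= %d recommended for a stable fit",
      length(y), n_params(model), 10 * n_params(model)))

  model$input_scaling <- fit_scaling(X[split == "train", , drop = FALSE])
  model$target_scaling <- fit_scaling(matrix(y[split == "train"]))
  X_s <- apply_scaling(model$input_scaling, X)
  y_s <- drop(apply_scaling(model$target_scaling, matrix(y)))

  tr <- split == "train"; va <- split == "val"
  Xtr <- X_s[tr, , drop = FALSE]; ytr <- y_s[tr]; wtr <- w[tr]
  Xva <- X_s[va, , drop = FALSE]; yva <- y_s[va]; wva <- w[va]
  if (sum(wtr) <= 0) stopf("training weights are all zero")
  sw <- sqrt(wtr)

  theta <- pack_params(model)
  mu <- cfg$mu0
  cur <- unpack_params(model, theta)
  fj <- forward_jacobian(cur, Xtr)
  loss <- weighted_mse(ytr, fj$yhat, wtr)
  val_loss <- weighted_mse(yva, forward_scaled(cur, Xva), wva)
  best <- list(theta = theta, val = val_loss, epoch = 0L)
  fails <- 0L
  hist <- vector("list", cfg$max_epochs)
  epoch <- 0L

  while (epoch < cfg$max_epochs) {
    rw <- sw * (ytr - fj$yhat)                 # weighted residuals
    Jw <- sw * fj$J                            # row-scaled Jacobian of yhat
    JtJ <- crossprod(Jw)
    Jtr_ <- crossprod(Jw, rw)                  # = -J_res' r, i.e. -0.5 grad
    if (max(abs(Jtr_)) * 2 / sum(wtr) < cfg$min_grad) break
    accepted <- FALSE
    while (!accepted && mu <= cfg$mu_max) {
      delta <- tryCatch(lm_step(JtJ, Jtr_, mu), error = function(e) NULL)
      if (!is.null(delta)) {
        cand <- unpack_params(cur, theta + drop(delta))
        cand_loss <- weighted_mse(ytr, forward_scaled(cand, Xtr), wtr)
        if (is.finite(cand_loss) && cand_loss < loss) {
          theta <- theta + drop(delta)
          cur <- cand
          loss <- cand_loss
          mu <- max(mu * cfg$mu_dec, 1e-20)
          accepted <- TRUE
        }
      }
      if (!accepted) mu <- mu * cfg$mu_inc
    }
    if (!accepted) break                       # mu ceiling reached
    epoch <- epoch + 1L
    fj <- forward_jacobian(cur, Xtr)
    val_loss <- weighted_mse(yva, forward_scaled(cur, Xva), wva)
    hist[[epoch]] <- c(epoch = epoch, mu = mu, train_loss = loss,
                       val_loss = val_loss)
    if (val_loss < best$val) {
      best <- list(theta = theta, val = val_loss, epoch = epoch)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= cfg$max_val_failures) break
    }
  }

  out <- unpack_params(cur, best$theta)
  out$history <- as.data.frame(do.call(rbind, hist[seq_len(epoch)]))
  out$best_epoch <- best$epoch
  out$split <- split
  yhat <- ann_forward(out, X)
  out$loss_pct2 <- c(
    train = weighted_mse(y[tr], yhat[tr], w[tr]),
    val = weighted_mse(y[va], yhat[va], w[va]),
    test = weighted_mse(y[split == "test"], yhat[split == "test"],
                        w[split == "test"]))
  out
}

#' Pixelwise SO2 map
#'
#' Applies a trained network to every foreground pixel of a reflectance cube:
#' each pixel's 16-channel spectrum is mean-normalised and passed through the
#' network. Masked-out pixels are `NA`.
#'
#' @param model a trained [train_lm()] model.
#' @param cube a reflectance [data_cube()].
#' @param mask logical rows x cols matrix (e.g. from [mask_foreground()]);
#'   default keeps every pixel.
#' @return Numeric rows x cols matrix of SO2 estimates in percent.
#' @export
predict_map <- function(model, cube, mask = NULL) {
  if (cube$stage != "reflectance") stopf("expects a reflectance cube")
  d <- dim(cube$values)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  out <- matrix(NA_real_, d[1], d[2])
  keep <- which(mask)
  if (length(keep) == 0) {
    warning("empty mask: returning an all-NA map")
    return(out)
  }
  flat <- matrix(cube$values, d[1] * d[2], d[3])[keep, , drop = FALSE]
  out[keep] <- ann_forward(model, normalize_spectrum(flat))
  out
}

#' Serialize / restore a trained model
#'
#' Flat JSON document holding shapes, scalings and weights.
#'
#' @param model an `ann_model`.
#' @param path JSON file path.
#' @return `write_ann` returns `path` invisibly; `read_ann` the model.
#' @export
write_ann <- function(model, path) {
  doc <- list(n_hidden = model$n_hidden, n_input = model$n_input,
              W1 = as.vector(model$W1), b1 = model$b1,
              W2 = as.vector(model$W2), b2 = model$b2,
              input_scaling = model$input_scaling,
              target_scaling = model$target_scaling, seed = model$seed)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ann
#' @export
read_ann <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n_hidden = doc$n_hidden, n_input = doc$n_input,
                 W1 = matrix(doc$W1, doc$n_hidden, doc$n_input),
                 b1 = doc$b1, W2 = matrix(doc$W2, 1, doc$n_hidden),
                 b2 = doc$b2, input_scaling = doc$input_scaling,
                 target_scaling = doc$target_scaling, seed = doc$seed,
                 history = NULL),
            class = "ann_model")
}
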