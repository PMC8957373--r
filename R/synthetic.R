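# Synthetic occlusion-cohort simulator: a deliberately simple forward optical
# model (single effective path length, modified Beer-Lambert) feeding an
# emulated 16-channel mosaic sensor with overlapping passbands. The simulator
# exists to exercise the full learning pipeline (sensor -> SO2 mapping trained
# against a noisy point reference); it does not attempt layered photon
# transport.

#' Emulated 16-channel filter bank
#'
#' Sixteen overlapping Gaussian-like passbands spanning 450-650 nm with a
#' broad secondary leak lobe (emulating the complex sensitivities of on-chip
#' interference filter mosaics) and per-sensor random perturbations of
#' centre, width and amplitude, plus a smooth broadband illumination
#' spectrum.
#'
#' @param seed per-sensor perturbation seed.
#' @param lambda wavelength grid in nm (1 nm step recommended).
#' @return Object of class `filter_bank`: `lambda`, `transmission` (length(lambda)
#'   x 16, in `[0, 1]`), `illumination`, `centers`.
#' @export
filter_bank <- function(seed = 1L, lambda = 450:650) {
  with_seed(seed, {
    centers <- seq(462, 642, length.out = 16) + stats::rnorm(16, 0, 2)
    widths <- 13 + stats::runif(16, -2, 2)
    amps <- 0.55 + stats::runif(16, -0.1, 0.15)
    leak_c <- centers + sample(c(-40, 40), 16, replace = TRUE)
    Tm <- sapply(1:16, function(k) {
      main <- amps[k] * exp(-(lambda - centers[k])^2 / (2 * widths[k]^2))
      leak <- 0.04 * amps[k] * exp(-(lambda - leak_c[k])^2 / (2 * (2.5 * widths[k])^2))
      pmin(main + leak, 1)
    })
    illum <- 0.15 + exp(-((lambda - 560) / 140)^2)
    structure(list(lambda = lambda, transmission = Tm, illumination = illum,
                   centers = centers, seed = seed),
              class = "filter_bank")
  })
}

#' Forward skin reflectance model
#'
#' Modified Beer-Lambert diffuse reflectance:
#' `R(lambda) = R_s(lambda) * exp(-L * (f_rbc * (so2 * mua_HbO2 + (1 - so2) * mua_Hb) + mel * mua_mel))`
#' with a slowly varying scattering baseline `R_s`, the embedded whole-blood
#' absorption curves, and a power-law melanin term. A single effective photon
#' path length `L` stands in for depth-resolved transport.
#'
#' @param params list with `L` (effective path length, mm), `f_rbc` (RBC
#'   tissue fraction; scalar or per-sample vector), `mel` (melanin fraction;
#'   scalar or vector), `scat` (scattering baseline amplitude at 550 nm).
#' @param so2 oxygen saturation fraction(s) in `[0, 1]`.
#' @param lambda wavelength grid (nm, 450-650).
#' @return length(so2) x length(lambda) matrix of reflectances in `(0, 1]`.
#' @export
forward_reflectance <- function(params, so2, lambda = 450:650) {
  if (any(so2 < 0 | so2 > 1)) stopf("so2 must lie in [0, 1]")
  n <- length(so2)
  f <- rep_len(params$f_rbc, n)
  m <- rep_len(params$mel, n)
  hb <- hemoglobin_absorption(lambda)
  Rs <- pmin(params$scat * (550 / lambda)^0.3, 1)
  att <- (params$L * f * so2) %o% hb$mua_hbo2 +
    (params$L * f * (1 - so2)) %o% hb$mua_hb +
    (params$L * m) %o% melanin_shape(lambda)
  sweep(exp(-att), 2, Rs, "*")
}

# Trapezoid quadrature weights on a (possibly non-uniform) grid.
trap_weights <- function(lambda) {
  n <- length(lambda)
  d <- diff(lambda)
  c(d[1] / 2, (d[-(n - 1)] + d[-1]) / 2, d[n - 1] / 2)
}

#' Sensor channel response
#'
#' Integrates a reflectance curve against each passband and the illumination
#' by trapezoid quadrature: `channel_c = integral R(lambda) T_c(lambda)
#' I(lambda) dlambda`. The white-reference response uses `R == 1`, so the
#' mosaic pipeline's white normalization recovers band-averaged reflectance.
#'
#' @param R reflectance curve(s): vector of length(lambda) or an N x
#'   length(lambda) matrix.
#' @param bank a [filter_bank()] on the same grid.
#' @return N x 16 matrix (or 16-vector) of channel responses.
#' @export
sensor_response <- function(R, bank) {
  if (is.null(dim(R))) {
    if (length(R) != length(bank$lambda)) stopf("grid mismatch")
    return(drop(matrix(R, 1) %*% (bank$transmission * bank$illumination *
                                    trap_weights(bank$lambda))))
  }
  if (ncol(R) != length(bank$lambda)) stopf("grid mismatch")
  R %*% (bank$transmission * bank$illumination * trap_weights(bank$lambda))
}

#' @rdname sensor_response
#' @export
white_response <- function(bank) {
  sensor_response(rep(1, length(bank$lambda)), bank)
}

#' Draw per-subject physiological parameters
#'
#' Baseline SO2 ~ N(56, 7^2)% clipped to `[39, 75]`; arterial end-occlusion
#' floor 0-3%; venous floor 18-49%; reperfusion peak 78-95%; exponential
#' decay/rebound time constants; optical parameters (effective path length,
#' RBC fraction, melanin, scattering) in ranges typical for volar forearm
#' skin of lightly pigmented subjects.
#'
#' @param seed subject seed.
#' @return List of class `subject_params`.
#' @export
subject_params <- function(seed = 1L) {
  with_seed(seed, {
    p <- list(
      so2_baseline = min(max(stats::rnorm(1, 56, 7), 39), 75),
      floor_arterial = stats::runif(1, 0, 3),
      floor_venous = stats::runif(1, 18, 49),
      peak_reperfusion = stats::runif(1, 78, 95),
      venous_rebound = stats::runif(1, 4, 12),
      tau_decay = stats::runif(1, 45, 70),
      tau_up = stats::runif(1, 3, 6),
      tau_relax = stats::runif(1, 50, 90),
      L = stats::runif(1, 1.0, 2.0),
      f_rbc = stats::runif(1, 0.008, 0.020),
      mel = stats::runif(1, 0.05, 0.20),
      scat = stats::runif(1, 0.5, 0.7),
      jitter_amp = stats::runif(2, 0.3, 0.8),
      jitter_period = stats::runif(2, 25, 120),
      jitter_phase = stats::runif(2, 0, 2 * pi),
      seed = seed)
    class(p) <- "subject_params"
    p
  })
}

#' True SO2 and RBC-fraction time course for an occlusion protocol
#'
#' Piecewise-smooth curves over the 9-min analysis window (occlusion at
#' `[60, 360]` s, post-release to 540 s): a baseline plateau, exponential
#' desaturation towards the provocation's floor during occlusion, a rapid
#' post-release overshoot (large for arterial reactive hyperemia, modest for
#' venous) relaxing back to baseline, plus slow physiological jitter. The RBC
#' tissue fraction rises during venous occlusion (pooling), dips slightly
#' during arterial occlusion, and peaks transiently during hyperemia.
#'
#' @param provocation `"arterial"` or `"venous"`.
#' @param params a [subject_params()].
#' @param t times in seconds (any subset of `[0, 540]`).
#' @param protocol list with `occl_start`, `occl_end` (defaults 60/360 s).
#' @return Data frame `t`, `so2` (%, in `[0, 100]`), `f_rbc`.
#' @export
occlusion_timecourse <- function(provocation = c("arterial", "venous"),
                                 params, t,
                                 protocol = list(occl_start = 60, occl_end = 360)) {
  provocation <- match.arg(provocation)
  t0 <- protocol$occl_start; t1 <- protocol$occl_end
  floor_ <- if (provocation == "arterial") params$floor_arterial else params$floor_venous
  peak <- if (provocation == "arterial") params$peak_reperfusion else
    min(params$so2_baseline + params$venous_rebound, 75)
  b <- params$so2_baseline
  so2 <- numeric(length(t))
  so2[t < t0] <- b
  occ <- t >= t0 & t < t1
  so2[occ] <- floor_ + (b - floor_) * exp(-(t[occ] - t0) / params$tau_decay)
  end_val <- floor_ + (b - floor_) * exp(-(t1 - t0) / params$tau_decay)
  post <- t >= t1
  u <- t[post] - t1
  g <- exp(-u / params$tau_relax) - exp(-u / params$tau_up)
  ustar <- log(params$tau_relax / params$tau_up) /
    (1 / params$tau_up - 1 / params$tau_relax)
  gmax <- exp(-ustar / params$tau_relax) - exp(-ustar / params$tau_up)
  so2[post] <- b + (end_val - b) * exp(-u / params$tau_up) +
    (peak - b) * g / gmax
  jit <- params$jitter_amp[1] * sin(2 * pi * t / params$jitter_period[1] +
                                      params$jitter_phase[1]) +
    params$jitter_amp[2] * sin(2 * pi * t / params$jitter_period[2] +
                                 params$jitter_phase[2])
  so2 <- pmin(pmax(so2 + jit, 0), 100)

  f0 <- params$f_rbc
  f <- rep(f0, length(t))
  if (provocation == "venous") {
    f[occ] <- f0 * (1 + 0.4 * (1 - exp(-(t[occ] - t0) / params$tau_decay)))
    f_end <- f0 * (1 + 0.4 * (1 - exp(-(t1 - t0) / params$tau_decay)))
    f[post] <- f0 + (f_end - f0) * exp(-u / 40)
  } else {
    f[occ] <- f0 * (1 - 0.15 * (1 - exp(-(t[occ] - t0) / params$tau_decay)))
    f[post] <- f0 * (1 + 0.5 * g / gmax)
  }
  data.frame(t = t, so2 = so2, f_rbc = f)
}
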