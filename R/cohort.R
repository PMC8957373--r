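# Cohort-level simulation: reference traces, sampled spectra, and (for the
# image pipeline) rendered mosaic frame series.

default_protocol <- function(cubes_per_provocation, t_end = 540) {
  list(occl_start = 60, occl_end = 360, t_end = t_end,
       cube_dt = t_end / cubes_per_provocation, ref_dt = 1)
}

# Site-mismatch modulation: the probe and ROI desaturate together at the
# extremes (arterial occlusion drives every site to ~0%), so the constant
# per-measurement offset is scaled by 4 p (1 - p), p = so2/100, which is ~1
# around baseline and vanishes at 0 and 100%.
site_modulation <- function(so2_pct) {
  p <- pmin(pmax(so2_pct / 100, 0), 1)
  4 * p * (1 - p)
}

#' Simulated point-probe reference trace
#'
#' Builds the 1-Hz reference series from the probe-site truth: the ROI truth
#' plus a constant site-mismatch offset (modulated towards zero at the SO2
#' extremes) plus Gaussian reference noise of the stated RMS.
#'
#' @param roi_curve function mapping times to true ROI SO2 (%).
#' @param t_end trace end time (s); samples at 0, 1, ..., t_end.
#' @param site_offset constant probe-vs-ROI offset for this measurement (%).
#' @param ref_noise_rms RMS deviation of the reference from the probe-site
#'   truth (default 5%).
#' @param seed noise seed.
#' @return Data frame `t`, `so2_true_probe`, `so2_ref`.
#' @export
reference_trace <- function(roi_curve, t_end = 540, site_offset = 0,
                       ref_noise_rms = 5, seed = 1L) {
  t <- 0:t_end
  truth_roi <- roi_curve(t)
  probe <- pmin(pmax(truth_roi + site_offset * site_modulation(truth_roi), 0), 100)
  ref <- probe + with_seed(seed, stats::rnorm(length(t), 0, ref_noise_rms))
  data.frame(t = t, so2_true_probe = probe, so2_ref = ref)
}

# Smooth positive multiplier field (rows x cols) for spatial heterogeneity:
# white lognormal noise averaged by a 3x3 box a few times.
smooth_field <- function(nr, nc, sd = 0.08, seed = 1L) {
  with_seed(seed, {
    z <- matrix(stats::rnorm(nr * nc, 0, sd * 3), nr, nc)
    for (it in 1:3) {
      zp <- rbind(z[1, ], z, z[nr, ])
      zp <- cbind(zp[, 1], zp, zp[, nc])
      z <- (zp[1:nr, 1:nc] + zp[1:nr, 2:(nc + 1)] + zp[1:nr, 3:(nc + 2)] +
              zp[2:(nr + 1), 1:nc] + zp[2:(nr + 1), 2:(nc + 1)] +
              zp[2:(nr + 1), 3:(nc + 2)] + zp[3:(nr + 2), 1:nc] +
              zp[3:(nr + 2), 2:(nc + 1)] + zp[3:(nr + 2), 3:(nc + 2)]) / 9
    }
    exp(z - mean(z))
  })
}

# Elliptical arm mask on the binned grid.
arm_mask <- function(nr, nc) {
  r <- (row(matrix(0, nr, nc)) - (nr + 1) / 2) / (0.48 * nr)
  c <- (col(matrix(0, nr, nc)) - (nc + 1) / 2) / (0.46 * nc)
  r^2 + c^2 <= 1
}

# Four quadrant ROIs centred on the binned grid (each nb/4 x nb/4 pixels).
quadrant_rois <- function(nr, nc) {
  q <- function(r0, r1, c0, c1, lab) roi(r0, r1, c0, c1, lab)
  r1 <- floor(nr / 4); r2 <- floor(nr / 2); r3 <- floor(3 * nr / 4)
  c1 <- floor(nc / 4); c2 <- floor(nc / 2); c3 <- floor(3 * nc / 4)
  list(ul = q(r1, r2, c1, c2, "ul"), ur = q(r1, r2, c2, c3, "ur"),
       ll = q(r2, r3, c1, c2, "ll"), lr = q(r2, r3, c2, c3, "lr"))
}

#' Render a synthetic mosaic measurement
#'
#' Produces raw mosaic frame series plus dark and white reference frames for
#' one subject and provocation: an elliptical arm on a dark background with
#' mild spatial heterogeneity in RBC fraction and melanin, imaged through the
#' filter bank with the mosaic layout, a fixed dark offset, and multiplicative
#' sensor noise; together with the reference trace, ground-truth SO2 maps and
#' the ROI set.
#'
#' @param params a [subject_params()].
#' @param provocation `"arterial"` or `"venous"`.
#' @param bank a [filter_bank()].
#' @param layout a [filter_layout()].
#' @param times cube acquisition times (s).
#' @param dims sensor dimensions (rows, cols); binned scene is `dims / 4`.
#' @param noise list: `sensor_sd` (multiplicative SD per summed frame,
#'   default 0.01), `dark_offset` (DN), `ref_noise_rms`, `site_sd` (%),
#'   `heterogeneity` (log-SD of the spatial RBC/melanin multiplier fields;
#'   0 renders a homogeneous arm).
#' @param seed measurement seed.
#' @return List: `frames` (list of [raw_mosaic_frame()]), `dark`, `white`,
#'   `trace`, `truth` (per-time list of binned SO2 maps), `timecourse`,
#'   `rois`, `mask` (binned arm mask), `probe_site`.
#' @export
render_measurement <- function(params, provocation, bank = filter_bank(),
                               layout = filter_layout(),
                               times = seq(0, 540, by = 5.4),
                               dims = c(64, 64),
                               noise = list(), seed = 1L) {
  noise <- utils::modifyList(list(sensor_sd = 0.01, dark_offset = 50,
                                  ref_noise_rms = 5, site_sd = 3,
                                  heterogeneity = 0.08), noise)
  nr <- dims[1] %/% 4; nc <- dims[2] %/% 4
  gain <- 1000
  mask <- arm_mask(nr, nc)
  u_frbc <- smooth_field(nr, nc, noise$heterogeneity, derive_seed(seed, 1))
  u_mel <- smooth_field(nr, nc, noise$heterogeneity, derive_seed(seed, 2))
  tc <- occlusion_timecourse(provocation, params, times)
  roi_curve <- function(t) occlusion_timecourse(provocation, params, t)$so2
  site_offset <- with_seed(derive_seed(seed, 3),
                           stats::rnorm(1, 0, noise$site_sd))
  trace <- reference_trace(roi_curve, t_end = max(times), site_offset = site_offset,
                      ref_noise_rms = noise$ref_noise_rms,
                      seed = derive_seed(seed, 4))

  wresp <- white_response(bank)
  # Mosaic band index per sensor pixel, precomputed once.
  band_at <- matrix(layout_band_at(layout,
                                   row(matrix(0, dims[1], dims[2])),
                                   col(matrix(0, dims[1], dims[2]))),
                    dims[1], dims[2])
  up <- function(m) m[rep(seq_len(nr), each = 4), rep(seq_len(nc), each = 4)]

  arm_idx <- which(mask)
  frames <- vector("list", length(times))
  truth <- vector("list", length(times))
  noise_seed <- derive_seed(seed, 5)
  k <- 0L
  for (i in seq_along(times)) {
    so2_i <- tc$so2[i] / 100
    fpar <- list(L = params$L, f_rbc = tc$f_rbc[i] * u_frbc[arm_idx],
                 mel = params$mel * u_mel[arm_idx], scat = params$scat)
    R <- forward_reflectance(fpar, rep(so2_i, length(arm_idx)), bank$lambda)
    ch <- sensor_response(R, bank)             # n_arm x 16
    planes <- array(0, c(nr, nc, 16))
    for (b in 1:16) {
      p <- matrix(0, nr, nc)
      p[arm_idx] <- ch[, b]
      planes[, , b] <- p
    }
    sens <- matrix(0, dims[1], dims[2])
    for (b in 1:16) {
      upb <- up(planes[, , b])
      sel <- band_at == b
      sens[sel] <- upb[sel]
    }
    vals <- sens * gain
    if (noise$sensor_sd > 0) {
      k <- k + 1L
      vals <- vals * (1 + with_seed(derive_seed(noise_seed, k),
                                    stats::rnorm(length(vals), 0, noise$sensor_sd)))
    }
    frames[[i]] <- raw_mosaic_frame(pmax(vals + noise$dark_offset, 0),
                                    layout = layout, timestamp = times[i])
    tm <- matrix(NA_real_, nr, nc)
    tm[arm_idx] <- tc$so2[i]
    truth[[i]] <- tm
  }
  dark <- raw_mosaic_frame(matrix(noise$dark_offset, dims[1], dims[2]),
                           layout = layout, timestamp = 0)
  wsens <- matrix(0, dims[1], dims[2])
  for (b in 1:16) wsens[band_at == b] <- wresp[b]
  wvals <- wsens * gain
  if (noise$sensor_sd > 0)
    wvals <- wvals * (1 + with_seed(derive_seed(noise_seed, 999999),
                                    stats::rnorm(length(wvals), 0, noise$sensor_sd)))
  white <- raw_mosaic_frame(wvals + noise$dark_offset, layout = layout,
                            timestamp = 0)
  list(frames = frames, dark = dark, white = white, trace = trace,
       truth = truth, timecourse = tc, rois = quadrant_rois(nr, nc),
       mask = mask, probe_site = c(row = floor(0.85 * nr), col = floor(nc / 2)),
       site_offset = site_offset)
}

#' Simulate a full occlusion cohort
#'
#' Generates the complete testbed: independent subject parameter draws, both
#' provocations per subject, reference traces with the configured RMS noise
#' and probe-site mismatch, and mean-normalised ROI pixel spectra paired with
#' the nearest-in-time reference sample. For speed, spectra are synthesised
#' directly from the forward model at sampled ROI pixel sites (the mosaic
#' render-and-preprocess round trip is validated separately and recovers the
#' same band reflectances).
#'
#' @param n_subjects number of subjects (>= 2; default 20).
#' @param seed master cohort seed; all per-subject randomness derives from it.
#' @param profile `"desk"` (100 cubes/provocation, 64 x 64 frames) or
#'   `"paper"` (756 cubes at 1.4 fps, 2048 x 1088 frames). Affects cube
#'   counts and nominal sensor dims only.
#' @param cubes_per_provocation override the profile's cube count.
#' @param n_pixels sampled pixels per cube (default 10).
#' @param sensor_noise multiplicative channel noise SD (default 0.01).
#' @param ref_noise_rms reference RMS deviation from probe truth (default 5%).
#' @param site_sd SD of the probe-vs-ROI site mismatch (default 3%).
#' @return Object of class `msi_cohort`: `spectra` (pooled [spectrum_set()]
#'   with subject/provocation/timestamp/target metadata), `traces`
#'   (per-subject, per-provocation reference traces), `truth` (ROI truth
#'   time courses), `params`, `bank`, `protocol`, `seed`.
#' @export
simulate_cohort <- function(n_subjects = 20L, seed = 1L,
                            profile = c("desk", "paper"),
                            cubes_per_provocation = NULL, n_pixels = 10L,
                            sensor_noise = 0.01, ref_noise_rms = 5,
                            site_sd = 3) {
  profile <- match.arg(profile)
  if (n_subjects < 2) stopf("need at least 2 subjects")
  cubes <- cubes_per_provocation %||% switch(profile, desk = 100L, paper = 756L)
  dims <- switch(profile, desk = c(64L, 64L), paper = c(1088L, 2048L))
  protocol <- default_protocol(cubes)
  bank <- filter_bank(derive_seed(seed, 1))
  wresp <- white_response(bank)
  nr <- dims[1] %/% 4; nc <- dims[2] %/% 4
  rois <- quadrant_rois(nr, nc)
  roi_near_probe <- rois$ll   # quadrant adjacent to the distal probe site
  roi_px <- roi_area(roi_near_probe)
  t_cubes <- protocol$cube_dt * (seq_len(cubes) - 1)

  sets <- list(); traces <- list(); truth <- list(); params <- list()
  for (k in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", k)
    sp <- subject_params(derive_seed(seed, 10 + k))
    params[[sid]] <- sp
    traces[[sid]] <- list(); truth[[sid]] <- list()
    for (prov in c("arterial", "venous")) {
      mseed <- derive_seed(seed, 1000 * k + (prov == "venous") * 500)
      tc <- occlusion_timecourse(prov, sp, t_cubes)
      roi_curve <- function(t) occlusion_timecourse(prov, sp, t)$so2
      site_offset <- with_seed(derive_seed(mseed, 3),
                               stats::rnorm(1, 0, site_sd))
      trace <- reference_trace(roi_curve, t_end = protocol$t_end,
                          site_offset = site_offset,
                          ref_noise_rms = ref_noise_rms,
                          seed = derive_seed(mseed, 4))
      traces[[sid]][[prov]] <- trace
      truth[[sid]][[prov]] <- tc

      n <- cubes * n_pixels
      draws <- with_seed(derive_seed(mseed, 5), {
        pix <- unlist(lapply(seq_len(cubes),
                             function(i) sample.int(roi_px, n_pixels)))
        list(pix = pix,
             u_frbc = exp(stats::rnorm(roi_px, 0, 0.08)),
             u_mel = exp(stats::rnorm(roi_px, 0, 0.08)),
             eps = matrix(stats::rnorm(n * 16, 0, sensor_noise), n, 16))
      })
      so2_s <- rep(tc$so2, each = n_pixels) / 100
      f_s <- rep(tc$f_rbc, each = n_pixels) * draws$u_frbc[draws$pix]
      m_s <- sp$mel * draws$u_mel[draws$pix]
      R <- forward_reflectance(list(L = sp$L, f_rbc = f_s, mel = m_s,
                                    scat = sp$scat),
                               so2_s, bank$lambda)
      ch <- sensor_response(R, bank)
      refl <- sweep(ch, 2, wresp, "/") * (1 + draws$eps)
      spec <- normalize_spectrum(refl)
      ts <- rep(t_cubes, each = n_pixels)
      idx <- nearest_index(ts, trace$t)
      sets[[length(sets) + 1]] <- spectrum_set(
        spec,
        data.frame(subject_id = sid, provocation = prov, timestamp_s = ts,
                   cube = rep(seq_len(cubes), each = n_pixels),
                   pixel = draws$pix,
                   target_so2 = trace$so2_ref[idx],
                   true_so2 = rep(tc$so2, each = n_pixels)))
    }
  }
  structure(list(spectra = bind_spectra(sets), traces = traces, truth = truth,
                 params = params, bank = bank, protocol = protocol,
                 rois = rois, dims = dims, seed = seed,
                 n_pixels = n_pixels,
                 noise = list(sensor_noise = sensor_noise,
                              ref_noise_rms = ref_noise_rms,
                              site_sd = site_sd)),
            class = "msi_cohort")
}

#' @export
print.msi_cohort <- function(x, ...) {
  cat(sprintf("synthetic MSI cohort: %d subjects, %d spectra, seed %s\n",
              length(x$params), n_spectra(x$spectra), format(x$seed)))
  invisible(x)
}

#' Write the cohort ground-truth manifest
#'
#' JSON manifest of subject parameters, per-measurement site offsets (via the
#' trace truth columns) and protocol settings; byte-identical under a fixed
#' cohort seed.
#'
#' @param cohort an [simulate_cohort()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(cohort, path) {
  manifest <- list(
    seed = cohort$seed, protocol = cohort$protocol, noise = cohort$noise,
    n_pixels = cohort$n_pixels,
    subjects = lapply(cohort$params, function(p) unclass(p)))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
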