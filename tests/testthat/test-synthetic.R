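test_that("forward reflectance follows the modified Beer-Lambert form", {
  lambda <- 450:650
  # no absorbers: reflectance equals the scattering baseline, any so2
  p0 <- list(L = 1.5, f_rbc = 0, mel = 0, scat = 0.6)
  R0 <- forward_reflectance(p0, 0.2, lambda)
  R1 <- forward_reflectance(p0, 0.9, lambda)
  expect_equal(R0, R1)
  expect_equal(drop(R0), pmin(0.6 * (550 / lambda)^0.3, 1))

  # doubling the path length squares the attenuation factor
  p <- list(L = 1, f_rbc = 0.015, mel = 0.1, scat = 0.6)
  p2 <- p; p2$L <- 2
  att1 <- forward_reflectance(p, 0.5, lambda) / drop(R0)
  att2 <- forward_reflectance(p2, 0.5, lambda) / drop(R0)
  expect_equal(drop(att2), drop(att1)^2, tolerance = 1e-12)

  expect_error(forward_reflectance(p, 1.2), "so2")
  expect_true(all(forward_reflectance(p, c(0, 0.5, 1)) > 0))
  expect_true(all(forward_reflectance(p, c(0, 0.5, 1)) <= 1))
})

test_that("oxy/deoxy curves cross at the tabulated isosbestic wavelengths", {
  lambda <- 450:650
  hb <- hemoglobin_absorption(lambda)
  # crossings of the embedded tables
  d <- hb$mua_hbo2 - hb$mua_hb
  cross_tab <- lambda[which(diff(sign(d)) != 0)]
  expect_gt(length(cross_tab), 2)

  # fully oxygenated vs fully deoxygenated reflectance curves cross within
  # 3 nm of each tabulated crossing
  p <- list(L = 1.5, f_rbc = 0.015, mel = 0.1, scat = 0.6)
  Rdiff <- drop(forward_reflectance(p, 1, lambda)) -
    drop(forward_reflectance(p, 0, lambda))
  cross_R <- lambda[which(diff(sign(Rdiff)) != 0)]
  for (cw in cross_tab)
    expect_lte(min(abs(cross_R - cw)), 3)
})

test_that("sensor response integrates passbands with a white reference", {
  bank <- filter_bank(4)
  w <- white_response(bank)
  expect_equal(sensor_response(rep(1, length(bank$lambda)), bank), w)
  half <- sensor_response(rep(0.5, length(bank$lambda)), bank)
  expect_equal(half / w, rep(0.5, 16))
  expect_error(sensor_response(rep(1, 10), bank), "grid")

  # transmissions in [0, 1]; adjacent passbands overlap
  expect_true(all(bank$transmission >= 0 & bank$transmission <= 1))
  ord <- order(bank$centers)
  for (k in 1:15) {
    a <- bank$transmission[, ord[k]]; b <- bank$transmission[, ord[k + 1]]
    expect_gt(sum(a * b), 0)
  }

  # identifiability floor: so2 = 0 vs 1 differ by > 1% relative L2 distance
  p <- list(L = 1.5, f_rbc = 0.015, mel = 0.1, scat = 0.6)
  ch <- sensor_response(forward_reflectance(p, c(0, 1)), bank)
  ch <- ch / rowMeans(ch)
  rel <- sqrt(sum((ch[1, ] - ch[2, ])^2)) / sqrt(sum(ch[1, ]^2))
  expect_gt(rel, 0.01)
})

test_that("occlusion time courses hit calibrated floors and peaks", {
  t <- 0:540
  for (k in 1:12) {
    sp <- subject_params(seed = 100 + k)
    art <- occlusion_timecourse("arterial", sp, t)
    ven <- occlusion_timecourse("venous", sp, t)
    expect_true(sp$so2_baseline >= 39 && sp$so2_baseline <= 75)
    # end of occlusion: arterial near its 0-3% floor, venous well above
    art_end <- mean(art$so2[t >= 300 & t <= 350])
    ven_end <- mean(ven$so2[t >= 300 & t <= 350])
    expect_lt(art_end, 8)
    expect_gt(ven_end, art_end + 5)
    expect_gt(ven_end, 14)
    # arterial reperfusion overshoot approaches the subject's peak
    expect_gt(max(art$so2[t > 360 & t < 420]), 72)
    # venous RBC pooling raises f_rbc during occlusion
    expect_gt(max(ven$f_rbc[t >= 300 & t < 360]), sp$f_rbc * 1.2)
    expect_true(all(art$so2 >= 0 & art$so2 <= 100))
  }
})

test_that("reference trace carries the configured noise and site mismatch", {
  sp <- subject_params(7)
  curve <- function(t) occlusion_timecourse("arterial", sp, t)$so2
  tr <- reference_trace(curve, site_offset = 0, ref_noise_rms = 5, seed = 3)
  rms <- sqrt(mean((tr$so2_ref - tr$so2_true_probe)^2))
  expect_equal(rms, 5, tolerance = 0.5)

  # site mismatch audit: baseline probe-vs-ROI offsets across measurements
  # have SD near the configured 3%
  co <- tiny_cohort()
  offs <- unlist(lapply(names(co$traces), function(s)
    lapply(co$traces[[s]], function(tr) {
      roi_truth <- co$truth[[s]][[
        if (identical(tr, co$traces[[s]]$arterial)) "arterial" else "venous"]]
      base <- tr$t <= 55
      mean(tr$so2_true_probe[base]) -
        mean(roi_truth$so2[roi_truth$t <= 55])
    })))
  expect_gt(sd(offs), 1.2)
  expect_lt(sd(offs), 5.5)
})

test_that("cohort generation is deterministic with audited spectrum counts", {
  co <- tiny_cohort()
  co2 <- simulate_cohort(n_subjects = 4, seed = 11, cubes_per_provocation = 30)
  expect_identical(co$spectra$spectra, co2$spectra$spectra)
  expect_identical(co$spectra$meta, co2$spectra$meta)

  dir <- withr::local_tempdir()
  m1 <- file.path(dir, "m1.json"); m2 <- file.path(dir, "m2.json")
  write_cohort_manifest(co, m1); write_cohort_manifest(co2, m2)
  expect_identical(readLines(m1), readLines(m2))

  # per-subject spectra count = provocations x cubes x pixels
  counts <- table(co$spectra$meta$subject_id)
  expect_true(all(counts == 2 * 30 * 10))
  expect_equal(rowMeans(co$spectra$spectra), rep(1, n_spectra(co$spectra)),
               tolerance = 1e-9)

  # pooled target histogram spans all ten bins, arterial dominating the tails
  W <- compute_weight_vector(co$spectra$meta$target_so2)
  expect_true(all(W$counts > 0))
  tails <- co$spectra$meta$target_so2 < 10 | co$spectra$meta$target_so2 > 90
  expect_gt(mean(co$spectra$meta$provocation[tails] == "arterial"), 0.8)
})

test_that("snapshot summation improves simulated SNR as sqrt(n)", {
  sp <- subject_params(9)
  ns <- list(sensor_sd = 0.04, heterogeneity = 0)
  mk <- function(seed) render_measurement(sp, "arterial", times = 100,
                                          dims = c(16, 16), noise = ns,
                                          seed = seed)$frames[[1]]
  frames <- lapply(1:16, mk)
  noiseless <- render_measurement(sp, "arterial", times = 100, dims = c(16, 16),
                                  noise = list(sensor_sd = 0, heterogeneity = 0),
                                  seed = 1)$frames[[1]]
  one_err <- sd(frames[[1]]$values - noiseless$values)
  sum_err <- sd(sum_snapshots(frames)$values / 16 - noiseless$values)
  # averaging 16 snapshots cuts noise ~4x
  expect_equal(one_err / sum_err, 4, tolerance = 1)
})
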