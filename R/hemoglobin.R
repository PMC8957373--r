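# Embedded chromophore absorption tables for the synthetic forward model.
# Molar extinction coefficients (cm^-1 / M) of oxy- and deoxyhemoglobin,
# coarsely resampled from standard published compilations at 5-10 nm spacing
# and linearly interpolated to the working 1 nm grid. The curves carry the
# features that matter for SO2 imaging in 450-650 nm: the oxyhemoglobin
# double peak near 542/577 nm, the single broad deoxy peak near 555 nm, and
# the crossing (isosbestic-like) points between them.

hb_table <- local({
  lambda <- c(450, 460, 470, 480, 490, 500, 510, 520, 530, 540, 550, 555,
              560, 570, 575, 580, 585, 590, 600, 610, 620, 630, 640, 650)
  eps_hbo2 <- c(62816, 44480, 33209, 26629, 23684, 20932, 20035, 24202,
                39956, 53236, 43016, 36000, 32613, 44496, 55540, 50104,
                31589, 14400, 3200, 1506, 942, 610, 442, 368)
  eps_hb <- c(103292, 86000, 66000, 47500, 31000, 22000, 24000, 30000,
              40500, 46500, 51000, 53412, 53000, 45072, 41500, 37020,
              32300, 26600, 14677, 9443, 6510, 5149, 4345, 3750)
  data.frame(lambda = lambda, eps_hbo2 = eps_hbo2, eps_hb = eps_hb)
})

#' Hemoglobin absorption spectra for whole blood
#'
#' Absorption coefficients (mm^-1) of fully oxygenated and fully
#' deoxygenated whole blood (150 g hemoglobin per litre, molar mass 64500
#' g/mol) on an arbitrary wavelength grid within 450-650 nm, interpolated
#' from the embedded extinction tables.
#'
#' @param lambda wavelengths in nm (450-650).
#' @return Data frame with columns `lambda`, `mua_hbo2`, `mua_hb` (mm^-1).
#' @export
hemoglobin_absorption <- function(lambda = 450:650) {
  if (any(lambda < 450 | lambda > 650))
    stopf("wavelengths must lie in 450-650 nm")
  # ln(10) * eps [cm^-1/M] * (150 g/L / 64500 g/mol) / 10 mm/cm
  k <- log(10) * (150 / 64500) / 10
  data.frame(
    lambda = lambda,
    mua_hbo2 = k * stats::approx(hb_table$lambda, hb_table$eps_hbo2, lambda)$y,
    mua_hb = k * stats::approx(hb_table$lambda, hb_table$eps_hb, lambda)$y)
}

# Normalised melanin absorption shape (1 at 550 nm), power-law decay.
melanin_shape <- function(lambda) (550 / lambda)^3.46
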