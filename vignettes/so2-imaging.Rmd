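---
title: "Estimating skin SO2 maps from snapshot mosaic multispectral images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating skin SO2 maps from snapshot mosaic multispectral images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the method

Snapshot multispectral imaging (MSI) cameras capture a full spectral data
cube in a single exposure through a repeating 4x4 mosaic of on-chip
interference filters: each sensor pixel sees exactly one of 16 spectral
bands in the 450-650 nm range. The filters have broad, overlapping and
sensor-specific passbands, which makes physics-based inversion of the
measured spectra (estimating hemoglobin oxygen saturation, SO2, from a
tissue optics model) fragile: small errors in the assumed filter
characteristics propagate directly into the estimates.

`oximap` implements the alternative strategy of *learning* the mapping from
measured 16-channel spectra to SO2 directly, by regressing against a
point-measuring reference probe recorded concurrently on the same skin
site. The training signal comes from occlusion provocations on the forearm:
an arterial occlusion drives tissue SO2 towards 0% with a reperfusion
overshoot towards 100% after cuff release, and a venous occlusion produces a
moderate decline with blood pooling. Together the two provocations cover
nearly the whole 0-100% range. A small feed-forward network (16 inputs, a
tanh hidden layer, linear output) then suffices, and because it is so small
it produces full SO2 maps in real time.

The package contains the complete pipeline:

1. **Mosaic preprocessing** (`dark_correct`, `demosaic_wbi`, `bin_spatial`,
   `white_normalize`, chained by `preprocess_frame`): raw 16-bit mosaic
   frames to reflectance cubes.
2. **Spectrum extraction** (`sample_roi_pixels`, `roi_mean_spectrum`,
   `normalize_spectrum`, `pair_reference`): mean-normalised spectra paired
   with the nearest-in-time reference sample.
3. **Error weighting** (`compute_weight_vector`, `lookup_weights`):
   inverse-frequency weights over 10% SO2 bins.
4. **Network training** (`init_ann`, `train_lm`): Levenberg-Marquardt with
   weighted mean-square error and validation-based early stopping.
5. **Evaluation** (`erms_w`, `loso_run`, `node_sweep`, `interval_summary`,
   `bland_altman`, `cohort_agreement`, `ablation_venous_only`): weighted RMS
   under leave-one-subject-out (LOSO) cross-validation, plus protocol-phase
   agreement analysis.
6. **A synthetic cohort simulator** (`simulate_cohort`,
   `render_measurement`): a full stand-in testbed, since suitable in vivo
   recordings are rarely shareable.

## Preprocessing choices

Raw frames are dark-corrected by subtracting an interleaved dark frame,
clamping negatives at zero (intensities are physical, and negative values
would propagate into negative reflectance). Demosaicing uses separable
weighted bilinear interpolation on each band's 4-strided native lattice:
the kernel is interpolating (native samples pass through unchanged), its
weights are convex, it reproduces affine intensity ramps exactly at
interior pixels, and it replicates the nearest native sample at the sensor
border. Published descriptions of mosaic-sensor pipelines rarely give the
kernel explicitly; this is the simplest kernel consistent with "weighted
bilinear interpolation" and it makes the preprocessing tests bit-stable.

Binning averages (rather than sums) 4x4 blocks so that the intensity scale
is independent of the binning factor; white normalization is a plain
elementwise ratio against a binned white-reference cube, with a hard error
(never a silent epsilon) on non-positive white values. The order is
demosaic, then bin, then white-normalize, matching the order in which these
steps are described for the real pipeline. Coordinates are row-major and
0-based with pixel (0,0) at the top-left; ROIs are half-open rectangles
`[row0, row1) x [col0, col1)`. Cubes persist as multi-page 32-bit float
TIFF stacks with a JSON sidecar (stage, band ids, timestamp, and an
intensity scale factor, since the TIFF writer stores values in [0, 1]).

## Spectra, targets and weights

Each spectrum is normalised to its mean intensity, cancelling illumination,
distance and exposure effects so that only spectral shape carries
information. Ten pixels per cube are sampled from the ROI nearest the probe,
uniformly without replacement within a cube and independently across cubes;
sampling more pixels adds little because spatially close pixels are highly
correlated. MSI cubes (~1.4 fps at full scale) are paired with the 1-Hz
reference by nearest timestamp, ties to the earlier sample; both signals
vary slowly relative to the 0.5 s maximum pairing error.

Occlusion protocols produce many more mid-range targets than extreme ones.
The error-weight vector counts targets in half-open 10% bins (`[k*10,
(k+1)*10)`, the last bin closed at 100; out-of-range targets clamp to the
end bins because reference values slightly below 0% do occur and should not
be discarded), takes 1/count per occupied bin and normalises the maximum
occupied weight to 1. Empty bins get weight 0 and a warning. The same
weights enter the training loss and the evaluation metric, so each 10% bin
contributes equally in expectation.

The weight vector is computed **once, globally**, from all subjects
including the left-out one. This mirrors a protocol in which the weights
are a fixed property of the whole study; it is a mild form of
train/evaluation leakage (bin counts only, not spectra), and
`loso_run(weight_scope = "train-only")` recomputes the weights per fold for
users who prefer strict hygiene. The venous-only ablation reuses the same
global weights rather than recomputing them from venous data alone.

## The network and its training

The model is `y = W2 tanh(W1 x + b1) + b2` with inputs and targets affinely
scaled to [-1, 1] (fitted on the training split; the scaling controls tanh
saturation and is stored with the model). Initialisation is layer-width
aware in the Nguyen-Widrow style, so hidden units start with their active
regions spread over the input range; distinct seeds give distinct networks,
which the repetition protocol relies on.

Training minimises the weighted mean-square error on a random
spectrum-level 70/15/15 train/validation/test split by Levenberg-Marquardt:
the residual Jacobian is computed analytically, the damped normal equations
`(J'J + mu I) delta = J'r` are solved each epoch, and `mu` shrinks by 0.1
on accepted steps and grows by 10 on rejected ones (start 1e-3, ceiling
1e10). Weights enter as residual scaling by `sqrt(w)` -- the standard
error-weight mechanism, and the only one consistent with the weighted RMS
metric. Training stops after 6 consecutive validation-loss increases, at
1000 epochs, at a gradient floor of 1e-7, or at the `mu` ceiling, and the
returned model is the one with the best validation loss. With uniform
weights, weighted and unweighted training are identical given the same
seeds.

Predictions are **not** clipped to [0, 100]: the reference itself takes
slightly out-of-range values, and clipping would bias the agreement
statistics. `predict_map` applies the network per foreground pixel
(mean-normalising each pixel's spectrum first); a 512 x 272 map with a
3-node network takes a fraction of a second.

## Evaluation protocol

`erms_w` is the weighted RMS `sqrt(sum(w (y - yhat)^2) / sum(w))`.
`loso_run` holds each subject out entirely, trains on the remaining
subjects' pooled spectra and evaluates on the untouched subject (the report
carries a per-fold audit of training subject ids and pool sizes, and the
test suite asserts the left-out subject never leaks). The hidden-layer size
is chosen by the mean evaluation error across folds in `node_sweep`
(sizes 1, 2, 3, 4, 5, 7, 10, 15, 20 with 10 re-initialised repetitions at
full scale); 3 nodes is the package default, and downstream analyses use
the first repetition of the 3-node model.

Agreement with the reference is analysed per protocol phase: baseline
(60 s to 5 s before occlusion), end of occlusion (60 s to 10 s before cuff
release) and early after release (5 s before to 55 s after release). The
first two phase values are window means. The release value must capture a
steep transient, so it is the median of nine reference-rate samples centred
on the reference peak within the window (the peak is located on the
reference only, and the prediction series is read at the same nine
timestamps -- matching samples, not matching peaks; the nine-sample window
is the peak index +/- 4, truncated with a warning at window edges).
`bland_altman` reports the mean difference (prediction minus reference) and
limits of agreement at +/- 1.96 sample (n-1) standard deviations.

## What the simulator emulates

`simulate_cohort` generates the full study: per-subject physiology and
optics, both provocations, reference traces and sampled spectra.

* **Forward optics**: modified Beer-Lambert reflectance with a single
  effective path length (1-2 mm), RBC tissue fraction 0.8-2%, melanin
  0.05-0.2 and a slowly varying scattering baseline, using embedded
  oxy/deoxyhemoglobin absorption tables (coarse resampling of standard
  published values) that carry the 540/560/577 nm band structure and
  isosbestic crossings. This is deliberately far simpler than layered
  Monte-Carlo skin optics: the learning method under test is agnostic to
  the true optics, and the simulator only needs a realistic, identifiable
  sensor-to-SO2 relationship.
* **The sensor**: 16 Gaussian-like passbands (centres ~462-642 nm, widths
  ~13 nm) with a weak broad leak lobe and per-sensor random perturbations,
  behind a smooth broadband illuminant; adjacent passbands overlap
  substantially. Channel responses are trapezoid integrals of reflectance x
  transmission x illumination; white normalization against the `R = 1`
  response recovers band-averaged reflectance.
* **Time courses**: baseline plateau ~N(56, 7^2)% clipped to [39, 75];
  exponential desaturation to a floor of 0-3% (arterial) or 18-49%
  (venous) with a 45-70 s time constant; post-release overshoot to 78-95%
  (arterial) or a modest rebound (venous) relaxing back to baseline; RBC
  fraction pooling during venous occlusion and transient hyperemia after
  arterial release; two slow sinusoidal jitter components (~0.3-0.8%).
  These ranges were calibrated once against the phase statistics a healthy
  forearm cohort exhibits (baseline ~56 +/- 10%, arterial end-occlusion
  ~0-5%, reperfusion peak up to ~96%).
* **The reference**: probe-site truth plus Gaussian noise with 5% RMS at
  1 Hz. The probe sits near, but not in, the sampled ROI; a per-measurement
  constant offset (SD 3%) models the site mismatch. The offset is modulated
  by `4 p (1 - p)` (p = SO2/100) so that it vanishes at the physiological
  extremes -- during a full arterial occlusion every nearby site
  desaturates to ~0%, so a constant site offset there would be
  unphysiological. The audit of the mismatch is therefore made at baseline.
* **Sensor noise**: multiplicative Gaussian, SD 1% per summed measurement.

Spectra for cohort-scale runs are synthesised directly from the forward
model at sampled ROI pixel sites (with static per-pixel RBC/melanin
heterogeneity fields); `render_measurement` produces actual mosaic frame
series (elliptical arm on a dark background, dark offset, white reference),
and the test suite verifies that the preprocessing chain recovers the
forward model's band reflectances from noiseless frames to 1e-6, so the
two paths agree.

**What the simulator does not emulate**: vendor-specific filter calibration files,
layered skin structure and depth-dependent sampling, specular artefacts,
motion and ROI tracking, melanin-rich (Fitzpatrick IV-VI) skin, vessels or
saturated pixels inside the ROI, and drift in either instrument. Passing
the synthetic acceptance analyses therefore demonstrates that the pipeline
is correct and that the protocol behaves as described -- not that any given
camera will reach the same accuracy in vivo.

## Problem sizes and reproducibility

The default "desk" profile uses 20 subjects, 100 cubes per provocation, 10
pixels per cube (40,000 spectra; LOSO training pools of 38,000) and 64 x 64
px frames; these sizes were chosen so a full LOSO run completes in a few
minutes on one CPU while keeping per-fold pools large relative to the
55-parameter model. The "paper" profile (756 cubes per provocation at
1.4 fps, 2048 x 1088 px frames) reproduces the full acquisition geometry.
All randomness flows from a single cohort seed through documented
per-subject, per-measurement sub-seeds; cohorts, splits, initialisations
and therefore whole reports are bit-reproducible given the seed.

With 5%-RMS reference noise, ~3% site mismatch and 1% sensor noise, the
evaluation error floor is roughly `sqrt(5^2 + 3^2) ~ 5.8%`; the observed
desk-scale mean LOSO weighted RMS of ~8% sits sensibly above it (model
error across subjects and sensor noise account for the rest), and no
predictor evaluated against the noisy reference can do materially better
than the floor.

## Known limitations

* The LM trainer forms dense `J'J` normal equations -- ideal for the
  55-550 parameter networks used here, unsuitable for much larger ones.
* Networks are sensor-specific by design: a model trained on one filter
  bank does not transfer to another (`filter_bank` seeds emulate this
  sensor individuality).
* Bland-Altman analysis assumes one paired value per subject and phase;
  repeated-measures extensions are out of scope.
* The venous-only ablation shares the global weight vector with the full
  analysis; bins that venous data never reaches still influence training
  only through their (zero-count) absence.
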