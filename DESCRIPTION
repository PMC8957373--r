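Package: oximap
Title: Skin Hemoglobin Oxygen Saturation Imaging from Snapshot Multispectral Mosaic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating skin hemoglobin oxygen saturation (SO2) maps
    from snapshot multispectral imaging (MSI) data acquired with a 4x4
    filter-mosaic sensor. Implements the sensor preprocessing chain (dark
    correction, weighted bilinear demosaicing, spatial binning, white
    normalization), mean-intensity spectrum normalization and ROI sampling,
    inverse-frequency error weighting over SO2 bins, a shallow feed-forward
    network (16 inputs, tanh hidden layer, linear output) trained by
    Levenberg-Marquardt with weighted mean-square error and validation-based
    early stopping, leave-one-subject-out evaluation with a weighted RMS
    metric, Bland-Altman agreement analysis over occlusion-protocol phases,
    and pixelwise SO2 mapping. A synthetic occlusion-cohort simulator
    (forward Beer-Lambert skin model, overlapping sensor passbands, sensor
    noise, and a noisy point-probe reference trace) provides a complete
    testbed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
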