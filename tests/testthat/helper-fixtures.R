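# Shared fixtures, built in code at test time.

# Constant-valued raw frame.
const_frame <- function(value, nr = 8, nc = 8, layout = filter_layout()) {
  raw_mosaic_frame(matrix(value, nr, nc), layout = layout)
}

# Reflectance cube filled with one spectrum at every pixel.
uniform_cube <- function(spectrum, nr = 8, nc = 8) {
  v <- array(NA_real_, c(nr, nc, length(spectrum)))
  for (b in seq_along(spectrum)) v[, , b] <- spectrum[b]
  data_cube(v, stage = "reflectance")
}

# Tiny cached cohort shared across test files (generated once per run).
.fixture_env <- new.env(parent = emptyenv())

tiny_cohort <- function() {
  if (is.null(.fixture_env$tiny))
    .fixture_env$tiny <- simulate_cohort(n_subjects = 4, seed = 11,
                                         cubes_per_provocation = 30)
  .fixture_env$tiny
}

# A quick training configuration for bookkeeping-style tests where only the
# control flow (not the fit quality) matters.
quick_cfg <- function(seed = 1) {
  training_config(max_epochs = 3, seed = seed)
}
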