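#' Inverse-frequency error weights over 10% SO2 bins
#'
#' Occlusion protocols produce targets that pile up near the baseline
#' plateau; inverse-frequency weights level out the contribution of each 10%
#' SO2 interval to the training loss and to the weighted RMS metric.
#'
#' Bins are half-open `[10k, 10(k+1))` for k = 0..9 with the last bin closed
#' at 100; targets below 0 fall in the first bin and above 100 in the last
#' (slightly out-of-range reference values occur and are not discarded).
#' Weights are `1/count` per occupied bin, normalised so the maximum occupied
#' bin weight is 1; empty bins get weight 0.
#'
#' @param targets numeric vector of target SO2 values in percent.
#' @return An object of class `weight_vector` with fields `bin_edges` (0, 10,
#'   ..., 100), `counts` (length 10) and `weights` (length 10, in `[0, 1]`).
#' @export
compute_weight_vector <- function(targets) {
  targets <- targets[is.finite(targets)]
  if (length(targets) == 0) stopf("no finite targets to bin")
  bins <- so2_bin(targets)
  counts <- tabulate(bins, nbins = 10L)
  w <- ifelse(counts > 0, 1 / counts, 0)
  w <- w / max(w)
  if (any(counts == 0))
    warning(sprintf("empty SO2 bin(s): %s",
                    paste(which(counts == 0) - 1L, collapse = ", ")))
  structure(list(bin_edges = seq(0, 100, by = 10), counts = counts,
                 weights = w),
            class = "weight_vector")
}

# Bin index 1..10 for SO2 targets in percent.
so2_bin <- function(targets) {
  pmin(pmax(floor(targets / 10), 0), 9) + 1L
}

#' Per-sample weight lookup
#'
#' Maps each target to the weight of its 10% bin.
#'
#' @param W a [compute_weight_vector()] result.
#' @param targets numeric vector of target SO2 values in percent.
#' @return Numeric vector of weights in `[0, 1]`.
#' @export
lookup_weights <- function(W, targets) {
  b <- so2_bin(targets)
  w <- W$weights[b]
  if (any(w == 0))
    warning("some targets fall in empty bins and receive weight 0")
  w
}

#' @export
print.weight_vector <- function(x, ...) {
  cat("SO2 bin weights (inverse frequency, max-normalised):\n")
  print(data.frame(bin_lo = x$bin_edges[-11], bin_hi = x$bin_edges[-1],
                   count = x$counts, weight = round(x$weights, 4)))
  invisible(x)
}

#' Persist a weight vector as a 10-row table
#' @param W a `weight_vector`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_weight_vector <- function(W, path) {
  utils::write.csv(data.frame(bin_lo = W$bin_edges[-11],
                              bin_hi = W$bin_edges[-1],
                              count = W$counts, weight = W$weights),
                   path, row.names = FALSE)
  invisible(path)
}
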