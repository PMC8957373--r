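# Protocol-phase agreement analysis: per-subject phase values over the
# occlusion protocol and Bland-Altman statistics across subjects.

#' Protocol phase windows
#'
#' The three analysis windows relative to the occlusion protocol: baseline
#' (60 s to 5 s before occlusion starts), end of occlusion (60 s to 10 s
#' before occlusion ends) and early after release (5 s before until 55 s
#' after release).
#'
#' @param protocol list with `occl_start` and `occl_end` times in seconds.
#' @return Named list of `c(from, to)` windows (seconds, closed intervals).
#' @export
phase_windows <- function(protocol) {
  list(baseline = c(protocol$occl_start - 60, protocol$occl_start - 5),
       end_occlusion = c(protocol$occl_end - 60, protocol$occl_end - 10),
       release = c(protocol$occl_end - 5, protocol$occl_end + 55))
}

window_mean <- function(series, value_col, win) {
  keep <- series$t >= win[1] & series$t <= win[2]
  if (!any(keep)) return(NA_real_)
  mean(series[[value_col]][keep])
}

#' Per-subject phase values
#'
#' Baseline and end-of-occlusion values are window means per method. In the
#' release window the SO2 rise is steep, so the release value is the median
#' of nine samples around the reference peak: the peak is located on the
#' reference series, the nine reference timestamps (peak index +/- 4,
#' truncated at the window edges) are fixed, and each method is read at those
#' same timestamps (the prediction series at its nearest sample times).
#'
#' @param series_pred data frame `t`, `so2_ann`: per-cube predictions.
#' @param series_ref data frame `t`, `so2_ref`: the 1-Hz reference trace.
#' @param protocol list with `occl_start`, `occl_end` (s).
#' @return Data frame with columns `phase`, `pred`, `ref` (one row per
#'   phase); phases without samples are `NA` (flagged with a warning).
#' @export
interval_summary <- function(series_pred, series_ref, protocol) {
  wins <- phase_windows(protocol)
  base_p <- window_mean(series_pred, "so2_ann", wins$baseline)
  base_r <- window_mean(series_ref, "so2_ref", wins$baseline)
  end_p <- window_mean(series_pred, "so2_ann", wins$end_occlusion)
  end_r <- window_mean(series_ref, "so2_ref", wins$end_occlusion)

  in_rel <- which(series_ref$t >= wins$release[1] & series_ref$t <= wins$release[2])
  if (length(in_rel) == 0) {
    warning("release window contains no reference samples")
    rel_p <- rel_r <- NA_real_
  } else {
    peak <- in_rel[which.max(series_ref$so2_ref[in_rel])]
    lo <- max(peak - 4L, in_rel[1]); hi <- min(peak + 4L, in_rel[length(in_rel)])
    if (hi - lo < 8L)
      warning("release peak window truncated at a window edge")
    idx <- lo:hi
    rel_r <- stats::median(series_ref$so2_ref[idx])
    pidx <- nearest_index(series_ref$t[idx], series_pred$t)
    rel_p <- stats::median(series_pred$so2_ann[pidx])
  }
  if (anyNA(c(base_p, base_r, end_p, end_r)))
    warning("a phase window contains no samples")
  data.frame(phase = c("baseline", "end_occlusion", "release"),
             pred = c(base_p, end_p, rel_p),
             ref = c(base_r, end_r, rel_r))
}

#' Bland-Altman agreement statistics
#'
#' Paired differences `d = a - b` (by convention, prediction minus
#' reference): bias is `mean(d)` and the limits of agreement are
#' `bias +/- 1.96 * SD(d)` with the sample (n-1) standard deviation.
#'
#' @param a,b paired per-subject values (equal length >= 2).
#' @return List with `bias`, `sd`, `lower`, `upper`, `differences`, `means`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    stopf("Bland-Altman needs at least 2 pairs of equal length")
  d <- a - b
  s <- stats::sd(d)
  list(bias = mean(d), sd = s,
       lower = mean(d) - 1.96 * s, upper = mean(d) + 1.96 * s,
       differences = d, means = (a + b) / 2)
}

#' Cohort agreement analysis over protocol phases
#'
#' Computes per-subject phase values ([interval_summary()]) for every fold's
#' arterial prediction series against that subject's reference trace, then
#' Bland-Altman statistics (prediction minus reference) per phase, plus a
#' summary table in `mean (SD) [max min]` layout for each method and phase.
#'
#' @param report an [loso_run()] report.
#' @param cohort the cohort the report was computed from.
#' @return List with `per_subject` (long data frame of phase values),
#'   `bland_altman` (per-phase statistics) and `summary` (per phase/method
#'   mean, sd, max, min).
#' @export
cohort_agreement <- function(report, cohort) {
  rows <- list()
  for (s in names(report$series)) {
    tr <- cohort$traces[[s]][["arterial"]]
    ph <- interval_summary(report$series[[s]], tr, cohort$protocol)
    ph$subject <- s
    rows[[s]] <- ph
  }
  per_subject <- do.call(rbind, rows)
  row.names(per_subject) <- NULL
  ba <- lapply(split(per_subject, per_subject$phase),
               function(d) bland_altman(d$pred, d$ref))
  summ <- do.call(rbind, lapply(split(per_subject, per_subject$phase), function(d)
    data.frame(phase = d$phase[1],
               method = c("ann", "reference"),
               mean = c(mean(d$pred), mean(d$ref)),
               sd = c(stats::sd(d$pred), stats::sd(d$ref)),
               max = c(max(d$pred), max(d$ref)),
               min = c(min(d$pred), min(d$ref)))))
  row.names(summ) <- NULL
  list(per_subject = per_subject, bland_altman = ba, summary = summ)
}
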