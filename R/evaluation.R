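#' Weighted RMS error
#'
#' The performance metric for SO2 regression:
#' `sqrt( sum(w * (y - yhat)^2) / sum(w) )`, with weights from the
#' inverse-frequency bin vector levelling the uneven target distribution.
#' With uniform weights it reduces to the plain RMS error.
#'
#' @param y_true,y_pred numeric vectors of equal length (%).
#' @param weights nonnegative weights, not all zero (default uniform).
#' @return Scalar weighted RMS error in percent.
#' @export
erms_w <- function(y_true, y_pred, weights = rep(1, length(y_true))) {
  if (length(y_true) != length(y_pred) || length(weights) != length(y_true))
    stopf("y_true, y_pred and weights must have equal length")
  if (any(weights < 0) || sum(weights) <= 0)
    stopf("weights must be nonnegative and not all zero")
  sqrt(sum(weights * (y_true - y_pred)^2) / sum(weights))
}

#' Protocol bookkeeping
#'
#' Closed-form spectrum counts for the acquisition/training protocol: with
#' `n_subjects` subjects, `cubes_per_provocation` cubes for each of
#' `n_provocations` provocations and `n_pixels` sampled pixels per cube, each
#' subject contributes `cubes * provocations * pixels` spectra and one
#' leave-one-subject-out fold pools the remaining subjects' spectra.
#'
#' @param n_subjects,cubes_per_provocation,n_provocations,n_pixels protocol
#'   counts.
#' @param sweep_sizes hidden-layer sizes of the node sweep.
#' @param sweep_reps repetitions per size.
#' @return List with `spectra_per_subject`, `loso_pool`,
#'   `models_per_fold` (sizes x reps).
#' @export
protocol_counts <- function(n_subjects = 20L, cubes_per_provocation = 760L,
                            n_provocations = 2L, n_pixels = 10L,
                            sweep_sizes = c(1, 2, 3, 4, 5, 7, 10, 15, 20),
                            sweep_reps = 10L) {
  per_subject <- cubes_per_provocation * n_provocations * n_pixels
  list(spectra_per_subject = per_subject,
       loso_pool = (n_subjects - 1L) * per_subject,
       models_per_fold = length(sweep_sizes) * sweep_reps)
}

# Train one LOSO fold and evaluate on the left-out subject.
fit_fold <- function(cohort, leave_out, n_hidden, cfg, W,
                     init_seed, train_provocation = NULL,
                     eval_provocation = NULL) {
  meta <- cohort$spectra$meta
  tr_idx <- meta$subject_id != leave_out
  if (!is.null(train_provocation))
    tr_idx <- tr_idx & meta$provocation %in% train_provocation
  ev_idx <- meta$subject_id == leave_out
  if (!is.null(eval_provocation))
    ev_idx <- ev_idx & meta$provocation %in% eval_provocation
  if (!any(ev_idx)) return(NULL)

  train_set <- subset_spectra(cohort$spectra, tr_idx)
  train_set$meta$weight <- lookup_weights(W, train_set$meta$target_so2)
  model <- init_ann(n_hidden, seed = init_seed)
  model <- train_lm(model, train_set, cfg)

  eval_set <- subset_spectra(cohort$spectra, ev_idx)
  pred <- ann_forward(model, eval_set$spectra)
  w_ev <- lookup_weights(W, eval_set$meta$target_so2)
  list(model = model,
       erms = c(train = sqrt(model$loss_pct2[["train"]]),
                val = sqrt(model$loss_pct2[["val"]]),
                test = sqrt(model$loss_pct2[["test"]]),
                evaluation = erms_w(eval_set$meta$target_so2, pred, w_ev)),
       eval_meta = eval_set$meta, eval_pred = pred,
       train_subjects = unique(train_set$meta$subject_id),
       n_train = n_spectra(train_set))
}

# Per-cube mean prediction series for one subject/provocation (mean over the
# sampled pixels of each cube).
fold_series <- function(fold, provocation = "arterial") {
  keep <- fold$eval_meta$provocation == provocation
  t <- fold$eval_meta$timestamp_s[keep]
  p <- fold$eval_pred[keep]
  agg <- tapply(p, t, mean)
  data.frame(t = as.numeric(names(agg)), so2_ann = as.numeric(agg))
}

#' Leave-one-subject-out evaluation
#'
#' For each subject, trains a network on the pooled spectra of all other
#' subjects (internal random 70/15/15 split) and evaluates the weighted RMS
#' error on the untouched left-out subject, using a single global
#' inverse-frequency weight vector for both training and evaluation. Also
#' records, per fold, the per-cube mean prediction time series during
#' arterial occlusion for downstream agreement analysis.
#'
#' @param cohort an [simulate_cohort()] cohort (or any object with the same
#'   `spectra`, `traces`, `protocol` fields).
#' @param n_hidden hidden-layer size (default 3).
#' @param cfg a [training_config()].
#' @param seed master seed; per-fold split and initialisation seeds are
#'   derived from it.
#' @param weight_scope `"global"` computes the weight vector from all
#'   subjects including the left-out one (mirroring a protocol in which the
#'   weights are fixed once for the whole cohort); `"train-only"` recomputes
#'   it per fold from the training subjects only.
#' @param train_provocation optional provocations to train on (e.g.
#'   `"venous"` for the restricted-range ablation); default both.
#' @param eval_provocation optional provocations to evaluate the weighted RMS
#'   on; default all left-out data.
#' @return An object of class `evaluation_report`: `folds` (per-subject
#'   train/val/test/evaluation weighted RMS), `series` (per-subject arterial
#'   prediction series), `models`, `W`, `n_hidden`.
#' @export
loso_run <- function(cohort, n_hidden = 3L, cfg = training_config(),
                     seed = 1L, weight_scope = c("global", "train-only"),
                     train_provocation = NULL, eval_provocation = NULL) {
  weight_scope <- match.arg(weight_scope)
  subjects <- unique(cohort$spectra$meta$subject_id)
  if (length(subjects) < 3) stopf("LOSO needs at least 3 subjects")
  W_global <- compute_weight_vector(cohort$spectra$meta$target_so2)

  folds <- list(); series <- list(); models <- list(); audit <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    W <- if (weight_scope == "global") W_global else
      compute_weight_vector(
        cohort$spectra$meta$target_so2[cohort$spectra$meta$subject_id != s])
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(seed, i)
    fold <- fit_fold(cohort, s, n_hidden, cfg_i, W,
                     init_seed = derive_seed(seed, 1000 + i),
                     train_provocation = train_provocation,
                     eval_provocation = eval_provocation)
    if (is.null(fold)) {
      warning(sprintf("subject %s has no evaluation data; fold skipped", s))
      next
    }
    folds[[s]] <- fold$erms
    series[[s]] <- fold_series(fold, "arterial")
    models[[s]] <- fold$model
    audit[[s]] <- list(train_subjects = fold$train_subjects,
                       n_train = fold$n_train)
  }
  folds_df <- data.frame(subject = names(folds),
                         do.call(rbind, folds), row.names = NULL)
  structure(list(folds = folds_df, series = series, models = models,
                 audit = audit, W = W_global, n_hidden = n_hidden,
                 train_provocation = train_provocation),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("LOSO evaluation report: %d folds, H = %d\n",
              nrow(x$folds), x$n_hidden))
  cat(sprintf("mean evaluation Erms,W = %.2f%% (SD %.2f%%)\n",
              mean(x$folds$evaluation), stats::sd(x$folds$evaluation)))
  invisible(x)
}

#' Hidden-layer size sweep
#'
#' Trains networks over a grid of hidden-layer sizes with several
#' re-initialised repetitions per size on each LOSO fold, recording the
#' weighted RMS on the internal test split and on the left-out evaluation
#' data.
#'
#' @inheritParams loso_run
#' @param sizes hidden-layer sizes to sweep.
#' @param reps re-initialised repetitions per size.
#' @param subjects optional subset of fold subjects (default: all).
#' @return List with `table` (subject x size x rep rows) and `summary` (mean
#'   and SD of evaluation and test weighted RMS per size).
#' @export
node_sweep <- function(cohort, sizes = c(1, 2, 3, 4, 5, 7, 10, 15, 20),
                       reps = 10L, cfg = training_config(), seed = 1L,
                       subjects = NULL) {
  all_subj <- unique(cohort$spectra$meta$subject_id)
  subjects <- subjects %||% all_subj
  W <- compute_weight_vector(cohort$spectra$meta$target_so2)
  rows <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(seed, i)
    for (h in sizes) for (r in seq_len(reps)) {
      fold <- fit_fold(cohort, s, h, cfg_i, W,
                       init_seed = derive_seed(seed, i * 100000 + h * 100 + r))
      rows[[length(rows) + 1]] <-
        data.frame(subject = s, size = h, rep = r,
                   erms_test = fold$erms[["test"]],
                   erms_eval = fold$erms[["evaluation"]])
    }
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$size), function(d)
    data.frame(size = d$size[1],
               eval_mean = mean(d$erms_eval), eval_sd = stats::sd(d$erms_eval),
               test_mean = mean(d$erms_test), test_sd = stats::sd(d$erms_test))))
  row.names(summ) <- NULL
  list(table = tab, summary = summ)
}

#' Venous-only training ablation
#'
#' Trains each LOSO fold on venous-occlusion spectra only (with the same
#' global weight vector) and evaluates on the left-out subject's arterial
#' data, which spans both lower and higher SO2 than the restricted training
#' range. Used to demonstrate that training data must cover the full target
#' range.
#'
#' @inheritParams loso_run
#' @return An `evaluation_report` (evaluation weighted RMS computed on
#'   arterial data only).
#' @export
ablation_venous_only <- function(cohort, n_hidden = 3L,
                                 cfg = training_config(), seed = 1L) {
  provs <- unique(cohort$spectra$meta$provocation)
  if (!all(c("arterial", "venous") %in% provs))
    stopf("ablation needs both provocations in the cohort")
  loso_run(cohort, n_hidden = n_hidden, cfg = cfg, seed = seed,
           train_provocation = "venous", eval_provocation = "arterial")
}
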