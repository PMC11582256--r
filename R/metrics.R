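#' Reconstruction error metrics
#'
#' `mae()` is the mean absolute difference, `rmse()` the root mean squared
#' difference. Both require identically shaped images and are zero iff the
#' images agree (rmse >= mae always, by Jensen's inequality).
#'
#' @param x,y real matrices of the same shape.
#' @return scalar.
#' @export
mae <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  mean(abs(x - y))
}

#' @rdname mae
#' @export
rmse <- function(x, y) {
  if (!all(dim(x) == dim(y))) stop("shape mismatch")
  sqrt(mean((x - y)^2))
}

#' Paired t-test between per-subject metric vectors
#'
#' Two-sided paired t-test on the per-subject differences (pairing by test
#' subject), as used to compare reconstruction experiments. Degenerate
#' inputs with zero difference variance are flagged rather than tested.
#'
#' @param metric_a,metric_b numeric vectors of equal length >= 2, one entry
#'   per subject, in the same subject order.
#' @return list with `statistic`, `p_value`, `mean_difference`, and
#'   `degenerate` (TRUE when the differences have zero variance, in which
#'   case `statistic` and `p_value` are `NA`).
#' @export
paired_ttest <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b)) stop("length mismatch")
  if (length(metric_a) < 2L) stop("need at least 2 paired subjects")
  d <- metric_a - metric_b
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(metric_a, metric_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_difference = mean(d), degenerate = FALSE)
}

#' Per-experiment result record
#'
#' @param subject_metrics data frame with columns `subject`, `mae`, `rmse`,
#'   `mssim` (one row per test subject).
#' @param run_id integer repetition index.
#' @param mode training data-source mode.
#' @param train_size number of (magnitude) training scans.
#' @param augmented logical, whether augmentation was used.
#' @param validation_mssim mean validation mSSIM used for model selection.
#' @return object of class `experiment_result`.
#' @export
experiment_result <- function(subject_metrics, run_id, mode, train_size,
                              augmented, validation_mssim) {
  stopifnot(is.data.frame(subject_metrics),
            all(c("subject", "mae", "rmse", "mssim") %in% names(subject_metrics)),
            all(subject_metrics$mae >= 0), all(subject_metrics$rmse >= 0),
            all(abs(subject_metrics$mssim) <= 1))
  structure(list(subject_metrics = subject_metrics, run_id = run_id,
                 mode = mode, train_size = train_size, augmented = augmented,
                 validation_mssim = validation_mssim),
            class = "experiment_result")
}

#' Select the repetition with the best validation mSSIM
#'
#' Argmax of the recorded validation mSSIM; ties are broken by the lowest
#' run id.
#'
#' @param results nonempty list of [experiment_result()]s.
#' @return the selected [experiment_result()].
#' @export
select_best_run <- function(results) {
  if (length(results) == 0L) stop("empty result list")
  v <- vapply(results, function(r) r$validation_mssim, numeric(1))
  id <- vapply(results, function(r) r$run_id, numeric(1))
  best <- which(v == max(v))
  results[[best[which.min(id[best])]]]
}

#' Evaluate a reconstruction model on test scans
#'
#' Undersamples every slice of every scan with the mask, reconstructs, and
#' computes MAE, RMSE, and mSSIM against the stored ground truth; metrics are
#' averaged per subject (matching the per-subject pairing of the t-tests).
#'
#' @param model a trained [recon_model()].
#' @param mask an [make_mask()].
#' @param scans list of [scan_record()]s with `$magnitude` ground truth.
#' @return data frame with one row per scan.
#' @export
evaluate_recon <- function(model, mask, scans) {
  rows <- lapply(seq_along(scans), function(i) {
    sc <- scans[[i]]
    m <- vapply(seq_len(n_slices(sc)), function(s) {
      und <- apply_undersampling(sc$kspace[[s]], mask)
      rec <- reconstruct(model, und, mask)
      gt <- sc$magnitude[[s]]
      c(mae(rec, gt), rmse(rec, gt), mssim(rec, gt, data_range = max(gt)))
    }, numeric(3))
    data.frame(subject = i, mae = mean(m[1L, ]), rmse = mean(m[2L, ]),
               mssim = mean(m[3L, ]))
  })
  do.call(rbind, rows)
}
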