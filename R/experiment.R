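#' Experiment configuration (YAML-backed)
#'
#' Mirrors the knobs of a reconstruction experiment: how many training scans
#' (magnitude images in the synthetic modes), which data-source mode, the
#' synthetic-pool mixing fraction, whether augmentation is used, and the
#' training schedule. [read_experiment_config()] / [write_experiment_config()]
#' round-trip the structure through a YAML file.
#'
#' @param train_size number of training scans (or magnitude images).
#' @param mode data-source mode; see [draw_training_sample()].
#' @param use_augmentation logical.
#' @param synthetic_fraction fraction of training samples drawn from the
#'   synthetic pool (default 0.75).
#' @param epochs,batches_per_epoch,batch_size training schedule.
#' @param repetitions number of repeated training runs per experiment.
#' @param seed master seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(train_size = 20L, mode = "synthetic-mix",
                              use_augmentation = FALSE,
                              synthetic_fraction = 0.75,
                              epochs = 1L, batches_per_epoch = 200L,
                              batch_size = 1L, repetitions = 5L, seed = 1L) {
  mode <- match.arg(mode, training_modes())
  stopifnot(synthetic_fraction >= 0, synthetic_fraction <= 1,
            train_size >= 1L, batch_size >= 1L, repetitions >= 1L)
  structure(as.list(environment()), class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file path.
#' @export
read_experiment_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(experiment_config, vals[intersect(names(vals),
                                            names(formals(experiment_config)))])
}

#' @rdname experiment_config
#' @param config an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run a grid of reconstruction experiments
#'
#' For every combination of mode, training-set size, and repetition: builds
#' the training sampler (real-only or the synthetic/real mixture with the
#' requested map sources), trains a reconstruction network, records the
#' validation mSSIM, and evaluates per-subject metrics on the test scans.
#' Returns all results plus a summary table (mean and standard deviation per
#' mode and size over repetitions) and, per mode pair and size, a paired
#' t-test on the per-subject MAE of the runs selected by validation mSSIM.
#' P-values are reported raw, without multiple-testing correction.
#'
#' @param modes character vector of data-source modes.
#' @param train_sizes integer vector of training-set sizes (counted in
#'   magnitude images for synthetic modes).
#' @param repetitions number of repeats per cell.
#' @param synth a [synthetic_pool()] (or `NULL` for real-only grids).
#' @param real a [real_pool()].
#' @param test_scans,validation_scans lists of [scan_record()]s.
#' @param mask an [make_mask()].
#' @param recon_cfg a [recon_config()] template (its seed is re-derived per
#'   run).
#' @param synthetic_fraction mixing fraction for the synthetic branch.
#' @param seed master seed.
#' @return list with `results` (list of [experiment_result()]),
#'   `summary` (data frame), and `comparisons` (data frame of paired tests).
#' @export
run_experiment_grid <- function(modes, train_sizes, repetitions = 2L,
                                synth = NULL, real, test_scans,
                                validation_scans, mask,
                                recon_cfg = recon_config(),
                                synthetic_fraction = 0.75, seed = 1L) {
  results <- list()
  for (mode in modes) {
    for (size in train_sizes) {
      synth_sz <- synth
      if (!is.null(synth_sz))
        synth_sz$magnitudes <-
          synth_sz$magnitudes[seq_len(min(size, length(synth_sz$magnitudes)))]
      for (rep_i in seq_len(repetitions)) {
        run_seed <- derive_seed(seed, paste(mode, size), rep_i)
        frac <- if (mode == "real") 0 else synthetic_fraction
        sampler <- function(s) {
          draw_training_sample(synth_sz, real, mix_fraction = frac,
                               mode = mode, seed = s)
        }
        cfg <- recon_cfg
        cfg$seed <- run_seed
        model <- train_recon(sampler, mask, cfg)
        val <- evaluate_recon(model, mask, validation_scans)
        met <- evaluate_recon(model, mask, test_scans)
        results[[length(results) + 1L]] <- experiment_result(
          met, run_id = rep_i, mode = mode, train_size = size,
          augmented = !is.null(cfg$augment),
          validation_mssim = mean(val$mssim))
      }
    }
  }
  list(results = results, summary = summarize_experiments(results),
       comparisons = compare_experiments(results))
}

#' Summarise experiment results
#'
#' Mean and standard deviation of each metric per (mode, training size),
#' aggregating the per-subject means of every repetition.
#'
#' @param results list of [experiment_result()]s.
#' @return data frame.
#' @export
summarize_experiments <- function(results) {
  key <- vapply(results, function(r) paste(r$mode, r$train_size), character(1))
  out <- lapply(unique(key), function(k) {
    rs <- results[key == k]
    per_run <- vapply(rs, function(r) c(mean(r$subject_metrics$mae),
                                        mean(r$subject_metrics$rmse),
                                        mean(r$subject_metrics$mssim)),
                      numeric(3))
    data.frame(mode = rs[[1L]]$mode, train_size = rs[[1L]]$train_size,
               runs = length(rs),
               mae_mean = mean(per_run[1L, ]), mae_sd = stats::sd(per_run[1L, ]),
               rmse_mean = mean(per_run[2L, ]), rmse_sd = stats::sd(per_run[2L, ]),
               mssim_mean = mean(per_run[3L, ]), mssim_sd = stats::sd(per_run[3L, ]))
  })
  do.call(rbind, out)
}

# paired per-subject MAE tests between the validation-selected runs of every
# mode pair at each training size (raw p-values, no correction)
compare_experiments <- function(results) {
  modes <- unique(vapply(results, function(r) r$mode, character(1)))
  sizes <- unique(vapply(results, function(r) r$train_size, numeric(1)))
  rows <- list()
  if (length(modes) < 2L) return(NULL)
  for (size in sizes) {
    sel <- lapply(modes, function(m) {
      rs <- Filter(function(r) r$mode == m && r$train_size == size, results)
      if (length(rs)) select_best_run(rs) else NULL
    })
    names(sel) <- modes
    for (i in seq_along(modes)) for (j in seq_along(modes)) {
      if (i >= j || is.null(sel[[i]]) || is.null(sel[[j]])) next
      tt <- paired_ttest(sel[[i]]$subject_metrics$mae,
                         sel[[j]]$subject_metrics$mae)
      rows[[length(rows) + 1L]] <- data.frame(
        train_size = size, mode_a = modes[i], mode_b = modes[j],
        mean_mae_diff = tt$mean_difference, statistic = tt$statistic,
        p_value = tt$p_value)
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
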