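#' Repeated random train/test splits
#'
#' Plain (non-stratified) uniform splits, repeated; the train set holds
#' `round(fraction * N)` instances. A split that leaves the training set
#' without a single positive cannot be fitted and is redrawn (with a
#' message). Splits are deterministic given the seed.
#'
#' @param data An [as_efo_table()] table with at least 10 instances.
#' @param fraction Train fraction, default 0.70.
#' @param repeats Number of splits, default 5.
#' @param seed Integer seed; `NULL` draws one.
#' @return A tibble of class `efo_splits`: `repeat_index`, `train_ids`,
#'   `test_ids` (list-columns of instance ids), `fraction`, `seed`.
#' @export
make_splits <- function(data, fraction = 0.70, repeats = 5, seed = NULL) {
  if (n_instances(data) < 10L) abort("Need at least 10 instances to split.")
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  seed <- as.integer(seed %||% sample.int(.Machine$integer.max, 1))
  withr::local_seed(seed)
  ids <- efo_ids(data)
  labels <- efo_labels(data)
  n <- length(ids)
  n_train <- as.integer(floor(fraction * n + 0.5))
  draw <- function(rep_i) {
    repeat {
      tr <- sort(sample.int(n, n_train))
      if (sum(labels[tr]) > 0L && sum(labels[tr]) < n_train) {
        return(tibble::tibble(repeat_index = rep_i,
                              train_ids = list(ids[tr]),
                              test_ids = list(ids[-tr]),
                              fraction = fraction, seed = seed))
      }
      inform(paste0("Split ", rep_i, " had a degenerate training set; redrawn."))
    }
  }
  out <- dplyr::bind_rows(purrr::map(seq_len(repeats), draw))
  structure(out, class = c("efo_splits", class(tibble::tibble())))
}

subset_by_ids <- function(data, ids) {
  keep <- efo_ids(data) %in% ids
  as_efo_table(tibble::as_tibble(data)[keep, , drop = FALSE],
               label = attr(data, "efo_label"), id = attr(data, "efo_id"))
}

#' Fit on a training split and evaluate on the held-out test set
#'
#' Models are fitted on the training subset only (the cluster size defaulting
#' to the number of training positives) and their thresholds derived from the
#' training ranking. Each kept model is then applied to the test subset: the
#' test instances scoring at or above the threshold are the predicted
#' positives, the confusion matrix follows from the test ranking, and the
#' report adds test-set enrichment factors at the top 1% and 10%.
#'
#' @param data The full table.
#' @param split One row of [make_splits()] output (or the whole tibble plus
#'   `repeat_index` selecting a row).
#' @param config An [efo_config()].
#' @param repeat_index Which split row to use when `split` has several.
#' @return A list of class `efo_evaluation`: `fit` (the training
#'   [efo_fit()]), `test` (one-row-per-model tibble of test statistics),
#'   `split`.
#' @export
evaluate_split <- function(data, split, config = efo_config(), repeat_index = 1L) {
  if (nrow(split) > 1L) split <- split[split$repeat_index == repeat_index, ]
  stopifnot(nrow(split) == 1L)
  train_ids <- split$train_ids[[1]]
  test_ids <- split$test_ids[[1]]
  if (length(intersect(train_ids, test_ids)) > 0L) {
    abort("Train and test ids overlap.")
  }
  train <- subset_by_ids(data, train_ids)
  test <- subset_by_ids(data, test_ids)

  fit <- efo_fit(train, config = config)
  test_p <- n_positive(test)
  test_rows <- purrr::imap(fit$models, function(mod, i) {
    ranking <- rank_instances(test, mod)
    n_pred <- sum(ranking$score >= mod$threshold)
    metrics <- classification_metrics(confusion_from_ranking(ranking, n_pred))
    if (test_p > 0L) {
      metrics$ef_top1 <- enrichment_factor(ranking, 0.01)
      metrics$ef_top10 <- enrichment_factor(ranking, 0.10)
      cs <- max(1L, min(test_p, nrow(ranking) - 1L))
      metrics$quality <- quality_score(cluster_distribution(ranking, cs))
    } else {
      metrics$ef_top1 <- NA_real_
      metrics$ef_top10 <- NA_real_
      metrics$quality <- NA_real_
    }
    dplyr::bind_cols(tibble::tibble(model = i,
                                    variables = paste(mod$variables, collapse = " + "),
                                    n_predicted_positive = n_pred), metrics)
  })
  structure(list(fit = fit, test = dplyr::bind_rows(test_rows), split = split),
            class = "efo_evaluation")
}

#' Run the full repeated hold-out protocol
#'
#' Convenience wrapper: draw `repeats` random `fraction` splits, fit on each
#' training subset and evaluate on the corresponding test subset, then stack
#' the per-model test reports.
#'
#' @inheritParams make_splits
#' @param config An [efo_config()]; its `split_fraction` / `split_repeats`
#'   are used when `fraction` / `repeats` are missing.
#' @return A tibble of test statistics, one row per (split, kept model),
#'   with a `repeat_index` column; the individual [evaluate_split()] results
#'   are attached as attribute `"evaluations"`.
#' @export
evaluate_protocol <- function(data, config = efo_config(), fraction = NULL,
                              repeats = NULL, seed = NULL) {
  fraction <- fraction %||% config$split_fraction
  repeats <- repeats %||% config$split_repeats
  seed <- as.integer(seed %||% config$seed %||% sample.int(.Machine$integer.max, 1))
  splits <- make_splits(data, fraction = fraction, repeats = repeats, seed = seed)
  evals <- purrr::map(seq_len(repeats), function(i) {
    cfg <- config
    # derived per-split seed keeps the repeats independent yet reproducible
    cfg$seed <- (seed + i) %% .Machine$integer.max
    evaluate_split(data, splits, config = cfg, repeat_index = i)
  })
  out <- purrr::imap(evals, function(ev, i) {
    dplyr::mutate(ev$test, repeat_index = i, .before = 1)
  }) |> dplyr::bind_rows()
  attr(out, "evaluations") <- evals
  out
}

#' Calibration sweep over learner settings
#'
#' Re-fits the learner on the full table for each row of a settings grid and
#' reports, per setting, the mean number of positives the kept models place
#' in the top 1% and top 10% of their rankings and the best top-10% count —
#' the three headline metrics of the method's calibration protocol.
#' Calibration deliberately skips hold-out validation: it probes how the
#' optimizer responds to its controls, not generalization.
#'
#' @param data The full table.
#' @param grid A data frame whose columns are any subset of `cluster_size`,
#'   `cycles`, `variables`, `cutoff`; each row is one setting, unspecified
#'   fields fall back to `config`.
#' @param config Baseline [efo_config()].
#' @param seed Seed applied to every setting (so rows differ only by the
#'   setting).
#' @return A tibble: the four setting columns, `n_discarded` (descriptors
#'   failing the filter), `mean_top1`, `mean_top10`, `best_top10`.
#' @export
calibration_sweep <- function(data, grid, config = efo_config(), seed = NULL) {
  grid <- tibble::as_tibble(grid)
  if (nrow(grid) == 0L) abort("`grid` must have at least one row.")
  extra <- setdiff(names(grid), c("cluster_size", "cycles", "variables", "cutoff"))
  if (length(extra) > 0L) {
    abort(paste0("Unknown grid column(s): ", paste(extra, collapse = ", ")))
  }
  seed <- as.integer(seed %||% config$seed %||% sample.int(.Machine$integer.max, 1))
  n <- n_instances(data)
  m1 <- max(1L, as.integer(floor(0.01 * n + 0.5)))
  m10 <- max(1L, as.integer(floor(0.10 * n + 0.5)))
  purrr::pmap(grid, function(...) {
    row <- list(...)
    cfg <- config
    cfg$cluster_size <- as.integer(row$cluster_size %||% cfg$cluster_size %||%
                                     n_positive(data))
    cfg$sampling_cycles_per_variable <- as.integer(row$cycles %||%
                                                     cfg$sampling_cycles_per_variable)
    cfg$n_variables <- as.integer(row$variables %||% cfg$n_variables)
    cfg$ef_filter_cutoff <- as.double(row$cutoff %||% cfg$ef_filter_cutoff)
    fit <- efo_fit(data, config = cfg, seed = seed)
    tops <- purrr::map(fit$models, function(mod) {
      r <- rank_instances(data, mod)
      c(top1 = sum(r$label[seq_len(m1)]), top10 = sum(r$label[seq_len(m10)]))
    })
    top1 <- purrr::map_dbl(tops, "top1")
    top10 <- purrr::map_dbl(tops, "top10")
    tibble::tibble(cluster_size = cfg$cluster_size,
                   cycles = cfg$sampling_cycles_per_variable,
                   variables = cfg$n_variables,
                   cutoff = cfg$ef_filter_cutoff,
                   n_discarded = sum(!fit$filter$kept),
                   mean_top1 = mean(top1),
                   mean_top10 = mean(top10),
                   best_top10 = max(top10))
  }) |> dplyr::bind_rows()
}
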