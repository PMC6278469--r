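#' Configuration for the EFO learner
#'
#' Bundles every tunable of the fitting pipeline with its default. Defaults
#' follow the method's standard regime: cluster size equal to the number of
#' positives in the training table, 6-variable models, a strict top-5%
#' enrichment-factor filter at 2.0, 12 random sampling cycles per included
#' variable, and a Hooke-Jeeves budget of 5000 evaluations at an RMS step
#' tolerance of 0.001.
#'
#' @param cluster_size Cluster size for the quality function; `NULL` means
#'   "number of positive instances in the training table".
#' @param n_variables Number of descriptors per model.
#' @param ef_filter_cutoff Keep a descriptor only if its best single-variable
#'   top-5% enrichment factor strictly exceeds this; 0 disables the filter.
#' @param sampling_cycles_per_variable Random coefficient draws per included
#'   variable used to seed the optimizer.
#' @param hj_iterations,hj_rms_tol Hooke-Jeeves evaluation budget and RMS
#'   step tolerance.
#' @param hj_starts Number of best random starts refined by full
#'   Hooke-Jeeves runs.
#' @param n_models_kept Number of best models retained (and the beam width of
#'   the greedy search).
#' @param split_fraction,split_repeats Train fraction and number of repeats
#'   of the hold-out protocol (see [make_splits()]).
#' @param max_combinations Above this many descriptor combinations the
#'   exhaustive enumeration falls back to greedy forward construction.
#' @param probability_bin Bin width (fraction of instances) of the score
#'   probability profile.
#' @param seed Integer seed; `NULL` draws one at fit time.
#' @return A list of class `efo_config`.
#' @export
efo_config <- function(cluster_size = NULL, n_variables = 6,
                       ef_filter_cutoff = 2.0,
                       sampling_cycles_per_variable = 12,
                       hj_iterations = 5000, hj_rms_tol = 0.001,
                       hj_starts = 3, n_models_kept = 20,
                       split_fraction = 0.70, split_repeats = 5,
                       max_combinations = 20000, probability_bin = 0.02,
                       seed = NULL) {
  cfg <- list(cluster_size = if (is.null(cluster_size)) NULL else as.integer(cluster_size),
              n_variables = as.integer(n_variables),
              ef_filter_cutoff = as.double(ef_filter_cutoff),
              sampling_cycles_per_variable = as.integer(sampling_cycles_per_variable),
              hj_iterations = as.integer(hj_iterations),
              hj_rms_tol = as.double(hj_rms_tol),
              hj_starts = as.integer(hj_starts),
              n_models_kept = as.integer(n_models_kept),
              split_fraction = as.double(split_fraction),
              split_repeats = as.integer(split_repeats),
              max_combinations = as.double(max_combinations),
              probability_bin = as.double(probability_bin),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (!is.null(cfg$cluster_size) && cfg$cluster_size < 1L) {
    abort("`cluster_size` must be at least 1.")
  }
  if (cfg$n_variables < 1L) abort("`n_variables` must be at least 1.")
  if (cfg$ef_filter_cutoff < 0) abort("`ef_filter_cutoff` must be >= 0.")
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1) {
    abort("`split_fraction` must be in (0, 1).")
  }
  structure(cfg, class = "efo_config")
}

#' Filter descriptors by single-variable enrichment
#'
#' Ranks the instances by each descriptor alone, in both directions
#' (descending: high values first; ascending: low values first), and records
#' the better top-5% enrichment factor. A descriptor is kept when that value
#' strictly exceeds `cutoff`; `cutoff = 0` disables the filter and keeps every
#' non-constant descriptor. Constant descriptors are always discarded — a
#' degenerate ranking has no meaningful enrichment. Note the strictness
#' matters near balance: on a perfectly balanced dataset the top-5% EF can
#' never exceed 2.0, so the default cutoff discards even a perfect separator
#' and should be lowered or removed for balanced problems.
#'
#' @param data An [as_efo_table()] table with at least one positive.
#' @param cutoff Strict lower bound on the best top-5% enrichment factor.
#' @param top_fraction Prefix fraction at which the EF is computed.
#' @return A tibble of class `efo_filter`: `descriptor`, `ef_top5`,
#'   `direction` (`"descending"` or `"ascending"`), `kept`.
#' @export
filter_descriptors <- function(data, cutoff = 2.0, top_fraction = 0.05) {
  assert_fit_ready(data)
  labels <- efo_labels(data)
  m <- descriptor_matrix(data)
  res <- purrr::map(colnames(m), function(nm) {
    x <- m[, nm]
    if (max(x) == min(x)) {
      return(tibble::tibble(descriptor = nm, ef_top5 = NA_real_,
                            direction = NA_character_, kept = FALSE))
    }
    ef_desc <- enrichment_factor(new_ranking(x, labels), top_fraction)
    ef_asc <- enrichment_factor(new_ranking(-x, labels), top_fraction)
    if (ef_desc >= ef_asc) {
      tibble::tibble(descriptor = nm, ef_top5 = ef_desc,
                     direction = "descending", kept = NA)
    } else {
      tibble::tibble(descriptor = nm, ef_top5 = ef_asc,
                     direction = "ascending", kept = NA)
    }
  })
  out <- dplyr::bind_rows(res)
  const <- is.na(out$ef_top5)
  if (any(const)) {
    inform(paste0("Discarding constant descriptor(s): ",
                  paste(out$descriptor[const], collapse = ", ")))
  }
  out$kept <- !const & (cutoff == 0 | out$ef_top5 > cutoff)
  structure(out, class = c("efo_filter", class(tibble::tibble())),
            cutoff = cutoff, top_fraction = top_fraction)
}

#' @export
autoplot.efo_filter <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      descriptor = stats::reorder(.data$descriptor, .data$ef_top5))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$descriptor, y = .data$ef_top5,
                                   fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(object, "cutoff"), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Best top-5% enrichment factor",
                  title = "Single-descriptor enrichment filter") +
    ggplot2::theme_minimal()
}

#' Random coefficient starts
#'
#' Draws coefficient vectors with each component uniform on \[-1, 1\] and then
#' rescaled by the reciprocal of the corresponding descriptor's sample
#' standard deviation, so that descriptors spanning very different raw
#' magnitudes contribute comparably to the starting scores (the data
#' themselves are never rescaled). Consumes the current RNG stream.
#'
#' @param k Number of coefficients per vector.
#' @param cycles Number of vectors; defaults to 12 per variable.
#' @param scale_sd Per-variable sample standard deviations; zero values are
#'   replaced by 1.
#' @return A `cycles` x `k` numeric matrix, one start per row.
#' @export
random_starts <- function(k, cycles = 12 * k, scale_sd = rep(1, k)) {
  k <- as.integer(k)
  cycles <- as.integer(cycles)
  if (k < 1L || cycles < 1L) abort("`k` and `cycles` must be positive.")
  scale_sd <- as.double(scale_sd)
  if (length(scale_sd) != k) abort("`scale_sd` must have length `k`.")
  zero <- !is.finite(scale_sd) | scale_sd == 0
  if (any(zero)) {
    inform(paste0("Zero-variance variable(s) at position(s) ",
                  paste(which(zero), collapse = ", "), "; scale factor 1 used."))
    scale_sd[zero] <- 1
  }
  m <- matrix(runif(cycles * k, -1, 1), nrow = cycles, ncol = k)
  sweep(m, 2, scale_sd, "/")
}

# Fast ranking-quality objective over coefficient vectors for a fixed
# variable subset; the closure is what hooke_jeeves() maximizes.
quality_objective <- function(data, variables, cluster_size) {
  x <- descriptor_matrix(data)[, variables, drop = FALSE]
  labels <- efo_labels(data)
  function(cf) .quality_objective_cpp(x, cf, labels, as.integer(cluster_size))
}

#' Optimize the coefficients of one descriptor combination
#'
#' Draws random starts, evaluates the ranking-quality objective at each,
#' refines the best `hj_starts` distinct starts with full Hooke-Jeeves runs,
#' keeps the best terminal point, normalizes the leading coefficient to
#' +/-1 (which cannot change any ranking) and derives the classification
#' threshold from the training ranking.
#'
#' @param data Training table.
#' @param variables Character vector of descriptor names to combine.
#' @param config An [efo_config()].
#' @return An [efo_model()] with `threshold` and `train_quality` set.
#' @export
optimize_combination <- function(data, variables, config = efo_config()) {
  assert_fit_ready(data)
  k <- length(variables)
  cs <- config$cluster_size %||% n_positive(data)
  if (cs >= n_instances(data)) {
    abort("`cluster_size` must be smaller than the number of instances.")
  }
  obj <- quality_objective(data, variables, cs)
  xm <- descriptor_matrix(data)[, variables, drop = FALSE]
  sds <- apply(xm, 2, sd)
  starts <- suppressMessages(
    random_starts(k, config$sampling_cycles_per_variable * k, scale_sd = sds))
  vals <- apply(starts, 1, obj)
  ord <- order(vals, decreasing = TRUE)
  n_runs <- min(config$hj_starts, nrow(starts))
  best <- NULL
  for (i in seq_len(n_runs)) {
    x0 <- starts[ord[i], ]
    run <- hooke_jeeves(obj, x0, iterations = config$hj_iterations,
                        rms_tol = config$hj_rms_tol)
    if (is.null(best) || run$value > best$value) best <- run
  }
  model <- efo_model(variables, best$par, cluster_size = cs,
                     train_quality = best$value, seed = config$seed)
  set_threshold(model, data)
}

#' Derive the classification threshold from the training ranking
#'
#' During learning the `n` best-scoring instances are treated as positive,
#' `n` being the number of positives in the training table. The score of the
#' rank-`n` instance — the last one considered positive — becomes the
#' threshold: an external instance is predicted positive when its score is
#' greater than or equal to it (the boundary instance itself counts as
#' positive).
#'
#' @param model An [efo_model()].
#' @param data Training table.
#' @return The model with `threshold` set.
#' @export
set_threshold <- function(model, data) {
  ranking <- rank_instances(data, model)
  n <- n_positive(data)
  model$threshold <- ranking$score[n]
  model
}

#' Score-based probability profile
#'
#' Partitions the training ranking into consecutive bins of
#' `ceiling(bin_fraction * N)` instances and records each bin's positive
#' fraction together with its score range. The fraction of the bin a new
#' score falls into is reported as that prediction's probability of being
#' positive; scores outside the training range clamp to the extreme bins.
#' With the default 2% bins, "a score in the top 2% of the training ranking"
#' maps to the top bin's empirical positive rate.
#'
#' @param model A fitted [efo_model()].
#' @param data Training table.
#' @param bin_fraction Bin width as a fraction of instances, in (0, 0.5].
#' @return A tibble of class `efo_profile`: `bin`, `from_rank`, `to_rank`,
#'   `score_upper`, `score_lower`, `n`, `positives`, `fraction`.
#' @export
probability_profile <- function(model, data, bin_fraction = 0.02) {
  if (!is.numeric(bin_fraction) || length(bin_fraction) != 1L ||
      bin_fraction <= 0 || bin_fraction > 0.5) {
    abort("`bin_fraction` must be a single number in (0, 0.5].")
  }
  ranking <- rank_instances(data, model)
  n <- nrow(ranking)
  b <- as.integer(ceiling(bin_fraction * n))
  bin <- (ranking$rank - 1L) %/% b + 1L
  prof <- ranking |>
    dplyr::mutate(bin = bin) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(from_rank = min(.data$rank), to_rank = max(.data$rank),
                     score_upper = max(.data$score),
                     score_lower = min(.data$score),
                     n = dplyr::n(), positives = sum(.data$label),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$positives / .data$n)
  structure(prof, class = c("efo_profile", class(tibble::tibble())),
            bin_fraction = bin_fraction)
}

# Map scores onto profile bins: topmost bin whose lower score edge is <= s,
# clamped to the extreme bins outside the training range.
profile_lookup <- function(profile, scores) {
  nb <- nrow(profile)
  breaks_inc <- rev(profile$score_lower)
  cnt <- findInterval(scores, breaks_inc)
  idx <- pmin(nb, nb - cnt + 1L)
  profile$fraction[idx]
}

#' @export
autoplot.efo_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Score bin (best first)", y = "Positive fraction",
                  title = "Score-based probability profile") +
    ggplot2::theme_minimal()
}

#' Fit EFO models to a descriptor table
#'
#' The full learning pipeline: filter descriptors by single-variable
#' enrichment, enumerate descriptor combinations of size `n_variables`
#' (exhaustively, or by greedy forward construction when the exhaustive count
#' exceeds `max_combinations`), optimize each combination's coefficients
#' against the ranking-quality function, and keep the best `n_models_kept`
#' models by training quality. Each kept model carries its threshold, a
#' score-probability profile, and a training evaluation report.
#'
#' @param data An [as_efo_table()] table.
#' @param config An [efo_config()].
#' @param seed Integer seed overriding `config$seed`; if both are `NULL` a
#'   seed is drawn and recorded. Identical (data, config, seed) give
#'   identical results.
#' @return An object of class `efo_fit`: a list with `models` (list of
#'   [efo_model()]), `results` (one-row-per-model tibble of training
#'   statistics), `filter`, `config`, `seed`, `search` (`"exhaustive"` or
#'   `"greedy"`), `n_combinations`.
#' @export
efo_fit <- function(data, config = efo_config(), seed = NULL) {
  assert_fit_ready(data)
  seed <- as.integer(seed %||% config$seed %||% sample.int(.Machine$integer.max, 1))
  config$seed <- seed
  config$cluster_size <- config$cluster_size %||% n_positive(data)
  withr::local_seed(seed)

  filt <- filter_descriptors(data, cutoff = config$ef_filter_cutoff)
  kept <- filt$descriptor[filt$kept]
  m <- length(kept)
  k <- config$n_variables
  if (m < k) {
    abort(paste0("Only ", m, " descriptor(s) pass the enrichment filter but ",
                 k, "-variable models were requested; lower `ef_filter_cutoff` ",
                 "(current: ", config$ef_filter_cutoff, ")."))
  }

  if (choose(m, k) <= config$max_combinations) {
    search <- "exhaustive"
    combos <- combn(kept, k, simplify = FALSE)
    models <- purrr::map(combos, function(v) optimize_combination(data, v, config))
    n_comb <- length(combos)
  } else {
    search <- "greedy"
    res <- greedy_forward(data, kept, config)
    models <- res$models
    n_comb <- res$n_optimized
  }
  qualities <- purrr::map_dbl(models, "train_quality")
  keep <- head(order(qualities, decreasing = TRUE), config$n_models_kept)
  models <- models[keep]

  models <- purrr::map(models, function(mod) {
    mod$profile <- probability_profile(mod, data, config$probability_bin)
    mod
  })
  results <- purrr::imap(models, function(mod, i) {
    rep <- evaluation_report(mod, data)
    dplyr::bind_cols(tibble::tibble(model = i,
                                    variables = paste(mod$variables, collapse = " + "),
                                    train_quality = mod$train_quality,
                                    threshold = mod$threshold), rep)
  }) |> dplyr::bind_rows()

  structure(list(models = models, results = results, filter = filt,
                 config = config, seed = seed, search = search,
                 n_combinations = n_comb),
            class = "efo_fit")
}

# Greedy forward construction: the best `n_models_kept` variable sets of size
# j, each extended by every remaining kept descriptor, seed size j+1.
greedy_forward <- function(data, kept, config) {
  beam <- list(character(0))
  n_opt <- 0L
  models <- NULL
  for (j in seq_len(config$n_variables)) {
    cand <- unique(unlist(
      purrr::map(beam, function(v) {
        purrr::map(setdiff(kept, v), function(d) sort(c(v, d)))
      }), recursive = FALSE))
    cfg_j <- config
    cfg_j$n_variables <- j
    models <- purrr::map(cand, function(v) optimize_combination(data, v, cfg_j))
    n_opt <- n_opt + length(cand)
    qual <- purrr::map_dbl(models, "train_quality")
    top <- head(order(qual, decreasing = TRUE), config$n_models_kept)
    beam <- purrr::map(models[top], "variables")
    models <- models[top]
  }
  list(models = models, n_optimized = n_opt)
}

# Training-set evaluation of one fitted model: confusion at the threshold,
# standard metrics, enrichment factors and ranking quality.
evaluation_report <- function(model, data, cluster_size = model$cluster_size) {
  ranking <- rank_instances(data, model)
  n_pred <- sum(ranking$score >= model$threshold)
  cm <- confusion_from_ranking(ranking, n_pred)
  metrics <- classification_metrics(cm)
  metrics$ef_top1 <- enrichment_factor(ranking, 0.01)
  metrics$ef_top10 <- enrichment_factor(ranking, 0.10)
  cs <- min(cluster_size, nrow(ranking) - 1L)
  metrics$quality <- quality_score(cluster_distribution(ranking, cs))
  metrics
}

#' @export
print.efo_fit <- function(x, ...) {
  cat("EFO fit (", x$search, " search, ", x$n_combinations,
      " combinations optimized, seed ", x$seed, ")\n", sep = "")
  cat("Descriptors kept by filter: ", sum(x$filter$kept), "/",
      nrow(x$filter), " (cutoff ", attr(x$filter, "cutoff"), ")\n", sep = "")
  print(x$results)
  invisible(x)
}

#' @describeIn efo_fit One row per model term across kept models.
#' @param x,object An `efo_fit`.
#' @param ... Unused.
#' @export
tidy.efo_fit <- function(x, ...) {
  purrr::imap(x$models, function(m, i) {
    dplyr::mutate(tidy(m), model = i, .before = 1)
  }) |> dplyr::bind_rows()
}

#' @describeIn efo_fit One-row fit summary.
#' @export
glance.efo_fit <- function(x, ...) {
  tibble::tibble(n_models = length(x$models),
                 best_quality = max(x$results$train_quality),
                 n_kept_descriptors = sum(x$filter$kept),
                 n_combinations = x$n_combinations,
                 search = x$search, seed = x$seed)
}

#' @export
autoplot.efo_fit <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(.data$model), y = .data$train_quality)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Model (by rank)", y = "Training quality",
                  title = "Kept models by training quality") +
    ggplot2::theme_minimal()
}

#' Predict with a fitted model
#'
#' Scores each instance, classifies by the model threshold (`>=` means
#' positive) and attaches the score-based probability read off the model's
#' training probability profile.
#'
#' @param object An [efo_model()] or an [efo_fit()] (then `model` selects
#'   which kept model, default the best).
#' @param data A descriptor table containing the model's variables.
#' @param ... Unused.
#' @return A tibble: `id`, `score`, `class` (0/1), `probability`.
#' @export
predict.efo_model <- function(object, data, ...) {
  sc <- score_instances(data, object)
  if (is.na(object$threshold)) {
    abort("Model has no threshold; fit it or call set_threshold() first.")
  }
  sc$class <- as.integer(sc$score >= object$threshold)
  if (is.null(object$profile)) {
    warn("Model has no probability profile; probabilities omitted.")
    sc$probability <- NA_real_
  } else {
    sc$probability <- profile_lookup(object$profile, sc$score)
  }
  sc[, c("id", "score", "class", "probability")]
}

#' @rdname predict.efo_model
#' @param model Index of the kept model to use.
#' @export
predict.efo_fit <- function(object, data, model = 1L, ...) {
  predict(object$models[[model]], data)
}

#' @describeIn predict.efo_model Input table with `.score`, `.class`,
#'   `.probability` columns appended.
#' @export
augment.efo_model <- function(x, data, ...) {
  pred <- predict(x, data)
  out <- tibble::as_tibble(data)
  out$.score <- pred$score
  out$.class <- pred$class
  out$.probability <- pred$probability
  out
}
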