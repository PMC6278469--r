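#' Score and rank instances with a linear model
#'
#' `score_instances()` returns per-instance scores in table order;
#' `rank_instances()` sorts them into a ranking, the object every
#' early-recognition statistic in the package is computed from. Higher scores
#' rank first and are interpreted as "more likely positive". Ties are broken
#' by original row order (stable sort) so results are reproducible.
#'
#' @param data An [as_efo_table()] table.
#' @param model An [efo_model()], or a named numeric vector of coefficients.
#' @return `score_instances()`: a tibble `id`, `score`, `label` in input
#'   order. `rank_instances()`: the same columns plus `rank`, sorted by
#'   descending score, of class `efo_ranking`.
#' @examples
#' tab <- as_efo_table(tibble::tibble(x = c(3, 1, 2), label = c(1, 0, 0)),
#'                     label = "label")
#' rank_instances(tab, efo_model("x", 1))
#' @export
rank_instances <- function(data, model) {
  sc <- score_instances(data, model)
  o <- order(sc$score, decreasing = TRUE, method = "radix")
  out <- sc[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "id", "score", "label")]
  structure(out, class = c("efo_ranking", class(tibble::tibble())))
}

#' @rdname rank_instances
#' @export
score_instances <- function(data, model) {
  if (is.numeric(model) && !is.null(names(model))) {
    model <- efo_model(names(model), unname(model))
  }
  stopifnot(inherits(model, "efo_model"))
  missing_vars <- setdiff(model$variables, descriptor_names(data))
  if (length(missing_vars) > 0L) {
    abort(paste0("Model variables not in table: ",
                 paste(missing_vars, collapse = ", ")))
  }
  m <- descriptor_matrix(data)[, model$variables, drop = FALSE]
  tibble::tibble(id = efo_ids(data),
                 score = unname(drop(m %*% model$coefficients)),
                 label = efo_labels(data))
}

# Build an efo_ranking directly from parallel vectors (used by oracles/tests
# and internal fast paths).
new_ranking <- function(scores, labels, ids = NULL) {
  ids <- ids %||% as.character(seq_along(scores))
  o <- order(scores, decreasing = TRUE, method = "radix")
  structure(tibble::tibble(rank = seq_along(scores), id = ids[o],
                           score = as.double(scores)[o],
                           label = as.integer(labels)[o]),
            class = c("efo_ranking", class(tibble::tibble())))
}

assert_ranking <- function(ranking) {
  if (!is.data.frame(ranking) || !all(c("score", "label") %in% names(ranking))) {
    abort("Expected a ranking with `score` and `label` columns (see rank_instances()).")
  }
  invisible(ranking)
}

#' Enrichment factor of a ranking
#'
#' The enrichment factor at a top fraction `f` is the positive rate among the
#' first `m = max(1, round(f * N))` ranked instances divided by the overall
#' positive rate: `EF = (h/m) / (P/N)`. EF is 1 for a random ranking; its
#' maximum is `min(m, P) * N / (m * P)` — e.g. exactly 2 at the top 5% of a
#' perfectly ranked, perfectly balanced dataset.
#'
#' @param ranking An `efo_ranking` (or any data frame with `score`, `label`
#'   sorted by descending score).
#' @param top_fraction Fraction of the ranking to inspect, in (0, 1].
#' @return The enrichment factor, a single number.
#' @export
enrichment_factor <- function(ranking, top_fraction) {
  assert_ranking(ranking)
  if (!is.numeric(top_fraction) || length(top_fraction) != 1L ||
      top_fraction <= 0 || top_fraction > 1) {
    abort("`top_fraction` must be a single number in (0, 1].")
  }
  n <- nrow(ranking)
  p <- sum(ranking$label)
  if (p == 0L) abort("Enrichment factor undefined: ranking has no positives.")
  m <- max(1L, as.integer(floor(top_fraction * n + 0.5)))
  h <- sum(ranking$label[seq_len(m)])
  (h / m) / (p / n)
}

#' Cluster distribution of a ranking
#'
#' Partitions a ranking into consecutive clusters of `cluster_size` instances
#' (the last cluster may be smaller) and counts the positives in each. The
#' per-cluster positive percentages are the profile the asymmetry index and
#' the quality function are computed from: a good model front-loads the
#' positives, giving a strongly right-skewed profile.
#'
#' @inheritParams enrichment_factor
#' @param cluster_size Number of instances per cluster, at least 1.
#' @return A tibble of class `efo_clusters` with columns `cluster`, `size`,
#'   `positives`, `percentage`, and attributes `cluster_size`,
#'   `mean_percentage`.
#' @export
cluster_distribution <- function(ranking, cluster_size) {
  assert_ranking(ranking)
  n <- nrow(ranking)
  cluster_size <- as.integer(cluster_size)
  if (is.na(cluster_size) || cluster_size < 1L) {
    abort("`cluster_size` must be a positive integer.")
  }
  if (cluster_size > n) abort("`cluster_size` exceeds the number of instances.")
  cl <- (seq_len(n) - 1L) %/% cluster_size + 1L
  k <- max(cl)
  counts <- as.integer(tabulate(cl[ranking$label == 1L], nbins = k))
  sizes <- as.integer(tabulate(cl, nbins = k))
  pct <- 100 * counts / sizes
  structure(tibble::tibble(cluster = seq_len(k), size = sizes,
                           positives = counts, percentage = pct),
            class = c("efo_clusters", class(tibble::tibble())),
            cluster_size = cluster_size,
            mean_percentage = mean(pct))
}

#' Asymmetry index of a cluster profile
#'
#' Pearson's moment coefficient of skewness of the per-cluster positive
#' percentages: the third central moment over the 3/2 power of the second,
#' both computed with 1/n weights. A right-skewed profile (positives
#' concentrated up front, long tail of empty clusters) gives a large positive
#' value. A zero-variance profile is degenerate and returns 0, so that
#' uninformative models score worst for the optimizer.
#'
#' @param dist An `efo_clusters` distribution (needs at least 2 clusters).
#' @return The skewness, a single number.
#' @export
asymmetry_index <- function(dist) {
  pct <- cluster_percentages(dist)
  n <- length(pct)
  if (n < 2L) abort("Asymmetry index needs at least 2 clusters.")
  mu <- mean(pct)
  v <- mean((pct - mu)^2)
  if (v == 0) return(0)
  mean((pct - mu)^3) / v^1.5
}

#' Ranking quality: asymmetry index times first-cluster positive rate
#'
#' The objective the EFO learner maximizes: the asymmetry index of the
#' cluster profile multiplied by the percentage of positives in the first
#' (best) cluster. The first factor rewards profiles that decay towards the
#' bottom of the ranking; the second rewards early recognition. When the
#' cluster size equals the number of positives, the first cluster plays the
#' role of the predicted-positive set.
#'
#' @param dist An `efo_clusters` distribution.
#' @return The quality value, a single number (0 for degenerate profiles).
#' @export
quality_score <- function(dist) {
  pct <- cluster_percentages(dist)
  ai <- asymmetry_index(dist)
  ai * pct[1]
}

cluster_percentages <- function(dist) {
  if (inherits(dist, "efo_clusters") ||
      (is.data.frame(dist) && "percentage" %in% names(dist))) {
    return(dist$percentage)
  }
  if (is.numeric(dist)) return(as.double(dist))
  abort("Expected an `efo_clusters` distribution or a numeric profile.")
}

#' Confusion matrix from the top of a ranking
#'
#' Predicted positives are the first `n_predicted_positive` instances of the
#' ranking; everything below is predicted negative. With
#' `n_predicted_positive` equal to the number of true positives this
#' reproduces the identities `fp = P - tp`, `fn = P - tp`,
#' `tn = N - tp - fp - fn` used when a model is scored by how many positives
#' it places in the top `P` positions.
#'
#' @inheritParams enrichment_factor
#' @param n_predicted_positive How many top-ranked instances to call positive,
#'   between 0 and the number of instances.
#' @return A list of class `efo_confusion` with elements `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_from_ranking <- function(ranking, n_predicted_positive) {
  assert_ranking(ranking)
  n <- nrow(ranking)
  k <- as.integer(n_predicted_positive)
  if (is.na(k) || k < 0L || k > n) {
    abort("`n_predicted_positive` must be between 0 and the number of instances.")
  }
  p <- sum(ranking$label)
  tp <- if (k > 0L) sum(ranking$label[seq_len(k)]) else 0L
  new_confusion(tp = tp, fp = k - tp, fn = p - tp, tn = n - k - (p - tp))
}

new_confusion <- function(tp, fp, fn, tn) {
  vals <- as.integer(c(tp, fp, fn, tn))
  if (anyNA(vals) || any(vals < 0L)) abort("Confusion counts must be non-negative.")
  structure(list(tp = vals[1], fp = vals[2], fn = vals[3], tn = vals[4]),
            class = "efo_confusion")
}

#' @export
print.efo_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("positive", "negative"), c("positive", "negative")))
  print(m)
  invisible(x)
}

#' @export
tidy.efo_confusion <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

#' Classification metrics from a confusion matrix
#'
#' Precision, accuracy, sensitivity, specificity and the Matthews correlation
#' coefficient. Any metric whose denominator is zero is reported as 0 and
#' named in the `flags` column rather than propagating NaN.
#'
#' @param cm An `efo_confusion` (see [confusion_from_ranking()]), or a list
#'   with elements `tp`, `fp`, `fn`, `tn`.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `precision`, `accuracy`,
#'   `sensitivity`, `specificity`, `mcc`, `flags` (comma-separated names of
#'   degenerate metrics, `NA` if none).
#' @export
classification_metrics <- function(cm) {
  tp <- as.numeric(cm$tp); fp <- as.numeric(cm$fp)
  fn <- as.numeric(cm$fn); tn <- as.numeric(cm$tn)
  n <- tp + fp + fn + tn
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      flags <<- c(flags, name)
      return(0)
    }
    num / den
  }
  precision <- safe(tp, tp + fp, "precision")
  accuracy <- safe(tp + tn, n, "accuracy")
  sensitivity <- safe(tp, tp + fn, "sensitivity")
  specificity <- safe(tn, tn + fp, "specificity")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    flags <- c(flags, "mcc")
    0
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  tibble::tibble(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 precision = precision, accuracy = accuracy,
                 sensitivity = sensitivity, specificity = specificity,
                 mcc = mcc,
                 flags = if (length(flags)) paste(flags, collapse = ",") else NA_character_)
}

#' @export
autoplot.efo_clusters <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cluster, y = .data$percentage)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "mean_percentage"),
                        linetype = "dashed") +
    ggplot2::labs(x = "Cluster (ranking order)",
                  y = "Positive instances (%)",
                  title = "Cluster distribution of positives",
                  subtitle = sprintf("cluster size %d, asymmetry index %.3f",
                                     attr(object, "cluster_size"),
                                     asymmetry_index(object))) +
    ggplot2::theme_minimal()
}
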