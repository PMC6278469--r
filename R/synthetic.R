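#' Specification for a synthetic descriptor table
#'
#' The generator emulates the statistical shape of a curated
#' reactive-metabolite substrate table: ~977 instances by ~28 continuous
#' descriptors on wildly heterogeneous raw scales, ~14% positives, and a
#' small informative subset of descriptors carrying a linear signal. Labels
#' are assigned by thresholding a latent linear score (the top `n_positive`
#' latent values are positive) and then flipping a small fraction — the same
#' model family the learner searches, which makes parameter recovery a sharp
#' test. A balanced mode emulates UCI-style benchmark shapes (e.g. 270 x 13
#' "heart", 208 x 60 "sonar") where roughly half the instances are positive.
#'
#' @param n_instances,n_descriptors Table dimensions.
#' @param n_positive Positive count before label noise; in balanced mode
#'   defaults to half the instances.
#' @param n_informative How many descriptors carry signal (chosen at random
#'   per seed).
#' @param effect_size Per-informative-descriptor contribution to the latent
#'   score, in SD units relative to the unit-variance latent noise; 0 gives
#'   pure noise labels.
#' @param label_noise Fraction of labels flipped after assignment, in
#'   \[0, 0.5).
#' @param descriptor_scales Per-descriptor raw-scale multipliers; the default
#'   spans four orders of magnitude (log-uniform grid from 0.01 to 100) to
#'   exercise the unscaled-descriptor regime.
#' @param mode `"unbalanced_rm"` (the default shape above) or
#'   `"balanced_uci"`.
#' @param seed Integer seed.
#' @return A list of class `efo_synthetic_spec`.
#' @export
synthetic_spec <- function(n_instances = 977, n_descriptors = 28,
                           n_positive = NULL, n_informative = min(6L, n_descriptors),
                           effect_size = 1.0, label_noise = 0.02,
                           descriptor_scales = NULL,
                           mode = c("unbalanced_rm", "balanced_uci"),
                           seed = NULL) {
  mode <- match.arg(mode)
  n_instances <- as.integer(n_instances)
  n_descriptors <- as.integer(n_descriptors)
  n_positive <- as.integer(n_positive %||%
    if (mode == "balanced_uci") round(n_instances / 2) else round(0.1412 * n_instances))
  if (n_positive <= 0L || n_positive >= n_instances) {
    abort("`n_positive` must satisfy 0 < n_positive < n_instances.")
  }
  n_informative <- as.integer(n_informative)
  if (n_informative < 0L || n_informative > n_descriptors) {
    abort("`n_informative` must be between 0 and `n_descriptors`.")
  }
  if (label_noise < 0 || label_noise >= 0.5) {
    abort("`label_noise` must be in [0, 0.5).")
  }
  scales <- descriptor_scales %||% 10^seq(-2, 2, length.out = n_descriptors)
  if (length(scales) != n_descriptors || any(scales <= 0)) {
    abort("`descriptor_scales` must be positive, one per descriptor.")
  }
  structure(list(n_instances = n_instances, n_descriptors = n_descriptors,
                 n_positive = n_positive, n_informative = n_informative,
                 effect_size = as.double(effect_size),
                 label_noise = as.double(label_noise),
                 descriptor_scales = as.double(scales), mode = mode,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "efo_synthetic_spec")
}

#' Generate a synthetic descriptor table
#'
#' Descriptors are independent Gaussians scaled per-descriptor; the latent
#' score is `effect_size * sum_j u_j z_j + noise` over the informative
#' descriptors, with `z_j` the standardized descriptor, per-descriptor weight
#' jitter `u_j ~ U(0.75, 1.25)` with random sign, and standard normal noise.
#' The top `n_positive` latent scores become positives; `label_noise * N`
#' randomly chosen labels are then flipped. With zero label noise the ground
#' truth reproduces the labels exactly.
#'
#' @param spec An [synthetic_spec()]; its `seed` (or the `seed` argument)
#'   makes the table reproducible.
#' @param seed Overrides `spec$seed`.
#' @return A list of class `efo_synthesis`: `table` (an [as_efo_table()]
#'   with `id` and `label` columns, descriptors `d01`, `d02`, ...),
#'   `truth` (list: `informative` descriptor names, `weights` on the
#'   standardized scale, `latent` scores, `labels_clean` pre-noise labels,
#'   `flipped` indices).
#' @export
synthetic_table <- function(spec = synthetic_spec(), seed = NULL) {
  stopifnot(inherits(spec, "efo_synthetic_spec"))
  seed <- as.integer(seed %||% spec$seed %||% sample.int(.Machine$integer.max, 1))
  withr::local_seed(seed)
  n <- spec$n_instances
  p <- spec$n_descriptors
  desc_names <- sprintf("d%02d", seq_len(p))
  x <- matrix(rnorm(n * p), n, p)
  x <- sweep(x, 2, spec$descriptor_scales, "*")
  colnames(x) <- desc_names

  informative <- sort(sample.int(p, spec$n_informative))
  weights <- numeric(0)
  latent <- rnorm(n)
  if (spec$n_informative > 0L) {
    weights <- spec$effect_size * runif(spec$n_informative, 0.75, 1.25) *
      sample(c(-1, 1), spec$n_informative, replace = TRUE)
    z <- scale(x[, informative, drop = FALSE])
    latent <- drop(z %*% weights) + latent
  }
  labels_clean <- as.integer(rank(-latent, ties.method = "first") <= spec$n_positive)
  labels <- labels_clean
  n_flip <- as.integer(round(spec$label_noise * n))
  flipped <- integer(0)
  if (n_flip > 0L) {
    flipped <- sort(sample.int(n, n_flip))
    labels[flipped] <- 1L - labels[flipped]
  }

  tab <- tibble::as_tibble(as.data.frame(x))
  tab <- dplyr::mutate(tab, id = sprintf("inst_%05d", seq_len(n)),
                       label = labels, .before = 1)
  structure(list(table = as_efo_table(tab, label = "label", id = "id"),
                 truth = list(informative = desc_names[informative],
                              weights = setNames(weights, desc_names[informative]),
                              latent = latent, labels_clean = labels_clean,
                              flipped = flipped),
                 spec = spec, seed = seed),
            class = "efo_synthesis")
}

#' @export
print.efo_synthesis <- function(x, ...) {
  cat("Synthetic descriptor table (seed ", x$seed, ", mode ",
      x$spec$mode, ")\n", sep = "")
  cat("  informative: ", paste(x$truth$informative, collapse = ", "), "\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' The table goes to `<path>.csv` (readable by [read_descriptor_table()]),
#' the ground truth to `<path>_truth.json`.
#'
#' @param x An `efo_synthesis`.
#' @param path Output path stem.
#' @return `x`, invisibly.
#' @export
write_synthetic <- function(x, path) {
  stopifnot(inherits(x, "efo_synthesis"))
  write_descriptor_table(x$table, paste0(path, ".csv"))
  truth <- x$truth
  truth$weights <- as.list(truth$weights)
  jsonlite::write_json(c(truth, list(seed = x$seed)),
                       paste0(path, "_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}
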