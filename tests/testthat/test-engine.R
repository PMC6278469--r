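test_that("filter: a perfect separator on a balanced table hits the EF ceiling and is NOT kept at 2.0", {
  n <- 100
  x <- seq_len(n)
  lab <- as.integer(x > n / 2) # high x = positive, perfectly separated
  tab <- as_efo_table(tibble::tibble(x = as.double(x), noise = rep(1, n),
                                     label = lab))
  filt <- suppressMessages(filter_descriptors(tab, cutoff = 2.0))
  row <- filt[filt$descriptor == "x", ]
  expect_identical(row$ef_top5, 2) # ceiling for a balanced dataset
  expect_false(row$kept)           # strict inequality at the default cutoff
  expect_false(filt$kept[filt$descriptor == "noise"]) # constant discarded
  expect_true(is.na(filt$ef_top5[filt$descriptor == "noise"]))
})

test_that("filter: perfect unbalanced separator reaches the closed-form EF maximum", {
  n <- 200
  p <- 30
  lab <- c(rep(1, p), rep(0, n - p))
  tab <- as_efo_table(tibble::tibble(d = as.double(rev(seq_len(n))),
                                     label = lab))
  filt <- filter_descriptors(tab, cutoff = 2.0)
  m <- max(1, floor(0.05 * n + 0.5))
  expect_equal(filt$ef_top5[1], min(m, p) * n / (m * p))
  expect_identical(filt$direction[1], "descending")
  expect_true(filt$kept[1])
})

test_that("filter: cutoff 0 keeps all non-constant descriptors; raising the cutoff shrinks the kept set", {
  tab <- planted_linear_table(n = 100, n_pos = 15)
  f0 <- filter_descriptors(tab, cutoff = 0)
  expect_true(all(f0$kept))
  prev <- sum(f0$kept)
  for (cut in c(0.5, 1, 1.5, 2, 3, 10)) {
    k <- sum(filter_descriptors(tab, cutoff = cut)$kept)
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("filter picks the ascending direction for inverted signals", {
  n <- 200
  lab <- c(rep(1, 25), rep(0, n - 25))
  tab <- as_efo_table(tibble::tibble(d = as.double(seq_len(n)), label = lab))
  filt <- filter_descriptors(tab, cutoff = 1)
  expect_identical(filt$direction[1], "ascending")
  expect_gt(filt$ef_top5[1], 2)
})

test_that("random starts: count, determinism, and sigma-scaled range", {
  s1 <- withr::with_seed(1, random_starts(3))
  expect_identical(dim(s1), c(36L, 3L)) # 12 cycles per variable
  s2 <- withr::with_seed(1, random_starts(3))
  expect_identical(s1, s2)

  sds <- c(0.01, 1, 100)
  draws <- withr::with_seed(2, random_starts(3, cycles = 10000, scale_sd = sds))
  for (j in 1:3) {
    expect_lte(max(abs(draws[, j])), 1 / sds[j])
    expect_gt(max(abs(draws[, j])), 0.97 / sds[j]) # range nearly filled
    expect_lt(abs(mean(draws[, j])), 0.02 / sds[j])
  }
  expect_message(random_starts(2, 4, scale_sd = c(0, 1)), "Zero-variance")
})

test_that("optimize_combination recovers a planted linear signal perfectly", {
  tab <- planted_linear_table(n = 120, n_pos = 20)
  cfg <- efo_config(seed = 5, cluster_size = 20, n_variables = 2)
  mod <- withr::with_seed(5, optimize_combination(tab, c("x1", "x2"), cfg))
  r <- rank_instances(tab, mod)
  # all 20 positives occupy the first 20 positions: perfect early recognition
  expect_identical(sum(r$label[1:20]), 20L)
  expect_identical(abs(mod$coefficients[1]), 1)
})

test_that("coefficient normalization preserves rankings and threshold classes", {
  tab <- planted_linear_table(n = 80, n_pos = 12)
  m_raw <- efo_model(c("x1", "x2"), c(2, 4.94))
  expect_identical(m_raw$coefficients, c(1, 2.47))
  m_half <- efo_model(c("x1", "x2"), c(1, 2.47))
  expect_identical(rank_instances(tab, m_raw)$id, rank_instances(tab, m_half)$id)
})

test_that("optimization is deterministic given the seed and beats every random start", {
  tab <- planted_linear_table(n = 100, n_pos = 15)
  cfg <- efo_config(seed = 3, cluster_size = 15, n_variables = 2,
                    sampling_cycles_per_variable = 6, hj_iterations = 500)
  m1 <- withr::with_seed(3, optimize_combination(tab, c("x1", "z1"), cfg))
  m2 <- withr::with_seed(3, optimize_combination(tab, c("x1", "z1"), cfg))
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$train_quality, m2$train_quality)

  # optimizer monotonicity: final quality >= quality of every start it saw
  obj <- efo:::quality_objective(tab, c("x1", "z1"), 15)
  sds <- apply(descriptor_matrix(tab)[, c("x1", "z1")], 2, sd)
  starts <- withr::with_seed(3, random_starts(2, 12, scale_sd = sds))
  start_vals <- apply(starts, 1, obj)
  expect_gte(m1$train_quality, max(start_vals))
})

test_that("set_threshold takes the rank-n score and >= classifies the boundary", {
  tab <- as_efo_table(tibble::tibble(x = c(5, 4, 3, 2, 1),
                                     label = c(1, 1, 0, 0, 0)))
  m <- set_threshold(efo_model("x", 1), tab)
  expect_identical(m$threshold, 4)
  pred <- suppressWarnings(predict(m, tab))
  expect_identical(sum(pred$class), 2L) # n_positive predicted positive on train
  # an external instance scoring exactly the threshold is positive
  ext <- as_efo_table(tibble::tibble(x = 4, label = 0))
  expect_identical(suppressWarnings(predict(m, ext))$class, 1L)
})

test_that("probability profile: bin arithmetic, separable extremes, conservation", {
  n <- 500
  lab <- c(rep(1, 70), rep(0, n - 70))
  tab <- as_efo_table(tibble::tibble(d = as.double(rev(seq_len(n))),
                                     label = lab))
  m <- set_threshold(efo_model("d", 1), tab)
  prof <- probability_profile(m, tab, bin_fraction = 0.02)
  expect_identical(nrow(prof), 50L)          # 2% of 500 = 10-instance bins
  expect_true(all(prof$n == 10L))
  expect_identical(prof$fraction[1], 1)      # top bins pure positive
  expect_identical(prof$fraction[50], 0)     # bottom bins pure negative
  expect_equal(sum(prof$fraction * prof$n) / n, 70 / n) # conservation
  expect_true(all(prof$fraction >= 0 & prof$fraction <= 1))
  expect_error(probability_profile(m, tab, bin_fraction = 0.7), "0.5")
})

test_that("predict attaches probabilities from the profile and clamps extremes", {
  n <- 200
  lab <- c(rep(1, 30), rep(0, n - 30))
  tab <- as_efo_table(tibble::tibble(d = as.double(rev(seq_len(n))),
                                     label = lab))
  m <- set_threshold(efo_model("d", 1), tab)
  m$profile <- probability_profile(m, tab, bin_fraction = 0.1)
  new <- as_efo_table(tibble::tibble(d = c(1e6, -1e6, 195.0), label = c(0, 0, 0)))
  pred <- predict(m, new)
  expect_identical(pred$probability[1], m$profile$fraction[1])  # above range
  expect_identical(pred$probability[2], m$profile$fraction[nrow(m$profile)])
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_identical(pred$class, c(1L, 0L, 1L))

  m_np <- set_threshold(efo_model("d", 1), tab)
  expect_warning(p2 <- predict(m_np, new), "no probability profile")
  expect_true(all(is.na(p2$probability)))
})

test_that("fit enumerates C(m, k) combinations and keeps a sorted, capped model list", {
  tab <- planted_linear_table(n = 150, n_pos = 21, seed = 8)
  cfg <- efo_config(seed = 2, n_variables = 3, ef_filter_cutoff = 0,
                    sampling_cycles_per_variable = 4, hj_iterations = 200,
                    n_models_kept = 3)
  fit <- suppressMessages(efo_fit(tab, cfg))
  expect_identical(fit$search, "exhaustive")
  expect_identical(fit$n_combinations, as.integer(choose(4, 3)))
  expect_lte(length(fit$models), 3L)
  expect_true(all(diff(fit$results$train_quality) <= 0))
  expect_identical(fit$config$cluster_size, 21L) # defaults to n_positive
  # every kept model carries threshold + profile
  for (m in fit$models) {
    expect_false(is.na(m$threshold))
    expect_s3_class(m$profile, "efo_profile")
  }
})

test_that("fit is deterministic given (table, config, seed)", {
  tab <- planted_linear_table(n = 100, n_pos = 15, seed = 4)
  cfg <- efo_config(n_variables = 2, ef_filter_cutoff = 0,
                    sampling_cycles_per_variable = 4, hj_iterations = 200,
                    n_models_kept = 4)
  f1 <- efo_fit(tab, cfg, seed = 11)
  f2 <- efo_fit(tab, cfg, seed = 11)
  expect_identical(f1$results, f2$results)
  expect_identical(purrr::map(f1$models, "coefficients"),
                   purrr::map(f2$models, "coefficients"))
})

test_that("fit errors helpfully when the filter leaves too few descriptors", {
  tab <- planted_linear_table(n = 100, n_pos = 15)
  cfg <- efo_config(n_variables = 4, ef_filter_cutoff = 50)
  expect_error(efo_fit(tab, cfg, seed = 1), "lower `ef_filter_cutoff`")
})

test_that("greedy forward construction engages above max_combinations and stays deterministic", {
  tab <- planted_linear_table(n = 100, n_pos = 15, seed = 6)
  cfg <- efo_config(n_variables = 3, ef_filter_cutoff = 0,
                    sampling_cycles_per_variable = 3, hj_iterations = 100,
                    n_models_kept = 2, max_combinations = 2)
  f1 <- efo_fit(tab, cfg, seed = 9)
  expect_identical(f1$search, "greedy")
  f2 <- efo_fit(tab, cfg, seed = 9)
  expect_identical(f1$results, f2$results)
  expect_identical(length(f1$models[[1]]$variables), 3L)
})

test_that("tidy/glance/augment provide broom-style views of a fit", {
  tab <- planted_linear_table(n = 100, n_pos = 15, seed = 2)
  cfg <- efo_config(n_variables = 2, ef_filter_cutoff = 0,
                    sampling_cycles_per_variable = 3, hj_iterations = 100,
                    n_models_kept = 2)
  fit <- efo_fit(tab, cfg, seed = 1)
  td <- tidy(fit)
  expect_true(all(c("model", "term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$search, "exhaustive")
  aug <- augment(fit$models[[1]], tab)
  expect_identical(nrow(aug), nrow(tab))
  expect_true(all(c(".score", ".class", ".probability") %in% names(aug)))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
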