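# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths. They operate on a plain 0/1 label
# vector already in ranking order.

oracle_prefix_size <- function(f, n) max(1, floor(f * n + 0.5))

oracle_ef <- function(labels_ranked, f) {
  n <- length(labels_ranked)
  p <- sum(labels_ranked)
  m <- oracle_prefix_size(f, n)
  hits <- 0
  for (i in seq_len(m)) hits <- hits + labels_ranked[i]
  (hits / m) / (p / n)
}

oracle_cluster_counts <- function(labels_ranked, cluster_size) {
  groups <- split(labels_ranked,
                  ceiling(seq_along(labels_ranked) / cluster_size))
  vapply(groups, sum, numeric(1), USE.NAMES = FALSE)
}

oracle_cluster_percentages <- function(labels_ranked, cluster_size) {
  groups <- split(labels_ranked,
                  ceiling(seq_along(labels_ranked) / cluster_size))
  vapply(groups, function(g) 100 * sum(g) / length(g), numeric(1),
         USE.NAMES = FALSE)
}

# two-pass population skewness
oracle_skewness <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  if (m2 == 0) return(0)
  m3 / m2^(3 / 2)
}

oracle_quality <- function(labels_ranked, cluster_size) {
  pct <- oracle_cluster_percentages(labels_ranked, cluster_size)
  oracle_skewness(pct) * pct[1]
}

# set-based confusion: predicted positives are the first k ranked instances
oracle_confusion <- function(labels_ranked, k) {
  n <- length(labels_ranked)
  idx <- seq_len(n)
  pred_pos <- idx[idx <= k]
  true_pos <- idx[labels_ranked == 1]
  tp <- length(intersect(pred_pos, true_pos))
  fp <- length(setdiff(pred_pos, true_pos))
  fn <- length(setdiff(true_pos, pred_pos))
  tn <- n - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# MCC as the Pearson correlation of the binary truth/prediction vectors
oracle_mcc <- function(cm) {
  truth <- c(rep(1, cm$tp), rep(1, cm$fn), rep(0, cm$fp), rep(0, cm$tn))
  pred <- c(rep(1, cm$tp), rep(0, cm$fn), rep(1, cm$fp), rep(0, cm$tn))
  if (sd(truth) == 0 || sd(pred) == 0) return(0)
  stats::cor(truth, pred)
}

# all 0/1 label vectors of length n, as rows
all_label_vectors <- function(n) {
  as.matrix(expand.grid(rep(list(0:1), n)))
}

# a ranking object from labels already in rank order (descending scores)
ranking_from_labels <- function(labels_ranked) {
  n <- length(labels_ranked)
  efo:::new_ranking(scores = as.double(n:1), labels = labels_ranked)
}

random_ranking <- function(n) {
  scores <- round(rnorm(n), 1) # coarse scores so ties occur
  labels <- sample(0:1, n, replace = TRUE)
  efo:::new_ranking(scores, labels)
}
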