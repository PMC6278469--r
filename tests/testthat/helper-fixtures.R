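# Small fixtures built in code.

tiny_table <- function() {
  as_efo_table(tibble::tibble(id = c("a", "b", "c", "d"),
                              x1 = c(3, 1, 2, 4),
                              x2 = c(0.5, 0.1, 0.9, 0.2),
                              label = c(0, 1, 0, 1)),
               label = "label", id = "id")
}

# exactly linearly separable by score = x1 + 2 * x2: labels are the top
# n_pos of that known linear score, plus pure-noise descriptors
planted_linear_table <- function(n = 120, n_pos = 20, seed = 42) {
  withr::with_seed(seed, {
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    s <- x1 + 2 * x2
    lab <- as.integer(rank(-s, ties.method = "first") <= n_pos)
    as_efo_table(tibble::tibble(x1 = x1, x2 = x2, z1 = z1, z2 = z2,
                                label = lab), label = "label")
  })
}

write_arff_fixture <- function(path) {
  writeLines(c(
    "@relation sonar_toy",
    "@attribute band1 numeric",
    "@attribute band2 numeric",
    "@attribute class {rock, metal}",
    "@data",
    "0.02, 0.37, rock",
    "0.45, 0.11, metal",
    "0.31, 0.24, metal",
    "0.05, 0.40, rock"
  ), path)
  path
}
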