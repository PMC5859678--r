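# Shared fixtures built in code.

# the 4-row, 2-cluster, 1-indicator hand example: clusters {0,2} and {4,6}
toy_dataset <- function() {
  multilevel_dataset(cbind(y = c(0, 2, 4, 6)),
                     cluster_id = rep(c("a", "b"), each = 2))
}

# random clustered dataset (optionally unbalanced, may include singleton
# clusters) from a 1-factor two-level population
random_dataset <- function(seed, p = 3, G = 8, balanced = TRUE) {
  set.seed(seed)
  sizes <- if (balanced) rep(5, G) else sample(1:8, G, replace = TRUE)
  if (sum(sizes) <= G) sizes[1] <- sizes[1] + 2
  lab <- paste0("y", seq_len(p))
  pop <- two_level_population(
    within = level_params(matrix(runif(p, 0.5, 1), p, 1,
                                 dimnames = list(lab, "f")),
                          1, runif(p, 0.3, 0.8)),
    between = level_params(matrix(runif(p, 0.3, 0.8), p, 1,
                                  dimnames = list(lab, "f")),
                           1, runif(p, 0.2, 0.5)),
    G = G, n = sizes)
  generate_dataset(pop, seed = seed)
}

# well-identified single-factor-per-level instances (both levels strongly
# determined), for oracle-equivalence checks
random_dataset_strong <- function(seed, p = 4, G = 40, n = 25) {
  set.seed(seed)
  lab <- paste0("y", seq_len(p))
  pop <- two_level_population(
    within = level_params(matrix(runif(p, 0.6, 1), p, 1,
                                 dimnames = list(lab, "f")),
                          1, runif(p, 0.3, 0.8)),
    between = level_params(matrix(runif(p, 0.5, 1), p, 1,
                                  dimnames = list(lab, "f")),
                           1, runif(p, 0.2, 0.5)),
    G = G, n = n)
  generate_dataset(pop, seed = seed)
}

study1_within <- function(marker_value = 1)
  factor_pattern(list(f1 = c("wordst", "cards", "matrix"),
                      f2 = c("figure", "animal", "occpat")),
                 marker_value = marker_value)

study1_between <- function()
  factor_pattern(list(B_f1 = c("wordst", "cards", "matrix",
                               "figure", "animal", "occpat")))

bench_within <- function(marker_value = 0.8)
  factor_pattern(list(W_f1 = paste0("V", 1:9)),
                 marker_value = marker_value)

bench_between <- function(marker_value = 0.8)
  factor_pattern(list(B_f1 = paste0("V", 1:3),
                      B_f2 = paste0("V", 4:6),
                      B_f3 = paste0("V", 7:9)),
                 marker_value = marker_value)

extdata <- function(f) system.file("extdata", f, package = "mlcfa")
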