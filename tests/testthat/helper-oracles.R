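# Independent brute-force oracles used to cross-check the implementation.

# k nearest neighbors of row i by explicit enumeration (ties to the lower
# index, self excluded) — deliberately written as plain loops, independent
# of the package's vectorized distance code.
brute_knn <- function(x, i, k, pool = seq_len(nrow(x))) {
  cand <- pool[pool != i]
  d <- numeric(length(cand))
  for (j in seq_along(cand)) {
    d[j] <- sqrt(sum((x[i, ] - x[cand[j], ])^2))
  }
  ord <- order(d, cand)
  cand[ord[seq_len(k)]]
}

# Exhaustive Tomek-link finder: all cross-class mutual nearest pairs.
brute_tomek_pairs <- function(x, y) {
  n <- nrow(x)
  nn <- integer(n)
  for (i in seq_len(n)) nn[i] <- brute_knn(x, i, 1)
  pairs <- list()
  for (i in seq_len(n)) {
    j <- nn[i]
    if (j > i && nn[j] == i && y[i] != y[j]) {
      pairs[[length(pairs) + 1]] <- c(i, j)
    }
  }
  pairs
}

# Exhaustive application of the two-stage neighborhood cleaning rule.
brute_ncr_removed <- function(x, y, k = 3, majority = "majority") {
  n <- nrow(x)
  removed1 <- integer(0)
  for (i in which(y == majority)) {
    nb <- brute_knn(x, i, k)
    if (sum(y[nb] != majority) > k / 2) removed1 <- c(removed1, i)
  }
  keep <- setdiff(seq_len(n), removed1)
  removed2 <- integer(0)
  for (i in keep[y[keep] == majority]) {
    others <- setdiff(keep, i)
    d <- numeric(length(others))
    for (j in seq_along(others)) {
      d[j] <- sqrt(sum((x[i, ] - x[others[j], ])^2))
    }
    nn <- others[order(d, others)][1]
    if (y[nn] == majority) removed2 <- c(removed2, i)
  }
  sort(c(removed1, removed2))
}

# Small fast session config used across tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_channels = 4, n_train_blocks = 4, n_test_blocks = 2,
         p300_amplitude = 10, noise_sd = 5),
    list(...))
  do.call(synthetic_config, args)
}

# Labelled two-cluster matrix with explicit coordinates.
toy_xy <- function(toy) list(x = toy$x, y = toy$labels)
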