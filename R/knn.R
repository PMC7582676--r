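# Exact k-nearest-neighbor queries by full pairwise Euclidean distance.
# Sampler datasets are at most a few hundred rows, so the quadratic search
# is both fast enough and free of approximation; ties are broken by the
# lower candidate index and a query point never appears in its own list.

pairwise_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# k nearest rows of `pool` (matrix, with `pool_idx` giving their identities)
# for each row of `query`; `query_idx` marks identities to exclude as self.
# Returns an n_query x k matrix of pool identities.
knn_index <- function(query, pool, k, query_idx = NULL,
                      pool_idx = seq_len(nrow(pool))) {
  d <- pairwise_dist(query, pool)
  out <- matrix(NA_integer_, nrow(query), k)
  for (i in seq_len(nrow(query))) {
    di <- d[i, ]
    if (!is.null(query_idx)) di[pool_idx == query_idx[i]] <- Inf
    ord <- order(di, pool_idx)
    out[i, ] <- pool_idx[ord[seq_len(k)]]
  }
  out
}

# Identity of the single nearest neighbor for each row, self excluded.
nn1_index <- function(x, idx = seq_len(nrow(x))) {
  knn_index(x, x, 1, query_idx = idx, pool_idx = idx)[, 1]
}
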