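#' Parameters shared by the resampling methods
#'
#' @param k Number of neighbors used for synthesis (SMOTE family) and for
#'   the ADASYN density estimate. Default 5.
#' @param m Number of neighbors used for the DANGER / support-vector
#'   qualification tests in borderline-SMOTE and SVM-SMOTE. Default 10.
#' @param beta ADASYN balance level in `[0, 1]`; 1 aims at fully equal
#'   class sizes.
#' @param sampling_ratio Desired minority:majority ratio after
#'   oversampling (or the inverse for undersampling), in `(0, 1]`. 1 means
#'   full balancing.
#' @param ncr_k Neighbor count of the neighborhood cleaning rule
#'   (default 3).
#' @param seed Optional integer seed; a fixed seed makes every sampler
#'   fully reproducible.
#' @return An object of class `sampler_params`.
#' @export
sampler_params <- function(k = 5, m = 10, beta = 1, sampling_ratio = 1,
                           ncr_k = 3, seed = NULL) {
  if (k < 1) stop("k must be >= 1")
  if (m < k) stop("m must be >= k")
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]")
  if (sampling_ratio <= 0 || sampling_ratio > 1) {
    stop("sampling_ratio must be in (0, 1]")
  }
  structure(list(k = as.integer(k), m = as.integer(m), beta = beta,
                 sampling_ratio = sampling_ratio, ncr_k = as.integer(ncr_k),
                 seed = seed),
            class = "sampler_params")
}

# Identify minority/majority classes by size. On a tie the `target` level
# (when present) is treated as the minority so that BCI feature sets keep
# their semantics; otherwise the first factor level is.
class_split <- function(y) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) != 2) stop("need exactly two classes")
  tab <- table(droplevels(y))
  if (tab[1] == tab[2]) {
    min_lab <- if ("target" %in% names(tab)) "target" else names(tab)[1]
  } else {
    min_lab <- names(tab)[which.min(tab)]
  }
  maj_lab <- setdiff(names(tab), min_lab)
  list(minority = min_lab, majority = maj_lab,
       min_idx = which(y == min_lab), maj_idx = which(y == maj_lab))
}

sampler_result <- function(x, y, method, params, original = NULL,
                           synthetic = NULL, removed = integer(0),
                           extra = list()) {
  structure(c(list(x = x, y = y, method = method, params = params,
                   synthetic = synthetic, removed = removed),
              extra),
            class = "sampler_result")
}

#' @export
print.sampler_result <- function(x, ...) {
  tab <- table(x$y)
  cat(sprintf("<sampler_result> %s: %s%s%s\n", x$method,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              if (!is.null(x$synthetic)) sprintf("; %d synthesized",
                                                 nrow(x$synthetic)) else "",
              if (length(x$removed)) sprintf("; %d removed",
                                             length(x$removed)) else ""))
  invisible(x)
}

resolve_xy <- function(x, y) {
  if (inherits(x, "feature_dataset")) return(list(x = x$x, y = x$y))
  if (inherits(x, "toy_dataset")) return(list(x = x$x, y = x$labels))
  list(x = as.matrix(x), y = as.factor(y))
}

with_sampler_seed <- function(params, expr) {
  if (is.null(params$seed)) expr else withr::with_seed(params$seed, expr)
}

# Core SMOTE interpolation step: for each seed p with a positive count,
# draw a neighbor d uniformly among its k nearest minority neighbors and a
# gap r ~ U(0, 1), and emit s = p + r * (neighbor - p).
synthesize <- function(x, parents, counts, neighbor_idx) {
  total <- sum(counts)
  if (total == 0) {
    return(list(x = x[0, , drop = FALSE],
                provenance = data.frame(parent = integer(0),
                                        neighbor = integer(0),
                                        r = numeric(0))))
  }
  parent_of <- rep(parents, counts)
  nb_row <- match(parent_of, parents)
  chosen <- neighbor_idx[cbind(nb_row,
                               sample.int(ncol(neighbor_idx), total,
                                          replace = TRUE))]
  r <- stats::runif(total)
  sx <- x[parent_of, , drop = FALSE] +
    r * (x[chosen, , drop = FALSE] - x[parent_of, , drop = FALSE])
  list(x = sx,
       provenance = data.frame(parent = parent_of, neighbor = chosen, r = r))
}

n_to_synthesize <- function(n_min, n_maj, sampling_ratio) {
  max(0L, as.integer(ceiling(sampling_ratio * n_maj)) - n_min)
}

oversample_from <- function(x, y, parents, params, method, extra = list()) {
  cs <- class_split(y)
  n_new <- n_to_synthesize(length(cs$min_idx), length(cs$maj_idx),
                           params$sampling_ratio)
  if (n_new == 0 || length(parents) == 0) {
    return(sampler_result(x, y, method, params, extra = extra))
  }
  nb <- knn_index(x[parents, , drop = FALSE],
                  x[cs$min_idx, , drop = FALSE], params$k,
                  query_idx = parents, pool_idx = cs$min_idx)
  counts <- rep(n_new %/% length(parents), length(parents))
  rem <- n_new %% length(parents)
  if (rem > 0) {
    pick <- sample.int(length(parents), rem)
    counts[pick] <- counts[pick] + 1L
  }
  syn <- synthesize(x, parents, counts, nb)
  new_x <- rbind(x, syn$x)
  new_y <- factor(c(as.character(y),
                    rep(cs$minority, nrow(syn$x))), levels = levels(y))
  syn$provenance$row <- nrow(x) + seq_len(nrow(syn$provenance))
  sampler_result(new_x, new_y, method, params, synthetic = syn$provenance,
                 extra = extra)
}

#' Random oversampling
#'
#' Grows the minority class by copying randomly chosen minority rows (with
#' replacement) until the class sizes satisfy `sampling_ratio`.
#'
#' @param x Feature matrix, `feature_dataset`, or `toy_dataset`.
#' @param y Two-class factor (ignored when `x` carries labels).
#' @param params A [sampler_params()].
#' @return A `sampler_result` with the resampled `x`, `y`, and for each
#'   appended row the index of the original it copies (in `synthetic`,
#'   with `r = 0` and `neighbor = parent` since no interpolation occurs).
#' @export
ros <- function(x, y = NULL, params = sampler_params()) {
  d <- resolve_xy(x, y)
  cs <- class_split(d$y)
  if (length(cs$min_idx) < 1) stop("minority class is empty")
  with_sampler_seed(params, {
    n_new <- n_to_synthesize(length(cs$min_idx), length(cs$maj_idx),
                             params$sampling_ratio)
    if (n_new == 0) {
      return(sampler_result(d$x, d$y, "ros", params))
    }
    pick <- cs$min_idx[sample.int(length(cs$min_idx), n_new, replace = TRUE)]
    new_x <- rbind(d$x, d$x[pick, , drop = FALSE])
    new_y <- factor(c(as.character(d$y), rep(cs$minority, n_new)),
                    levels = levels(d$y))
    sampler_result(new_x, new_y, "ros", params,
                   synthetic = data.frame(parent = pick, neighbor = pick,
                                          r = 0,
                                          row = nrow(d$x) + seq_len(n_new)))
  })
}

#' Synthetic minority oversampling technique (SMOTE)
#'
#' New minority instances are linear interpolations `s = p + r * (q - p)`
#' between a minority seed `p` and one of its `k` nearest minority
#' neighbors `q`, with `r` uniform on `(0, 1)`. Seeds are used as evenly as
#' possible until the requested balance is reached.
#'
#' @inheritParams ros
#' @return A `sampler_result`; `synthetic` records parent, neighbor and
#'   interpolation factor of every synthesized row.
#' @export
smote <- function(x, y = NULL, params = sampler_params()) {
  d <- resolve_xy(x, y)
  cs <- class_split(d$y)
  if (length(cs$min_idx) <= params$k) {
    stop("SMOTE needs more than k minority instances")
  }
  with_sampler_seed(params,
    oversample_from(d$x, d$y, cs$min_idx, params, "smote"))
}

danger_set <- function(x, y, cs, m, exclude_noise = FALSE) {
  nb <- knn_index(x[cs$min_idx, , drop = FALSE], x, m,
                  query_idx = cs$min_idx)
  maj_count <- rowSums(matrix(y[nb] == cs$majority, nrow = nrow(nb)))
  sel <- maj_count > m / 2
  if (exclude_noise) sel <- sel & maj_count < m
  list(idx = cs$min_idx[sel], maj_count = maj_count)
}

#' Borderline-SMOTE
#'
#' Restricts SMOTE synthesis to the DANGER set: minority instances whose
#' `m`-nearest neighborhood (over the full dataset) contains more majority
#' than minority points. Interpolation partners are the `k` nearest
#' *minority* neighbors of each DANGER member.
#'
#' @inheritParams ros
#' @param exclude_noise If `TRUE`, minority points whose `m` neighbors are
#'   *all* majority are treated as noise and excluded from the DANGER set
#'   (the behavior of the original borderline-SMOTE publication). The
#'   default `FALSE` keeps every point passing the more-than-half rule.
#' @return A `sampler_result`; when the DANGER set is empty the dataset is
#'   returned unchanged with a warning.
#' @export
borderline_smote <- function(x, y = NULL, params = sampler_params(),
                             exclude_noise = FALSE) {
  d <- resolve_xy(x, y)
  cs <- class_split(d$y)
  if (length(cs$min_idx) <= params$k) {
    stop("borderline-SMOTE needs more than k minority instances")
  }
  ds <- danger_set(d$x, d$y, cs, params$m, exclude_noise)
  if (length(ds$idx) == 0) {
    warning("DANGER set is empty; returning dataset unchanged")
    return(sampler_result(d$x, d$y, "b-smote", params,
                          extra = list(danger = integer(0))))
  }
  with_sampler_seed(params,
    oversample_from(d$x, d$y, ds$idx, params, "b-smote",
                    extra = list(danger = ds$idx)))
}

#' SVM-SMOTE
#'
#' Trains a soft-margin SVM on the dataset and uses the minority-class
#' support vectors as synthesis seeds, keeping only those with fewer than
#' half majority points among their `m` nearest neighbors. Interpolation
#' partners are the `k` nearest minority neighbors.
#'
#' @inheritParams ros
#' @param spec An [svm_spec()] for the internal SVM (default `C = 1`,
#'   linear kernel).
#' @return A `sampler_result`; unchanged with a warning when no support
#'   vector qualifies.
#' @export
svm_smote <- function(x, y = NULL, params = sampler_params(),
                      spec = svm_spec()) {
  d <- resolve_xy(x, y)
  cs <- class_split(d$y)
  if (length(cs$min_idx) <= params$k) {
    stop("SVM-SMOTE needs more than k minority instances")
  }
  model <- train_svm(d$x, d$y, spec, positive = cs$minority)
  sv_idx <- model$fit$index
  min_sv <- intersect(sv_idx, cs$min_idx)
  if (length(min_sv) == 0) {
    warning("no minority support vectors; returning dataset unchanged")
    return(sampler_result(d$x, d$y, "svm-smote", params,
                          extra = list(parents = integer(0))))
  }
  nb <- knn_index(d$x[min_sv, , drop = FALSE], d$x, params$m,
                  query_idx = min_sv)
  maj_count <- rowSums(matrix(d$y[nb] == cs$majority, nrow = nrow(nb)))
  seeds <- min_sv[maj_count < params$m / 2]
  if (length(seeds) == 0) {
    warning("no qualifying minority support vectors; dataset unchanged")
    return(sampler_result(d$x, d$y, "svm-smote", params,
                          extra = list(parents = integer(0))))
  }
  with_sampler_seed(params,
    oversample_from(d$x, d$y, seeds, params, "svm-smote",
                    extra = list(parents = seeds)))
}

#' Adaptive synthetic sampling (ADASYN)
#'
#' The total synthesis budget is `G = beta * (|S_maj| - |S_min|)`. Each
#' minority instance i gets a share proportional to the fraction
#' `delta(i) / k` of majority points among its `k` nearest neighbors,
#' normalized over the minority class (`gamma(i)`, summing to 1); the
#' per-instance count is `g(i) = ceiling(gamma(i) * G)`, so harder,
#' borderline instances receive more synthetic data. Synthesis itself is
#' the SMOTE interpolation toward the `k` nearest minority neighbors.
#'
#' @inheritParams ros
#' @return A `sampler_result`; `adasyn` holds `G`, `Z`, `delta`, `gamma`
#'   and `g` per minority instance. When no minority point has majority
#'   neighbors (`Z = 0`) the budget is spread uniformly.
#' @export
adasyn <- function(x, y = NULL, params = sampler_params()) {
  d <- resolve_xy(x, y)
  cs <- class_split(d$y)
  if (length(cs$min_idx) <= params$k) {
    stop("ADASYN needs more than k minority instances")
  }
  n_min <- length(cs$min_idx)
  G <- params$beta * (length(cs$maj_idx) - n_min)
  nb <- knn_index(d$x[cs$min_idx, , drop = FALSE], d$x, params$k,
                  query_idx = cs$min_idx)
  delta <- rowSums(matrix(d$y[nb] == cs$majority, nrow = nrow(nb)))
  Z <- sum(delta / params$k)
  gamma <- if (Z == 0) rep(1 / n_min, n_min) else (delta / params$k) / Z
  g <- as.integer(ceiling(gamma * G))
  info <- list(adasyn = list(G = G, Z = Z, delta = delta, gamma = gamma,
                             g = g))
  if (sum(g) == 0) {
    return(sampler_result(d$x, d$y, "adasyn", params, extra = info))
  }
  with_sampler_seed(params, {
    parents <- cs$min_idx[g > 0]
    nb_min <- knn_index(d$x[parents, , drop = FALSE],
                        d$x[cs$min_idx, , drop = FALSE], params$k,
                        query_idx = parents, pool_idx = cs$min_idx)
    syn <- synthesize(d$x, parents, g[g > 0], nb_min)
    new_x <- rbind(d$x, syn$x)
    new_y <- factor(c(as.character(d$y), rep(cs$minority, nrow(syn$x))),
                    levels = levels(d$y))
    syn$provenance$row <- nrow(d$x) + seq_len(nrow(syn$provenance))
    sampler_result(new_x, new_y, "adasyn", params,
                   synthetic = syn$provenance, extra = info)
  })
}

undersample_result <- function(x, y, keep, method, params, extra = list()) {
  removed <- setdiff(seq_len(nrow(x)), keep)
  sampler_result(x[keep, , drop = FALSE], y[keep],
                 method, params, removed = removed, extra = extra)
}

#' Random undersampling
#'
#' Removes uniformly chosen majority rows (without replacement) until the
#' class sizes satisfy `sampling_ratio`.
#'
#' @inheritParams ros
#' @return A `sampler_result`; `removed` lists the dropped original rows.
#' @export
rus <- function(x, y = NULL, params = sampler_params()) {
  d <- resolve_xy(x, y)
  cs <- class_split(d$y)
  n_keep <- min(length(cs$maj_idx),
                as.integer(ceiling(length(cs$min_idx) /
                                     params$sampling_ratio)))
  with_sampler_seed(params, {
    keep_maj <- sort(cs$maj_idx[sample.int(length(cs$maj_idx), n_keep)])
    keep <- sort(c(cs$min_idx, keep_maj))
    undersample_result(d$x, d$y, keep, "rus", params)
  })
}

#' Neighborhood cleaning rule (NCR)
#'
#' Two-stage majority-class cleaning. Stage 1 (edited nearest neighbors):
#' a majority instance is removed when more than half of its `ncr_k`
#' nearest neighbors are not majority. Stage 2 is then applied to the
#' cleaned set: a surviving majority instance is removed when its single
#' nearest neighbor (within the cleaned set) is itself majority, and kept
#' when that neighbor is minority. Stage 2 is evaluated simultaneously for
#' all instances on the stage-1 result. Minority instances are never
#' removed.
#'
#' Note that stage 2 as stated inverts the classic condensed-nearest-
#' neighbor rule (it prunes interior majority points rather than keeping a
#' consistent subset); it is implemented as stated.
#'
#' @inheritParams ros
#' @return A `sampler_result` with `removed` split into `removed_enn` and
#'   `removed_cnn` provenance.
#' @export
ncr <- function(x, y = NULL, params = sampler_params()) {
  d <- resolve_xy(x, y)
  cs <- class_split(d$y)
  k <- params$ncr_k
  if (length(cs$maj_idx) <= k) stop("NCR needs more than ncr_k majority rows")
  nb <- knn_index(d$x[cs$maj_idx, , drop = FALSE], d$x, k,
                  query_idx = cs$maj_idx)
  not_maj <- rowSums(matrix(d$y[nb] != cs$majority, nrow = nrow(nb)))
  removed_enn <- cs$maj_idx[not_maj > k / 2]
  keep1 <- setdiff(seq_len(nrow(d$x)), removed_enn)
  x1 <- d$x[keep1, , drop = FALSE]
  y1 <- d$y[keep1]
  maj1 <- which(y1 == cs$majority)
  removed_cnn <- integer(0)
  if (length(maj1) > 0 && length(keep1) > 1) {
    nn1 <- knn_index(x1[maj1, , drop = FALSE], x1, 1,
                     query_idx = maj1)[, 1]
    removed_cnn <- keep1[maj1[y1[nn1] == cs$majority]]
  }
  keep <- setdiff(seq_len(nrow(d$x)), c(removed_enn, removed_cnn))
  undersample_result(d$x, d$y, keep, "ncr", params,
                     extra = list(removed_enn = removed_enn,
                                  removed_cnn = removed_cnn))
}

#' Tomek links undersampling
#'
#' A Tomek link is a pair of points from different classes that are each
#' other's nearest neighbor. All minority data are kept; the majority
#' member of every link is removed in a single pass.
#'
#' @inheritParams ros
#' @return A `sampler_result`.
#' @export
tomek <- function(x, y = NULL, params = sampler_params()) {
  d <- resolve_xy(x, y)
  cs <- class_split(d$y)
  nn <- nn1_index(d$x)
  in_link <- vapply(seq_len(nrow(d$x)), function(i) {
    j <- nn[i]
    nn[j] == i && d$y[i] != d$y[j]
  }, logical(1))
  drop <- which(in_link & d$y == cs$majority)
  keep <- setdiff(seq_len(nrow(d$x)), drop)
  undersample_result(d$x, d$y, keep, "tomek", params)
}

#' Available within-dataset sampler names
#' @return Character vector of method names accepted by [apply_sampler()].
#' @export
sampler_methods <- function() {
  c("ros", "smote", "b-smote", "svm-smote", "adasyn", "rus", "ncr", "tomek")
}

#' Apply a sampler by name
#'
#' @param method One of [sampler_methods()].
#' @inheritParams ros
#' @param spec [svm_spec()] used by `"svm-smote"`.
#' @return The method's `sampler_result`.
#' @export
apply_sampler <- function(method, x, y = NULL, params = sampler_params(),
                          spec = svm_spec()) {
  switch(match.arg(method, sampler_methods()),
         "ros" = ros(x, y, params),
         "smote" = smote(x, y, params),
         "b-smote" = borderline_smote(x, y, params),
         "svm-smote" = svm_smote(x, y, params, spec),
         "adasyn" = adasyn(x, y, params),
         "rus" = rus(x, y, params),
         "ncr" = ncr(x, y, params),
         "tomek" = tomek(x, y, params))
}
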