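test_that("kNN queries match the brute-force oracle", {
  set.seed(41)
  for (rep in 1:3) {
    n <- sample(20:120, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    k <- sample(1:8, 1)
    got <- p300balance:::knn_index(x, x, k, query_idx = seq_len(n))
    for (i in sample(n, 10)) {
      expect_equal(got[i, ], brute_knn(x, i, k))
    }
  }
})

test_that("SMOTE interpolation follows s = p + r (q - p)", {
  # direct arithmetic: parent (0,0), sole neighborhood along the segment
  x <- rbind(c(0, 0), c(1, 1), c(0.1, 0), c(0, 0.1), c(0.9, 1), c(1, 0.9),
             c(10, 10), c(10, 11), c(11, 10), c(11, 11),
             c(10.5, 10.5), c(10.2, 10.8), c(10.8, 10.2), c(10.4, 10.4),
             c(10.6, 10.6), c(10.3, 10.3), c(10.1, 10.1), c(10.9, 10.9))
  y <- factor(c(rep("minority", 6), rep("majority", 12)),
              levels = c("minority", "majority"))
  r <- smote(x, y, sampler_params(k = 5, seed = 7))
  expect_equal(sum(r$y == "minority"), sum(r$y == "majority"))
  # every synthetic point lies on the segment between parent and neighbor
  for (i in seq_len(nrow(r$synthetic))) {
    p <- x[r$synthetic$parent[i], ]
    q <- x[r$synthetic$neighbor[i], ]
    s <- r$x[r$synthetic$row[i], ]
    expect_equal(unname(s), unname(p + r$synthetic$r[i] * (q - p)),
                 tolerance = 1e-12)
    expect_true(r$synthetic$r[i] >= 0 && r$synthetic$r[i] <= 1)
    # parent and neighbor are both minority
    expect_true(all(y[c(r$synthetic$parent[i], r$synthetic$neighbor[i])]
                    == "minority"))
  }
  # original rows untouched and first
  expect_equal(r$x[seq_len(nrow(x)), ], x)
  expect_error(smote(x[1:10, ], y[1:10], sampler_params(k = 5)), "minority")
})

test_that("SMOTE r = 0 gives the parent and r = 1 the neighbor", {
  p <- c(0, 0); q <- c(1, 1)
  expect_equal(p + 0 * (q - p), p)
  s <- p + 0.5 * (q - p)
  expect_equal(s, c(0.5, 0.5))
})

test_that("oversamplers with ratio 1 equalize classes and keep originals", {
  toy <- generate_toy_2d(25, 75, separation = 1.5, seed = 42)
  for (m in c("ros", "smote", "b-smote", "svm-smote")) {
    r <- apply_sampler(m, toy, params = sampler_params(seed = 5))
    expect_equal(sum(r$y == "minority"), sum(r$y == "majority"),
                 info = m)
    expect_equal(r$x[seq_len(nrow(toy$x)), ], toy$x, info = m,
                 ignore_attr = TRUE)
    # appended rows are all minority
    expect_true(all(r$y[-seq_len(nrow(toy$x))] == "minority"), info = m)
  }
  # ADASYN equalizes up to the per-instance ceiling excess
  r <- adasyn(toy, params = sampler_params(seed = 5))
  n_min <- sum(r$y == "minority")
  expect_gte(n_min, 75)
  expect_lte(n_min, 75 + sum(r$adasyn$g > 0))
})

test_that("samplers are reproducible under a fixed seed", {
  toy <- generate_toy_2d(20, 60, separation = 1, seed = 43)
  for (m in sampler_methods()) {
    a <- apply_sampler(m, toy, params = sampler_params(seed = 17))
    b <- apply_sampler(m, toy, params = sampler_params(seed = 17))
    expect_identical(a[c("x", "y", "synthetic", "removed")],
                     b[c("x", "y", "synthetic", "removed")], info = m)
  }
})

test_that("already balanced data pass through ROS and RUS unchanged", {
  toy <- generate_toy_2d(30, 30, separation = 2, seed = 44)
  r1 <- ros(toy, params = sampler_params(seed = 1))
  expect_equal(nrow(r1$x), 60)
  r2 <- rus(toy, params = sampler_params(seed = 1))
  expect_equal(nrow(r2$x), 60)
  expect_length(r2$removed, 0)
})

test_that("ROS copies are verbatim minority rows", {
  toy <- generate_toy_2d(10, 40, separation = 1, seed = 45)
  r <- ros(toy, params = sampler_params(seed = 2))
  added <- r$x[-seq_len(50), , drop = FALSE]
  for (i in seq_len(nrow(added))) {
    expect_equal(unname(added[i, ]),
                 unname(toy$x[r$synthetic$parent[i], ]))
    expect_true(toy$labels[r$synthetic$parent[i]] == "minority")
  }
})

test_that("DANGER membership follows the more-than-half rule", {
  toy <- generate_toy_2d(40, 120, separation = 1, seed = 46)
  params <- sampler_params(m = 10, k = 5, seed = 3)
  r <- borderline_smote(toy, params = params)
  # oracle: recompute the DANGER set by enumeration
  min_idx <- which(toy$labels == "minority")
  oracle <- min_idx[vapply(min_idx, function(i) {
    nb <- brute_knn(toy$x, i, 10)
    sum(toy$labels[nb] == "majority") > 5
  }, logical(1))]
  expect_equal(sort(r$danger), sort(oracle))
  # every synthesis parent is a DANGER member; partners are minority
  expect_true(all(r$synthetic$parent %in% oracle))
  expect_true(all(toy$labels[r$synthetic$neighbor] == "minority"))
  # the noise-excluding flag drops all-majority-neighborhood points
  r2 <- borderline_smote(toy, params = params, exclude_noise = TRUE)
  all_maj <- min_idx[vapply(min_idx, function(i) {
    nb <- brute_knn(toy$x, i, 10)
    sum(toy$labels[nb] == "majority") == 10
  }, logical(1))]
  expect_true(!any(r2$danger %in% all_maj))
  expect_true(all(setdiff(oracle, all_maj) %in% r2$danger))
})

test_that("SVM-SMOTE seeds are qualifying minority support vectors", {
  toy <- generate_toy_2d(30, 90, separation = 2.5, seed = 47)
  params <- sampler_params(seed = 4)
  r <- svm_smote(toy, params = params)
  # retrain the same SVM independently to recover the SV set
  m <- train_svm(toy$x, toy$labels, svm_spec(), positive = "minority")
  sv <- m$fit$index
  expect_true(all(r$parents %in% intersect(sv, which(toy$labels == "minority"))))
  expect_true(all(r$synthetic$parent %in% r$parents))
  # qualification: fewer than half majority among 10 neighbors
  for (i in r$parents) {
    nb <- brute_knn(toy$x, i, 10)
    expect_lt(sum(toy$labels[nb] == "majority"), 5)
  }
  # minority size never exceeds the requested balance
  expect_lte(sum(r$y == "minority"), sum(r$y == "majority"))
})

test_that("ADASYN budget and shares follow G, gamma and the ceiling rule", {
  # printed class sizes: G = beta (150 - 50) = 100
  expect_equal(1 * (150 - 50), 100)
  # one interior minority point, one borderline minority point
  x <- rbind(
    # tight interior minority cluster (6 points)
    matrix(rep(c(0, 0), each = 6), ncol = 2) + 0.01 * matrix(rnorm(12), 6),
    # borderline minority point inside the majority cloud
    c(5, 0),
    # majority cloud around (5, 0)
    cbind(5 + 0.3 * rnorm(20), 0.3 * rnorm(20)))
  y <- factor(c(rep("minority", 7), rep("majority", 20)),
              levels = c("minority", "majority"))
  r <- adasyn(x, y, sampler_params(k = 5, seed = 6))
  expect_equal(r$adasyn$G, 13)
  expect_equal(sum(r$adasyn$gamma), 1)
  expect_equal(r$adasyn$g, as.integer(ceiling(r$adasyn$gamma * 13)))
  # the borderline point (delta = 5) receives more than any interior one
  expect_equal(r$adasyn$delta[7], 5)
  expect_true(all(r$adasyn$delta[1:6] == 0))
  expect_gt(r$adasyn$g[7], max(r$adasyn$g[1:6]))
  # interior points with delta = 0 receive nothing
  expect_equal(sum(r$adasyn$g[1:6]), 0)
  # minority grows by sum(g)
  expect_equal(sum(r$y == "minority"), 7 + sum(r$adasyn$g))
})

test_that("ADASYN falls back to uniform shares when no majority neighbors exist", {
  toy <- generate_toy_2d(10, 30, separation = 100, seed = 48)
  r <- adasyn(toy, params = sampler_params(seed = 7))
  expect_equal(r$adasyn$Z, 0)
  expect_equal(r$adasyn$gamma, rep(0.1, 10))
  expect_equal(sum(r$y == "minority"), 10 + sum(r$adasyn$g))
})

test_that("RUS removes majority rows uniformly down to the minority size", {
  toy <- generate_toy_2d(50, 150, separation = 1, seed = 49)
  r <- rus(toy, params = sampler_params(seed = 8))
  expect_equal(as.vector(table(r$y)), c(50, 50))
  # kept + removed partition the original rows
  kept_maj <- sum(r$y == "majority")
  expect_equal(kept_maj + length(r$removed), 150)
  expect_true(all(toy$labels[r$removed] == "majority"))
  # every kept row is an original row (multiset inclusion)
  expect_true(all(r$x %in% toy$x))
})

test_that("NCR matches exhaustive application of both stages", {
  set.seed(50)
  for (rep in 1:3) {
    toy <- generate_toy_2d(12, 28, separation = sample(c(0.5, 1, 2), 1),
                           seed = 50 + rep)
    r <- ncr(toy, params = sampler_params())
    oracle <- brute_ncr_removed(toy$x, toy$labels, k = 3)
    expect_equal(sort(r$removed), oracle)
    # minority points are never removed
    expect_true(all(toy$labels[r$removed] == "majority"))
    expect_equal(sum(r$y == "minority"), 12)
  }
})

test_that("NCR stage 1 removes majority points outvoted by their 3 neighbors", {
  # hand-built 7-point configuration
  x <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),      # minority cluster
             c(0.05, 0.05),                       # majority point inside it
             c(5, 5), c(5.1, 5), c(5, 5.1))       # far majority triple
  y <- factor(c("minority", "minority", "minority",
                "majority", "majority", "majority", "majority"),
              levels = c("minority", "majority"))
  r <- ncr(x, y, sampler_params())
  # point 4: all 3 neighbors minority -> stage 1 removal
  expect_equal(r$removed_enn, 4L)
  # the far triple survives stage 1 (majority-dominated neighborhoods)
  # but stage 2 removes each: its nearest surviving neighbor is majority
  expect_equal(sort(r$removed_cnn), c(5L, 6L, 7L))
  expect_equal(sort(r$removed), c(4L, 5L, 6L, 7L))
})

test_that("Tomek links are mutual cross-class nearest pairs", {
  # 4-point construction with exactly one cross-class mutual pair:
  # 1-2 are mutual nearest neighbors across classes; 3-4 are mutual
  # nearest neighbors within the majority class (not a link)
  x <- rbind(c(0, 0), c(0.5, 0), c(2, 0), c(2.3, 0))
  y <- factor(c("minority", "majority", "majority", "majority"),
              levels = c("minority", "majority"))
  # oracle confirms the construction
  expect_equal(brute_tomek_pairs(x, y), list(c(1, 2)))
  r <- tomek(x, y, sampler_params())
  expect_equal(r$removed, 2L)
  expect_equal(sum(r$y == "minority"), 1)

  # well-separated clusters form no links
  toy <- generate_toy_2d(15, 45, separation = 30, seed = 51)
  expect_length(brute_tomek_pairs(toy$x, toy$labels), 0)
  r2 <- tomek(toy, params = sampler_params())
  expect_length(r2$removed, 0)
  expect_equal(nrow(r2$x), 60)
})

test_that("Tomek removal matches the brute-force oracle on random data", {
  for (rep in 1:3) {
    toy <- generate_toy_2d(20, 40, separation = 0.8, seed = 60 + rep)
    pairs <- brute_tomek_pairs(toy$x, toy$labels)
    expected <- sort(vapply(pairs, function(p) {
      p[toy$labels[p] == "majority"]
    }, integer(1)))
    r <- tomek(toy, params = sampler_params())
    expect_equal(sort(r$removed), expected)
  }
})

test_that("sampler parameter validation enforces the documented ranges", {
  expect_error(sampler_params(k = 0), "k must")
  expect_error(sampler_params(m = 3, k = 5), "m must")
  expect_error(sampler_params(beta = 1.5), "beta")
  expect_error(sampler_params(sampling_ratio = 0), "sampling_ratio")
  expect_error(ros(matrix(0, 3, 2),
                   factor(rep("majority", 3),
                          levels = c("minority", "majority"))),
               "two classes")
})

test_that("partial sampling ratios stop short of full balance", {
  toy <- generate_toy_2d(20, 80, separation = 1, seed = 52)
  r <- smote(toy, params = sampler_params(sampling_ratio = 0.5, seed = 9))
  expect_equal(sum(r$y == "minority"), 40)
  r2 <- rus(toy, params = sampler_params(sampling_ratio = 0.5, seed = 9))
  expect_equal(sum(r2$y == "majority"), 40)
})
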