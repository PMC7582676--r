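separable_data <- function(gap = 4, n = 20, seed = 71) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n, sd = 0.3), ncol = 2),
               matrix(rnorm(2 * n, sd = 0.3), ncol = 2) + gap)
    y <- factor(rep(c("target", "nontarget"), c(n / 2, n)),
                levels = c("nontarget", "target"))
    list(x = x, y = y)
  })
}

test_that("linearly separable data are fit with zero slack", {
  d <- separable_data()
  m <- train_svm(d$x, d$y, svm_spec(cost = 10))
  xi <- slack_variables(m, d$x, d$y)
  expect_lt(max(xi), 1e-6)
  expect_equal(as.character(predict_classes(m, d$x)),
               as.character(d$y))
})

test_that("balanced class weights scale C inversely to class sizes", {
  y <- factor(rep(c("target", "nontarget"), c(50, 150)),
              levels = c("nontarget", "target"))
  w <- p300balance:::resolve_class_weights(
    svm_spec(class_weights = "balanced"), y)
  # 3x multiplier for the 50-sample target class vs nontarget
  expect_equal(unname(w["target"] / w["nontarget"]), 3)
  expect_equal(unname(w["target"]), 200 / (2 * 50))
  # equal class sizes reduce to plain C
  y2 <- factor(rep(c("target", "nontarget"), each = 50))
  w2 <- p300balance:::resolve_class_weights(
    svm_spec(class_weights = "balanced"), y2)
  expect_equal(unname(w2), c(1, 1))
})

test_that("duplicating every training point leaves the boundary unchanged", {
  d <- separable_data(gap = 2.5, n = 24, seed = 72)
  m1 <- train_svm(d$x, d$y, svm_spec())
  m2 <- train_svm(rbind(d$x, d$x), factor(c(as.character(d$y),
                                            as.character(d$y))),
                  svm_spec())
  probe <- as.matrix(expand.grid(seq(-1, 4, length.out = 7),
                                 seq(-1, 4, length.out = 7)))
  s1 <- target_scores(m1, probe)
  s2 <- target_scores(m2, probe)
  # same sign everywhere and nearly identical decision values
  expect_equal(sign(s1), sign(s2))
  expect_equal(s1, s2, tolerance = 1e-4)
})

test_that("single-class input is rejected", {
  x <- matrix(rnorm(20), 10, 2)
  y <- factor(rep("target", 10))
  expect_error(train_svm(x, y), "both classes")
})

test_that("block selection takes the argmax with ties to the lowest index", {
  d <- separable_data()
  m <- train_svm(d$x, d$y, svm_spec(), calibrate = TRUE, seed = 1)
  # block of 4 rows: row 2 deep in target territory
  block <- rbind(c(4, 4), c(0, 0), c(4.2, 3.8), c(3.9, 4.1))
  sel <- predict_block(m, block)
  expect_equal(sel$chosen, 2)
  # identical rows tie; the lowest stimulus index wins
  tie_block <- rbind(c(2, 2), c(2, 2), c(2, 2), c(2, 2))
  expect_equal(predict_block(m, tie_block)$chosen, 1)
  # probabilities are a strictly monotone transform of decision values,
  # so the selection is invariant to the score type
  expect_equal(predict_block(m, block, type = "probability")$chosen,
               predict_block(m, block, type = "decision")$chosen)
  p <- target_scores(m, block, "probability")
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(order(p), order(target_scores(m, block, "decision")))
})

test_that("WUS weights are the exact rational rank ladder", {
  toy <- generate_toy_2d(20, 60, separation = 1.2, seed = 73)
  w3 <- train_wus(toy, n_subsets = 3, seed = 2)
  expect_setequal(w3$weights, c(1 / 6, 2 / 6, 3 / 6))
  expect_equal(sum(w3$weights), 1)
  # weight order follows training-accuracy rank (ties by subset index)
  expect_equal(order(w3$weights),
               order(rank(w3$train_accuracy, ties.method = "first")))
  w5 <- train_wus(toy, n_subsets = 5, seed = 2)
  expect_setequal(w5$weights, (1:5) / 15)
  expect_equal(sum(w5$weights), 1)
  # subset sizes differ by at most one and partition the majority rows
  sizes <- lengths(w5$subsets)
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(unlist(w5$subsets), which(toy$labels == "majority"))
  expect_error(train_wus(toy, n_subsets = 1), "n_subsets")
})

test_that("the ensemble argmax matches hand enumeration of sum(w_i p_ij)", {
  # hand-set 2-member, 4-stimulus probability table
  p <- rbind(c(0.9, 0.2, 0.5, 0.1),
             c(0.1, 0.8, 0.5, 0.3))
  w <- c(0.25, 0.75)
  scores <- as.numeric(t(p) %*% w)
  # by hand: 0.9*0.25+0.1*0.75 = 0.3; 0.2*0.25+0.8*0.75 = 0.65;
  #          0.5*0.25+0.5*0.75 = 0.5; 0.1*0.25+0.3*0.75 = 0.25
  expect_equal(scores, c(0.3, 0.65, 0.5, 0.25))
  fake <- structure(list(
    members = list(
      structure(list(p = p[1, ]), class = "stub_model"),
      structure(list(p = p[2, ]), class = "stub_model")),
    weights = w), class = "wus_ensemble")
  # emulate ensemble aggregation arithmetic directly
  agg <- p[1, ] * w[1] + p[2, ] * w[2]
  expect_equal(which.max(agg), 2)
})

test_that("unanimous members pick the agreed stimulus regardless of weights", {
  toy <- generate_toy_2d(15, 45, separation = 3, seed = 74)
  ens <- train_wus(toy, n_subsets = 3, seed = 3)
  block <- rbind(c(8, 8), c(0.1, -0.1), c(7, 9), c(9, 7))
  per_member <- vapply(ens$members,
                       function(m) which.max(target_scores(m, block,
                                                           "probability")),
                       integer(1))
  if (length(unique(per_member)) == 1) {
    expect_equal(predict_block_wus(ens, block)$chosen, per_member[1])
  }
  # convexity: the aggregated score is within the members' score range
  agg <- p300balance:::ensemble_scores(ens, block)
  per <- vapply(ens$members,
                function(m) target_scores(m, block, "probability"),
                numeric(nrow(block)))
  expect_true(all(agg <= apply(per, 1, max) + 1e-12))
  expect_true(all(agg >= apply(per, 1, min) - 1e-12))
})

test_that("a single member with weight 1 reduces to the plain model", {
  toy <- generate_toy_2d(20, 20, separation = 2, seed = 75)
  m <- train_svm(toy$x, toy$labels, calibrate = TRUE, seed = 4,
                 positive = "minority")
  ens <- structure(list(members = list(m), weights = 1,
                        n_subsets = 1, positive = "minority"),
                   class = "wus_ensemble")
  block <- toy$x[c(1, 25, 30, 35), ]
  expect_equal(predict_block_wus(ens, block)$chosen,
               predict_block(m, block, type = "probability")$chosen)
  expect_equal(p300balance:::ensemble_scores(ens, block),
               target_scores(m, block, "probability"))
})

test_that("WUS training is reproducible under a fixed seed", {
  toy <- generate_toy_2d(15, 45, separation = 1, seed = 76)
  a <- train_wus(toy, n_subsets = 3, seed = 11)
  b <- train_wus(toy, n_subsets = 3, seed = 11)
  expect_identical(a$subsets, b$subsets)
  expect_identical(a$weights, b$weights)
  expect_identical(a$train_accuracy, b$train_accuracy)
})

test_that("models survive a save/load round trip", {
  d <- separable_data()
  m <- train_svm(d$x, d$y, calibrate = TRUE, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  probe <- matrix(rnorm(20), 10, 2)
  expect_equal(target_scores(m2, probe, "probability"),
               target_scores(m, probe, "probability"))
})
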