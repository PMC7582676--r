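#' Soft-margin SVM specification
#'
#' The classifier solves the usual soft-margin problem
#' `min 1/2 |w|^2 + C sum(xi_i)` subject to
#' `y_i (w . phi(x_i) + b) >= 1 - xi_i`. `C` is fixed to 1 by default (no
#' hyperparameter search). `class_weights = "balanced"` multiplies `C` per
#' class by `l / (2 n_class)` — the inversely-proportional weighting used
#' to counter class imbalance through regularization instead of
#' resampling; with equal class sizes it reduces to plain `C`.
#'
#' @param cost Regularization parameter `C` (> 0), default 1.
#' @param kernel Kernel family, default `"linear"` (standard for
#'   high-dimensional ERP features); any kernel accepted by
#'   [e1071::svm()].
#' @param class_weights `NULL` (equal), `"balanced"`, or a named numeric
#'   vector of per-class multipliers on `cost`.
#' @param calibrate_folds Folds of the internal cross-validation used to
#'   fit the Platt-style probability calibrator (default 3).
#' @return An object of class `svm_spec`.
#' @export
svm_spec <- function(cost = 1, kernel = "linear", class_weights = NULL,
                     calibrate_folds = 3) {
  if (cost <= 0) stop("cost must be > 0")
  if (is.numeric(class_weights) && any(class_weights <= 0)) {
    stop("class weights must be > 0")
  }
  structure(list(cost = cost, kernel = kernel,
                 class_weights = class_weights,
                 calibrate_folds = as.integer(calibrate_folds)),
            class = "svm_spec")
}

resolve_class_weights <- function(spec, y) {
  cw <- spec$class_weights
  if (is.null(cw)) return(NULL)
  if (identical(cw, "balanced")) {
    tab <- table(droplevels(y))
    w <- as.numeric(length(y) / (length(tab) * tab))
    names(w) <- names(tab)
    return(w)
  }
  cw
}

fit_raw_svm <- function(x, y, spec) {
  e1071::svm(x = x, y = y, kernel = spec$kernel, cost = spec$cost,
             class.weights = resolve_class_weights(spec, y),
             scale = FALSE, probability = FALSE)
}

# Oriented decision values: positive means "more target-like" regardless
# of libsvm's internal label order.
raw_decision <- function(fit, newx, positive) {
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/")[[1]][1]
  sgn <- if (first == positive) 1 else -1
  as.numeric(dv[, 1]) * sgn
}

platt_calibrator <- function(x, y, spec, positive, folds, seed = NULL) {
  run <- function() {
    z <- as.integer(y == positive)
    tab <- table(y)
    k <- max(2L, min(folds, min(tab)))
    if (min(tab) < 2) {
      fit <- fit_raw_svm(x, y, spec)
      dv <- raw_decision(fit, x, positive)
    } else {
      fold <- integer(length(y))
      for (lev in levels(droplevels(y))) {
        idx <- sample(which(y == lev))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
      dv <- numeric(length(y))
      for (f in seq_len(k)) {
        tr <- fold != f
        m <- fit_raw_svm(x[tr, , drop = FALSE], droplevels(y[tr]), spec)
        dv[!tr] <- raw_decision(m, x[!tr, , drop = FALSE], positive)
      }
    }
    g <- suppressWarnings(
      stats::glm(z ~ dv, family = stats::binomial()))
    list(a = unname(stats::coef(g)[2]), b = unname(stats::coef(g)[1]))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Train a soft-margin SVM target classifier
#'
#' Fits the SVM of [svm_spec()] and, optionally, a Platt-style sigmoid
#' calibrator mapping decision values to target probability. The
#' calibrator is fit on cross-validated decision values of the training
#' data so probabilities are not resubstitution-optimistic.
#'
#' @param x Feature matrix or `feature_dataset`.
#' @param y Two-class factor (ignored when `x` is a `feature_dataset`).
#' @param spec An [svm_spec()].
#' @param calibrate Fit the probability calibrator (needed for
#'   probability-type scores and for ensemble aggregation).
#' @param seed Optional seed for the calibration folds.
#' @param positive Label of the positive ("target") class; defaults to
#'   `"target"` when present, otherwise the minority class.
#' @return An object of class `p300_svm` with the fitted model, the
#'   support-vector inventory, and the calibrator.
#' @export
train_svm <- function(x, y = NULL, spec = svm_spec(), calibrate = FALSE,
                      seed = NULL, positive = NULL) {
  d <- resolve_xy(x, y)
  y <- droplevels(as.factor(d$y))
  if (nlevels(y) < 2) stop("training data must contain both classes")
  if (is.null(positive)) {
    positive <- if ("target" %in% levels(y)) "target" else
      class_split(y)$minority
  }
  fit <- fit_raw_svm(d$x, y, spec)
  calibrator <- NULL
  if (calibrate) {
    calibrator <- platt_calibrator(d$x, y, spec, positive,
                                   spec$calibrate_folds, seed)
  }
  structure(list(fit = fit, spec = spec, levels = levels(y),
                 positive = positive, calibrator = calibrator,
                 n_features = ncol(d$x)),
            class = "p300_svm")
}

#' @export
print.p300_svm <- function(x, ...) {
  cat(sprintf("<p300_svm> %s kernel, C=%g, %d SVs (%s)%s\n",
              x$spec$kernel, x$spec$cost, nrow(x$fit$SV),
              paste(sprintf("%s=%d", x$fit$levels[x$fit$labels], x$fit$nSV),
                    collapse = ", "),
              if (is.null(x$calibrator)) "" else ", calibrated"))
  invisible(x)
}

#' Target scores for new samples
#'
#' @param model A `p300_svm`.
#' @param newx Feature matrix (or `feature_dataset`).
#' @param type `"decision"` for oriented decision values (positive =
#'   target side), `"probability"` for calibrated target probabilities.
#' @return Numeric vector, one score per row.
#' @export
target_scores <- function(model, newx,
                          type = c("decision", "probability")) {
  type <- match.arg(type)
  if (inherits(newx, "feature_dataset")) newx <- newx$x
  dv <- raw_decision(model$fit, newx, model$positive)
  if (type == "decision") return(dv)
  if (is.null(model$calibrator)) {
    stop("model was trained without calibration; no probabilities")
  }
  stats::plogis(model$calibrator$b + model$calibrator$a * dv)
}

#' Predicted class labels
#'
#' @inheritParams target_scores
#' @return Factor of predicted labels.
#' @export
predict_classes <- function(model, newx) {
  if (inherits(newx, "feature_dataset")) newx <- newx$x
  stats::predict(model$fit, newx)
}

#' Slack variables of the training solution
#'
#' `xi_i = max(0, 1 - y_i f(x_i))`; all zero on linearly separable data.
#'
#' @param model A `p300_svm`.
#' @param x,y The training data the model was fit on.
#' @return Numeric vector of slacks.
#' @export
slack_variables <- function(model, x, y = NULL) {
  d <- resolve_xy(x, y)
  dv <- raw_decision(model$fit, d$x, model$positive)
  ysgn <- ifelse(d$y == model$positive, 1, -1)
  pmax(0, 1 - ysgn * dv)
}

#' Block-level target selection
#'
#' Given one feature row per stimulus of a block, scores each stimulus
#' with the classifier and selects the stimulus with the highest target
#' score (argmax); ties are broken in favor of the lowest stimulus index.
#' For a single model the selection is identical for decision values and
#' calibrated probabilities, since the calibration is strictly monotone.
#'
#' @param model A `p300_svm`.
#' @param block_x Matrix with exactly one row per stimulus, ordered by
#'   stimulus index.
#' @param type Score type, see [target_scores()].
#' @return List with `scores` (per stimulus) and `chosen` (stimulus index).
#' @export
predict_block <- function(model, block_x,
                          type = c("decision", "probability")) {
  type <- match.arg(type)
  scores <- target_scores(model, block_x, type)
  list(scores = scores, chosen = which.max(scores))
}

#' Weighted undersampling bagging (WUS) ensemble
#'
#' Shuffles the nontarget (majority) data, splits it into `n_subsets`
#' disjoint subsets of near-equal size (differing by at most one), pairs
#' each subset with the full target set, and trains one calibrated SVM per
#' pair. Each member's resubstitution training accuracy is computed and
#' members are ranked; the member with rank i (1 = lowest accuracy) gets
#' weight `i / (n (n + 1) / 2)`, i.e. exactly 1/6, 2/6, 3/6 for 3 subsets
#' and 1/15 ... 5/15 for 5, summing to 1. Ties in accuracy are broken by
#' subset index.
#'
#' @param x Feature matrix or `feature_dataset`.
#' @param y Labels (ignored for `feature_dataset`).
#' @param n_subsets Number of majority subsets (>= 2); 3 for 4-stimulus
#'   designs, 5 for 6-stimulus designs.
#' @param spec An [svm_spec()].
#' @param seed Seed controlling the shuffle and member calibrations.
#' @return An object of class `wus_ensemble` with `members`, `weights`
#'   (in subset order), `train_accuracy`, and `subsets` (row indices).
#' @export
train_wus <- function(x, y = NULL, n_subsets = 3, spec = svm_spec(),
                      seed = NULL) {
  if (n_subsets < 2) stop("n_subsets must be >= 2")
  d <- resolve_xy(x, y)
  cs <- class_split(d$y)
  run <- function() {
    maj <- sample(cs$maj_idx)
    assign <- rep_len(seq_len(n_subsets), length(maj))
    member_seeds <- sample.int(.Machine$integer.max, n_subsets)
    subsets <- split(maj, assign)
    members <- vector("list", n_subsets)
    acc <- numeric(n_subsets)
    for (i in seq_len(n_subsets)) {
      rows <- c(cs$min_idx, subsets[[i]])
      xi <- d$x[rows, , drop = FALSE]
      yi <- droplevels(d$y[rows])
      members[[i]] <- train_svm(xi, yi, spec, calibrate = TRUE,
                                seed = member_seeds[i],
                                positive = cs$minority)
      acc[i] <- mean(predict_classes(members[[i]], xi) == yi)
    }
    ranks <- rank(acc, ties.method = "first")
    weights <- ranks / (n_subsets * (n_subsets + 1) / 2)
    structure(list(members = members, weights = weights,
                   train_accuracy = acc, subsets = subsets,
                   n_subsets = n_subsets, positive = cs$minority,
                   spec = spec, seed = seed),
              class = "wus_ensemble")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.wus_ensemble <- function(x, ...) {
  cat(sprintf("<wus_ensemble> %d members; weights: %s; train acc: %s\n",
              x$n_subsets, paste(round(x$weights, 3), collapse = ", "),
              paste(round(x$train_accuracy, 3), collapse = ", ")))
  invisible(x)
}

#' Ensemble target probabilities
#'
#' Weighted sum of the members' calibrated target probabilities,
#' `sum_i w_i p_i(x)`.
#'
#' @param ensemble A `wus_ensemble`.
#' @param newx Feature matrix.
#' @return Numeric vector of aggregated target probabilities.
#' @export
ensemble_scores <- function(ensemble, newx) {
  if (inherits(newx, "feature_dataset")) newx <- newx$x
  p <- vapply(ensemble$members,
              function(m) target_scores(m, newx, "probability"),
              numeric(nrow(newx)))
  p <- matrix(p, nrow = nrow(newx))
  as.numeric(p %*% ensemble$weights)
}

#' Block-level selection with the WUS ensemble
#'
#' Selects `argmax_j sum_i w_i p_ij`: for each stimulus j the members'
#' target probabilities are aggregated with the rank weights and the
#' highest-scoring stimulus is chosen (ties to the lowest index).
#'
#' @param ensemble A `wus_ensemble`.
#' @param block_x One feature row per stimulus, ordered by stimulus index.
#' @return List with `scores` and `chosen`.
#' @export
predict_block_wus <- function(ensemble, block_x) {
  scores <- ensemble_scores(ensemble, block_x)
  list(scores = scores, chosen = which.max(scores))
}

#' Save / load a trained model
#'
#' Serializes a `p300_svm` or `wus_ensemble` (R serialization format).
#'
#' @param model The model object.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
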