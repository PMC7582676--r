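#' Confusion counts and derived rates
#'
#' Tabulates TP/FP/FN/TN against the positive ("target") class and derives
#' recall `TP/(TP+FN)`, precision `TP/(TP+FP)` and the F1 score (harmonic
#' mean of the two). Rates with an undefined (zero) denominator are
#' reported as `NA`, never as 0.
#'
#' @param predicted,actual Equal-length label vectors.
#' @param positive Positive-class label (default `"target"`).
#' @return List of class `confusion_metrics` with counts `tp`, `fp`, `fn`,
#'   `tn`, rates `accuracy`, `recall`, `precision`, `f1`.
#' @export
confusion_metrics <- function(predicted, actual, positive = "target") {
  if (length(predicted) != length(actual)) {
    stop("predicted and actual must have the same length")
  }
  pred_pos <- as.character(predicted) == positive
  act_pos <- as.character(actual) == positive
  tp <- sum(pred_pos & act_pos)
  fp <- sum(pred_pos & !act_pos)
  fn <- sum(!pred_pos & act_pos)
  tn <- sum(!pred_pos & !act_pos)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- rate(tp, tp + fn)
  precision <- rate(tp, tp + fp)
  f1 <- if (is.na(recall) || is.na(precision) || recall + precision == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = rate(tp + tn, tp + fp + fn + tn),
                 recall = recall, precision = precision, f1 = f1),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "TP=%d FP=%d FN=%d TN=%d | acc=%.3f recall=%.3f precision=%.3f F1=%.3f\n",
    x$tp, x$fp, x$fn, x$tn, x$accuracy, x$recall, x$precision, x$f1))
  invisible(x)
}

#' Information transfer rate (bits per minute)
#'
#' `ITR = (log2 N + P log2 P + (1 - P) log2((1 - P)/(N - 1))) / T` with
#' `N` selectable stimuli, `P` the selection accuracy, and `T` the time
#' per selection in minutes. The limits are handled exactly: `P = 1` gives
#' `log2(N)/T`, and the `x log2 x` terms vanish as `P -> 0`; at chance
#' (`P = 1/N`) the rate is 0.
#'
#' @param n_classes Number of selectable stimuli (>= 2).
#' @param p Accuracy fraction in `[0, 1]` (vectorized).
#' @param t_min Time per selection in minutes (> 0). This is an explicit
#'   input: it must reflect the real paradigm timing and is never inferred
#'   from the data.
#' @return ITR in bits/min.
#' @export
itr <- function(n_classes, p, t_min) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (t_min <= 0) stop("t_min must be > 0")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  xlog2 <- function(v) ifelse(v <= 0, 0, v * log2(v))
  bits <- log2(n_classes) + xlog2(p) +
    ifelse(p >= 1, 0, (1 - p) * log2((1 - p) / (n_classes - 1)))
  bits / t_min
}

#' Support-vector introspection of a trained SVM
#'
#' Reports the number of support vectors per class, the target:nontarget
#' support-vector ratio, and the mean relative distance of the support
#' vectors to the decision boundary, `mean(|f(x_sv)|) / |w|` (linear
#' kernel only) — the margin-geometry quantities that reveal how
#' oversampling reshapes the classifier.
#'
#' @param model A `p300_svm` with a linear kernel. For an ensemble,
#'   introspect each member separately.
#' @return List with `sv_count_target`, `sv_count_nontarget`, `sv_ratio`,
#'   `mean_rel_distance`, and `w_norm`.
#' @export
sv_introspection <- function(model) {
  if (inherits(model, "wus_ensemble")) {
    stop("introspection applies to single SVMs; introspect each member")
  }
  stopifnot(inherits(model, "p300_svm"))
  if (model$spec$kernel != "linear") {
    stop("boundary distance is implemented for the linear kernel")
  }
  fit <- model$fit
  w <- crossprod(fit$coefs, fit$SV)
  w_norm <- sqrt(sum(w^2))
  f_sv <- as.numeric(fit$SV %*% t(w)) - fit$rho
  classes <- fit$levels[fit$labels]
  counts <- stats::setNames(fit$nSV, classes)
  pos <- model$positive
  neg <- setdiff(classes, pos)
  n_pos <- if (pos %in% names(counts)) unname(counts[pos]) else 0L
  n_neg <- if (length(neg)) unname(counts[neg[1]]) else 0L
  list(sv_count_target = n_pos, sv_count_nontarget = n_neg,
       sv_ratio = if (n_neg > 0) n_pos / n_neg else NA_real_,
       mean_rel_distance = mean(abs(f_sv)) / w_norm,
       w_norm = w_norm)
}

# Paired two-sided Wilcoxon signed-rank across subjects. All-zero
# differences (a method compared with itself) are reported as p = 1.
paired_signed_rank <- function(a, b) {
  d <- a - b
  if (all(d == 0)) {
    return(list(p_value = 1, mean_diff = 0))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = FALSE))
  list(p_value = wt$p.value, mean_diff = mean(d))
}
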