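#' Methods compared by the analysis runner
#'
#' `"none"` (no balancing), the eight within-dataset samplers, the WUS
#' ensemble, and the class-weighted-C SVM.
#'
#' @return Character vector of method names.
#' @export
comparison_methods <- function() {
  c("none", sampler_methods(), "wus", "weighted-c")
}

#' Fit a classifier for one balancing method
#'
#' Applies the requested balancing to the training data and trains the
#' corresponding classifier: a plain SVM on the (re)sampled data, the WUS
#' ensemble (3 subsets for 4-stimulus designs, 5 for 6), or a single SVM
#' with `class_weights = "balanced"` for `"weighted-c"`.
#'
#' @param method One of [comparison_methods()].
#' @param train A training `feature_dataset`.
#' @param spec An [svm_spec()].
#' @param params A [sampler_params()].
#' @param seed Integer seed for the stochastic methods.
#' @param n_stimuli Stimulus count (chooses the WUS subset count).
#' @param calibrate Fit the Platt probability calibrator on the
#'   (re)balanced training data. Calibrated models classify a sample as
#'   target when its calibrated probability exceeds 0.5, which is how the
#'   balancing methods shift the operating point; block selection by
#'   argmax is unaffected. WUS members are always calibrated.
#' @return A `p300_svm` or `wus_ensemble`.
#' @export
fit_method <- function(method, train, spec = svm_spec(),
                       params = sampler_params(), seed = NULL,
                       n_stimuli = 4, calibrate = TRUE) {
  method <- match.arg(method, comparison_methods())
  if (method == "none") {
    return(train_svm(train, spec = spec, calibrate = calibrate,
                     seed = seed))
  }
  if (method == "wus") {
    n_sub <- if (n_stimuli == 6) 5 else 3
    return(train_wus(train, n_subsets = n_sub, spec = spec, seed = seed))
  }
  if (method == "weighted-c") {
    spec$class_weights <- "balanced"
    return(train_svm(train, spec = spec, calibrate = calibrate,
                     seed = seed))
  }
  params$seed <- seed
  sr <- apply_sampler(method, train, params = params, spec = spec)
  if (nlevels(droplevels(as.factor(sr$y))) < 2) {
    # NCR as stated can strip the whole majority class from cleanly
    # separated data; train on the original data instead
    warning(sprintf("%s removed an entire class; training unbalanced",
                    method))
    return(train_svm(train, spec = spec, calibrate = calibrate,
                     seed = seed))
  }
  train_svm(sr$x, sr$y, spec = spec, calibrate = calibrate, seed = seed)
}

# Binary target/nontarget labels: calibrated models threshold the target
# probability at 0.5 (the probability scale is where resampling shifts
# the operating point); uncalibrated single models fall back to the
# decision-value sign.
binary_predictions <- function(model, x) {
  if (inherits(model, "wus_ensemble")) {
    ifelse(ensemble_scores(model, x) > 0.5, model$positive, "nontarget")
  } else if (!is.null(model$calibrator)) {
    ifelse(target_scores(model, x, "probability") > 0.5,
           model$positive, setdiff(model$levels, model$positive)[1])
  } else {
    as.character(predict_classes(model, x))
  }
}

block_selections <- function(model, dataset) {
  blocks <- unique(dataset$block_id)
  chosen <- integer(length(blocks))
  truth <- integer(length(blocks))
  for (i in seq_along(blocks)) {
    rows <- which(dataset$block_id == blocks[i])
    rows <- rows[order(dataset$stimulus_id[rows])]
    bx <- dataset$x[rows, , drop = FALSE]
    sel <- if (inherits(model, "wus_ensemble")) {
      predict_block_wus(model, bx)
    } else {
      predict_block(model, bx)
    }
    chosen[i] <- dataset$stimulus_id[rows][sel$chosen]
    truth[i] <- dataset$stimulus_id[rows][dataset$y[rows] == "target"]
  }
  data.frame(block_id = blocks, chosen = chosen, truth = truth)
}

#' Evaluate a trained model on a test feature dataset
#'
#' Computes block-level BCI accuracy (fraction of blocks whose argmax
#' selection matches the true target) and per-stimulus binary
#' classification metrics (every averaged ERP sample classified
#' target/nontarget independently).
#'
#' @param model A `p300_svm` or `wus_ensemble`.
#' @param test A `feature_dataset` with block structure.
#' @return List with `block_accuracy`, `blocks` (per-block selections),
#'   and `binary` (a [confusion_metrics()] object).
#' @export
evaluate_model <- function(model, test) {
  sel <- block_selections(model, test)
  bin <- confusion_metrics(binary_predictions(model, test$x),
                           as.character(test$y))
  list(block_accuracy = mean(sel$chosen == sel$truth), blocks = sel,
       binary = bin)
}

#' Compare balancing methods across a synthetic cohort
#'
#' Runs the full factorial of methods x subjects: each subject's session
#' is preprocessed once, every method is fit on the training features and
#' evaluated on the test features. Each method is compared against the
#' unbalanced baseline with a paired two-sided Wilcoxon signed-rank test
#' over subjects (no multiplicity correction). Poor performers are the
#' subjects whose unbalanced block accuracy falls below the cohort mean.
#'
#' @param cohort List of `session_recording`s (see [generate_cohort()]).
#' @param methods Subset of [comparison_methods()]; include `"none"` to
#'   obtain paired tests and the poor-performer split.
#' @param spec An [svm_spec()].
#' @param params A [sampler_params()].
#' @param seed Master seed for the stochastic methods.
#' @param selection_time_min Time per selection in minutes for the ITR
#'   column; `NA` ITRs are reported when omitted.
#' @param calibrate Calibrate single-model probabilities (see
#'   [fit_method()]); disable for block-accuracy-only runs, where the
#'   argmax selection is provably identical and fits are cheaper.
#' @return An object of class `comparison_result`: `results` (one row per
#'   subject x method), `summary` (means per method), `tests` (paired
#'   tests vs `"none"`), `poor_performers` (subject ids and per-method
#'   means over that subset).
#' @export
run_comparison <- function(cohort, methods = comparison_methods(),
                           spec = svm_spec(), params = sampler_params(),
                           seed = 1, selection_time_min = NULL,
                           calibrate = TRUE) {
  if (length(cohort) < 1) stop("cohort is empty")
  methods <- match.arg(methods, comparison_methods(), several.ok = TRUE)
  method_seeds <- withr::with_seed(
    seed, matrix(sample.int(.Machine$integer.max,
                            length(cohort) * length(methods)),
                 nrow = length(cohort)))
  rows <- list()
  for (s in seq_along(cohort)) {
    sess <- cohort[[s]]
    n_stim <- sess$config$n_stimuli
    feats <- subject_features(sess)
    for (m in seq_along(methods)) {
      model <- fit_method(methods[m], feats$train, spec = spec,
                          params = params, seed = method_seeds[s, m],
                          n_stimuli = n_stim, calibrate = calibrate)
      ev <- evaluate_model(model, feats$test)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s, method = methods[m],
        block_accuracy = ev$block_accuracy,
        recall = ev$binary$recall, precision = ev$binary$precision,
        f1 = ev$binary$f1, binary_accuracy = ev$binary$accuracy,
        itr = if (is.null(selection_time_min)) NA_real_ else
          itr(n_stim, ev$block_accuracy, selection_time_min))
    }
  }
  results <- do.call(rbind, rows)
  agg <- function(df) {
    do.call(rbind, lapply(split(df, df$method), function(g) {
      data.frame(method = g$method[1],
                 block_accuracy = mean(g$block_accuracy),
                 recall = mean(g$recall, na.rm = TRUE),
                 precision = mean(g$precision, na.rm = TRUE),
                 f1 = mean(g$f1, na.rm = TRUE),
                 itr = mean(g$itr))
    }))
  }
  summary <- agg(results)
  summary <- summary[match(methods, summary$method), ]
  tests <- NULL
  poor <- NULL
  if ("none" %in% methods && length(cohort) >= 2) {
    base <- results[results$method == "none", ]
    base <- base[order(base$subject), ]
    tests <- do.call(rbind, lapply(setdiff(methods, "none"), function(m) {
      g <- results[results$method == m, ]
      g <- g[order(g$subject), ]
      pt <- paired_signed_rank(g$block_accuracy, base$block_accuracy)
      data.frame(method = m, mean_diff = pt$mean_diff,
                 p_value = pt$p_value)
    }))
    poor_ids <- base$subject[base$block_accuracy <
                               mean(base$block_accuracy)]
    poor <- list(subjects = poor_ids,
                 summary = if (length(poor_ids) > 0) {
                   sub <- results[results$subject %in% poor_ids, ]
                   out <- agg(sub)
                   out[match(methods, out$method), ]
                 })
  }
  structure(list(results = results, summary = summary, tests = tests,
                 poor_performers = poor, methods = methods, seed = seed),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %d subjects x %d methods\n",
              length(unique(x$results$subject)), length(x$methods)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Sweep the minority:majority ratio of an oversampler
#'
#' Re-balances the training data of one or more sessions to each requested
#' target ratio with borderline-SMOTE (or SMOTE), trains the SVM, and
#' records binary classification metrics and block-level BCI accuracy for
#' both training and test sessions. Training metrics are resubstitution
#' metrics on the resampled training set; training BCI accuracy uses the
#' original (un-resampled) training blocks. Pearson correlations between
#' each measure and BCI accuracy are computed over all (session, ratio)
#' runs, separately for training and test.
#'
#' @param sessions A `session_recording` or list of them (repeats to
#'   average over).
#' @param ratios Target minority:majority ratios, each within
#'   `(natural ratio, 1]`; the natural ratio itself is allowed and yields
#'   zero synthesis.
#' @param params A [sampler_params()].
#' @param spec An [svm_spec()].
#' @param seed Master seed.
#' @param method `"b-smote"` (default) or `"smote"`.
#' @return An object of class `ratio_sweep_result`: `runs` (one row per
#'   session x ratio), `summary` (means per ratio), `correlations`.
#' @export
ratio_sweep <- function(sessions, ratios, params = sampler_params(),
                        spec = svm_spec(), seed = 1, method = "b-smote") {
  if (inherits(sessions, "session_recording")) sessions <- list(sessions)
  method <- match.arg(method, c("b-smote", "smote"))
  run_seeds <- withr::with_seed(
    seed, matrix(sample.int(.Machine$integer.max,
                            length(sessions) * length(ratios)),
                 nrow = length(sessions)))
  rows <- list()
  for (s in seq_along(sessions)) {
    feats <- subject_features(sessions[[s]])
    cs <- class_split(feats$train$y)
    natural <- length(cs$min_idx) / length(cs$maj_idx)
    for (r in seq_along(ratios)) {
      ratio <- ratios[r]
      if (ratio < natural - 1e-9) {
        stop(sprintf("ratio %.3f below the natural class ratio %.3f",
                     ratio, natural))
      }
      p <- params
      p$sampling_ratio <- ratio
      p$seed <- run_seeds[s, r]
      sr <- apply_sampler(method, feats$train, params = p, spec = spec)
      model <- train_svm(sr$x, sr$y, spec = spec, calibrate = TRUE,
                         seed = run_seeds[s, r])
      train_bin <- confusion_metrics(
        binary_predictions(model, sr$x), as.character(sr$y))
      train_sel <- block_selections(model, feats$train)
      test_ev <- evaluate_model(model, feats$test)
      rows[[length(rows) + 1]] <- data.frame(
        session = s, ratio = ratio,
        train_accuracy = train_bin$accuracy, train_recall = train_bin$recall,
        train_precision = train_bin$precision, train_f1 = train_bin$f1,
        train_bci_accuracy = mean(train_sel$chosen == train_sel$truth),
        test_accuracy = test_ev$binary$accuracy,
        test_recall = test_ev$binary$recall,
        test_precision = test_ev$binary$precision,
        test_f1 = test_ev$binary$f1,
        test_bci_accuracy = test_ev$block_accuracy)
    }
  }
  runs <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(runs, runs$ratio), function(g) {
    cbind(data.frame(ratio = g$ratio[1]),
          as.data.frame(lapply(g[, -(1:2)], mean, na.rm = TRUE)))
  }))
  summary <- summary[order(summary$ratio), ]
  # correlations are taken across ratio conditions on the repeat-averaged
  # curves, so between-session quality differences do not masquerade as
  # ratio effects
  cor_row <- function(measure, against, phase) {
    a <- summary[[measure]]
    b <- summary[[against]]
    ok <- stats::complete.cases(a, b)
    if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
      return(data.frame(phase = phase, measure = measure,
                        corrcoef = NA_real_, p_value = NA_real_))
    }
    ct <- stats::cor.test(a[ok], b[ok])
    data.frame(phase = phase, measure = measure,
               corrcoef = unname(ct$estimate), p_value = ct$p.value)
  }
  correlations <- rbind(
    cor_row("train_recall", "train_bci_accuracy", "train"),
    cor_row("train_precision", "train_bci_accuracy", "train"),
    cor_row("train_f1", "train_bci_accuracy", "train"),
    cor_row("train_accuracy", "train_bci_accuracy", "train"),
    cor_row("test_recall", "test_bci_accuracy", "test"),
    cor_row("test_precision", "test_bci_accuracy", "test"),
    cor_row("test_f1", "test_bci_accuracy", "test"),
    cor_row("test_accuracy", "test_bci_accuracy", "test"))
  structure(list(runs = runs, summary = summary,
                 correlations = correlations, ratios = ratios,
                 method = method, seed = seed),
            class = "ratio_sweep_result")
}

#' @export
print.ratio_sweep_result <- function(x, ...) {
  cat(sprintf("<ratio_sweep_result> %s over ratios %s\n", x$method,
              paste(round(x$ratios, 3), collapse = ", ")))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run a full cohort analysis from a structured configuration
#'
#' The configuration (a list, or a path to a YAML file) describes the
#' cohort (`n_subjects`, `p300_amplitudes`, any [synthetic_config()]
#' override), the methods, sampler parameters, classifier cost, the
#' selection time for ITR, and the master `seed`. Results, summaries,
#' paired tests and a manifest of every seed and parameter are written to
#' `out_dir` as delimited text and JSON.
#'
#' @param config List or YAML file path.
#' @param out_dir Output directory (created if needed).
#' @return The `comparison_result`, invisibly.
#' @export
run_config <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  n_subjects <- config$n_subjects %||% 5
  cfg_args <- config$session %||% list()
  amplitudes <- config$p300_amplitudes %||%
    rep(cfg_args$p300_amplitude %||% 5, n_subjects)
  amplitudes <- rep_len(amplitudes, n_subjects)
  configs <- lapply(amplitudes, function(a) {
    do.call(synthetic_config,
            utils::modifyList(cfg_args, list(p300_amplitude = a)))
  })
  cohort <- generate_cohort(configs, seed = seed)
  methods <- config$methods %||% comparison_methods()
  params <- do.call(sampler_params, config$sampler %||% list())
  spec <- do.call(svm_spec, config$svm %||% list())
  res <- run_comparison(cohort, methods = methods, spec = spec,
                        params = params, seed = seed,
                        selection_time_min = config$selection_time_min)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res$results, file.path(out_dir, "results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(res$tests)) {
      utils::write.table(res$tests, file.path(out_dir, "tests.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("p300balance")),
      seed = seed, n_subjects = n_subjects, methods = methods,
      p300_amplitudes = amplitudes, sampler = unclass(params),
      svm = unclass(spec), session = cfg_args,
      selection_time_min = config$selection_time_min)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
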