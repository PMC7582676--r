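# Zero-phase IIR filtering with odd-symmetric edge padding (the usual
# forward-backward scheme; padding keeps slow filters from ringing at the
# block edges).
zerophase_filter <- function(filt, x, pad) {
  n <- length(x)
  p <- min(pad, n - 1)
  if (p > 0) {
    head_pad <- 2 * x[1] - x[(p + 1):2]
    tail_pad <- 2 * x[n] - x[(n - 1):(n - p)]
    xp <- c(head_pad, x, tail_pad)
  } else {
    xp <- x
  }
  y <- signal::filtfilt(filt, xp)
  y[(p + 1):(p + n)]
}

#' Band-pass filter and common-average re-reference a session
#'
#' Per channel: zero-phase Butterworth high-pass at `high_cutoff` Hz
#' (order 4), then the across-channel mean is subtracted at every sample
#' (common average reference), then a zero-phase Butterworth low-pass at
#' `low_cutoff` Hz (order 6, chosen so that mains-band components near 60 Hz
#' are suppressed by more than 20 dB after the two passes).
#'
#' @param recording A `session_recording`.
#' @param high_cutoff High-pass cutoff in Hz (default 0.5).
#' @param low_cutoff Low-pass cutoff in Hz (default 50).
#' @return The recording with filtered, re-referenced block signals.
#' @export
bandpass_and_car <- function(recording, high_cutoff = 0.5, low_cutoff = 50) {
  stopifnot(inherits(recording, "session_recording"))
  fs <- recording$config$sampling_rate
  if (recording$config$n_channels < 2) {
    stop("common average reference needs at least 2 channels")
  }
  hp <- signal::butter(4, high_cutoff / (fs / 2), type = "high")
  lp <- signal::butter(6, low_cutoff / (fs / 2), type = "low")
  pad <- round(3 * fs)
  recording$blocks <- lapply(recording$blocks, function(b) {
    sig <- b$signal
    for (ch in seq_len(nrow(sig))) {
      sig[ch, ] <- zerophase_filter(hp, sig[ch, ], pad)
    }
    sig <- sweep(sig, 2, colMeans(sig))
    for (ch in seq_len(nrow(sig))) {
      sig[ch, ] <- zerophase_filter(lp, sig[ch, ], pad)
    }
    b$signal <- sig
    b
  })
  recording$filtered <- TRUE
  recording
}

#' Cut baseline-corrected epochs around every stimulus onset
#'
#' Epochs span `[-200, 600)` ms around onset (400 samples at 500 Hz). For
#' each trial and channel the mean of the pre-stimulus baseline `[-200, 0)`
#' is subtracted.
#'
#' @param recording A (typically filtered) `session_recording`.
#' @param tmin,tmax Epoch limits in ms relative to onset, half-open
#'   `[tmin, tmax)`.
#' @param baseline_end End of the baseline window in ms (baseline is
#'   `[tmin, baseline_end)`).
#' @return An object of class `epoch_set`: `data` is an epochs x
#'   (channels*times) matrix (channel-major feature layout), `info` a
#'   data frame with `block_id`, `stimulus_id`, `is_target`, `phase`, and
#'   `times` the epoch time axis in ms.
#' @export
epoch_and_baseline <- function(recording, tmin = -200, tmax = 600,
                               baseline_end = 0) {
  stopifnot(inherits(recording, "session_recording"))
  fs <- recording$config$sampling_rate
  n_pre <- round(-tmin / 1000 * fs)
  n_post <- round(tmax / 1000 * fs)
  n_time <- n_pre + n_post
  n_base <- round((baseline_end - tmin) / 1000 * fs)
  times <- (seq_len(n_time) - n_pre - 1) / fs * 1000
  n_ch <- recording$config$n_channels
  n_epochs <- sum(vapply(recording$blocks, function(b) nrow(b$events), 0L))
  data <- matrix(NA_real_, n_epochs, n_ch * n_time)
  info <- data.frame(block_id = integer(n_epochs),
                     stimulus_id = integer(n_epochs),
                     is_target = logical(n_epochs),
                     phase = character(n_epochs))
  row <- 0L
  for (b in recording$blocks) {
    ns <- ncol(b$signal)
    for (i in seq_len(nrow(b$events))) {
      on <- b$events$onset_sample[i]
      lo <- on - n_pre
      hi <- on + n_post - 1L
      if (lo < 1 || hi > ns) {
        stop(sprintf("epoch at onset %d exceeds block %d signal bounds",
                     on, b$block_id))
      }
      seg <- b$signal[, lo:hi, drop = FALSE]
      seg <- seg - rowMeans(seg[, seq_len(n_base), drop = FALSE])
      row <- row + 1L
      data[row, ] <- as.vector(t(seg))
      info$block_id[row] <- b$block_id
      info$stimulus_id[row] <- b$events$stimulus_id[i]
      info$is_target[row] <- b$events$is_target[i]
      info$phase[row] <- b$phase
    }
  }
  structure(list(data = data, info = info, times = times,
                 n_channels = n_ch, sampling_rate = fs),
            class = "epoch_set")
}

#' Construct a feature dataset
#'
#' Container for a labelled ERP feature matrix: one row per (block,
#' stimulus) averaged epoch, features are the per-channel amplitudes in the
#' `[100, 600)` ms window, concatenated across channels.
#'
#' @param x Numeric feature matrix.
#' @param y Factor with levels `nontarget`/`target` (or any two labels).
#' @param block_id,stimulus_id Integer metadata per row.
#' @param scaler Optional list with `center` and `scale` per feature.
#' @param n_channels,n_times Feature layout (features = n_channels * n_times).
#' @return An object of class `feature_dataset`.
#' @export
feature_dataset <- function(x, y, block_id = NULL, stimulus_id = NULL,
                            scaler = NULL, n_channels = NA_integer_,
                            n_times = NA_integer_) {
  structure(list(x = x, y = y, block_id = block_id,
                 stimulus_id = stimulus_id, scaler = scaler,
                 n_channels = n_channels, n_times = n_times),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d samples x %d features; classes: %s\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", names(table(x$y)), table(x$y)),
                    collapse = ", ")))
  invisible(x)
}

fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  zero <- scale == 0 | !is.finite(scale)
  if (any(zero)) {
    warning(sprintf("%d zero-variance features; scale set to 1", sum(zero)))
    scale[zero] <- 1
  }
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

#' Average epochs into standardized ERP features
#'
#' For every (block, stimulus) pair the `n_reps` single-trial epochs are
#' averaged into one ERP, the `[100, 600)` ms post-onset window is cropped
#' (250 time points per channel at 500 Hz), and channels are concatenated
#' into one feature row. Features are standardized per column (zero mean,
#' unit variance); the standardizer is fit on the data at hand when
#' `standardizer = NULL` (training) and reused otherwise (test).
#'
#' @param epochs An `epoch_set`.
#' @param standardizer `NULL` to fit on these data, or the `scaler` of a
#'   previously fitted training `feature_dataset`.
#' @param window Feature window in ms, half-open `[window[1], window[2])`.
#' @return A `feature_dataset` with labels `target`/`nontarget`.
#' @export
extract_features <- function(epochs, standardizer = NULL,
                             window = c(100, 600)) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep_t <- epochs$times >= window[1] & epochs$times < window[2]
  n_time_full <- length(epochs$times)
  keep_cols <- rep(keep_t, epochs$n_channels)
  group <- interaction(epochs$info$block_id, epochs$info$stimulus_id,
                       drop = TRUE)
  summed <- rowsum(epochs$data[, keep_cols, drop = FALSE], group,
                   reorder = FALSE)
  counts <- as.vector(table(group)[rownames(summed)])
  avg <- summed / counts
  first <- !duplicated(group)
  block_id <- epochs$info$block_id[first]
  stimulus_id <- epochs$info$stimulus_id[first]
  is_target <- epochs$info$is_target[first]
  ord <- order(block_id, stimulus_id)
  avg <- avg[ord, , drop = FALSE]
  block_id <- block_id[ord]
  stimulus_id <- stimulus_id[ord]
  y <- factor(ifelse(is_target[ord], "target", "nontarget"),
              levels = c("nontarget", "target"))
  if (is.null(standardizer)) standardizer <- fit_scaler(avg)
  xs <- apply_scaler(avg, standardizer)
  feature_dataset(xs, y, block_id = block_id, stimulus_id = stimulus_id,
                  scaler = standardizer, n_channels = epochs$n_channels,
                  n_times = sum(keep_t))
}

#' Preprocess one session into train and test feature datasets
#'
#' Runs the full preprocessing chain (band-pass + common average reference,
#' epoching with baseline correction, per-block/stimulus averaging,
#' standardization fit on the training portion only) and splits by block
#' phase.
#'
#' @param session A `session_recording`.
#' @param ... Passed on to [bandpass_and_car()].
#' @return List with `train` and `test` `feature_dataset`s (test is `NULL`
#'   when the session has no test blocks).
#' @export
subject_features <- function(session, ...) {
  rec <- bandpass_and_car(session, ...)
  ep <- epoch_and_baseline(rec)
  is_tr <- ep$info$phase == "train"
  subset_epochs <- function(keep) {
    structure(list(data = ep$data[keep, , drop = FALSE],
                   info = ep$info[keep, , drop = FALSE],
                   times = ep$times, n_channels = ep$n_channels,
                   sampling_rate = ep$sampling_rate),
              class = "epoch_set")
  }
  train <- extract_features(subset_epochs(is_tr))
  test <- NULL
  if (any(!is_tr)) {
    test <- extract_features(subset_epochs(!is_tr),
                             standardizer = train$scaler)
  }
  list(train = train, test = test)
}

#' Write / read a feature dataset as delimited text
#'
#' Tab-separated: `block_id`, `stimulus_id`, `label`, then one column per
#' feature. The standardizer, when present, goes to a JSON sidecar
#' `<path>.scaler.json`.
#'
#' @param dataset A `feature_dataset`.
#' @param path Output TSV path.
#' @export
write_feature_dataset <- function(dataset, path) {
  df <- data.frame(
    block_id = if (is.null(dataset$block_id)) NA else dataset$block_id,
    stimulus_id = if (is.null(dataset$stimulus_id)) NA else dataset$stimulus_id,
    label = as.character(dataset$y))
  df <- cbind(df, as.data.frame(dataset$x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(dataset$scaler)) {
    jsonlite::write_json(dataset$scaler, paste0(path, ".scaler.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_feature_dataset
#' @export
read_feature_dataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, -(1:3), drop = FALSE])
  lev <- if (all(df$label %in% c("nontarget", "target"))) {
    c("nontarget", "target")
  } else {
    unique(df$label)
  }
  scaler <- NULL
  sidecar <- paste0(path, ".scaler.json")
  if (file.exists(sidecar)) {
    scaler <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  feature_dataset(x, factor(df$label, levels = lev),
                  block_id = df$block_id, stimulus_id = df$stimulus_id,
                  scaler = scaler)
}
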