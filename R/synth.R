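#' Configuration for a synthetic oddball EEG session
#'
#' Describes one simulated subject/session of a visual oddball experiment:
#' `n_stimuli` icons are highlighted one at a time for `stim_duration` ms with
#' an inter-trial interval of `iti` ms; within a block every stimulus is
#' highlighted exactly `n_reps` times and exactly one stimulus is the target.
#' Target highlights evoke a P300-like positive deflection (a Gaussian bump in
#' time, scaled per channel by `channel_topography`) on top of background
#' noise; nontarget highlights carry noise only. Subject quality is controlled
#' by the ratio `p300_amplitude / noise_sd`.
#'
#' @param n_channels Number of EEG channels (default 32).
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @param n_stimuli Number of stimuli in the interface, 4 or 6.
#' @param n_reps Highlights per stimulus per block (default 10).
#' @param n_train_blocks,n_test_blocks Number of training / test blocks.
#' @param stim_duration,iti Highlight duration and inter-trial interval in ms.
#' @param p300_amplitude Peak amplitude of the evoked bump in microvolts;
#'   zero yields statistically identical target and nontarget trials.
#' @param p300_latency Latency of the evoked peak in ms after stimulus onset.
#' @param p300_width Temporal standard deviation of the Gaussian bump in ms.
#' @param noise_sd Standard deviation of the background noise in microvolts
#'   (per channel, all components combined).
#' @param latency_jitter_sd Per-trial jitter (SD, ms) of the evoked latency;
#'   0 disables jitter.
#' @param noise_type Temporal spectrum of the background sources: `"pink"`
#'   (1/f, the default, matching resting EEG) or `"white"`.
#' @param n_noise_sources Number of latent background sources mixed into
#'   the channels (volume conduction makes real EEG channels highly
#'   correlated; a small source count concentrates the noise variance in
#'   few spatial dimensions, which is what gives genuinely overlapping
#'   target/nontarget feature clouds). `0` switches to independent
#'   per-channel noise.
#' @param sensor_noise_frac Fraction of `noise_sd` contributed by
#'   independent per-channel sensor noise on top of the mixed sources.
#' @param channel_topography Optional length-`n_channels` weight vector for
#'   the evoked component; defaults to a fixed midline-weighted profile.
#' @param seed Optional integer seed stored with the config.
#'
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 32, sampling_rate = 500,
                             n_stimuli = 4, n_reps = 10,
                             n_train_blocks = 50, n_test_blocks = 30,
                             stim_duration = 62.5, iti = 62.5,
                             p300_amplitude = 5, p300_latency = 300,
                             p300_width = 50, noise_sd = 10,
                             latency_jitter_sd = 0,
                             noise_type = c("pink", "white"),
                             n_noise_sources = 4, sensor_noise_frac = 0.1,
                             channel_topography = NULL, seed = NULL) {
  noise_type <- match.arg(noise_type)
  if (!n_stimuli %in% c(4L, 6L)) {
    stop("n_stimuli must be 4 or 6 (the supported interface layouts)")
  }
  if (n_channels < 1 || n_reps < 1 || n_train_blocks < 0 || n_test_blocks < 0) {
    stop("counts must be positive")
  }
  if (stim_duration <= 0 || iti <= 0 || sampling_rate <= 0) {
    stop("durations and sampling rate must be positive")
  }
  if (p300_amplitude < 0) stop("p300_amplitude must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (p300_width <= 0 || p300_latency <= 0) {
    stop("p300_latency and p300_width must be positive")
  }
  if (n_noise_sources < 0) stop("n_noise_sources must be >= 0")
  if (sensor_noise_frac < 0 || sensor_noise_frac > 1) {
    stop("sensor_noise_frac must be in [0, 1]")
  }
  if (is.null(channel_topography)) {
    channel_topography <- default_topography(n_channels)
  }
  if (length(channel_topography) != n_channels) {
    stop("channel_topography must have one weight per channel")
  }
  structure(list(
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    n_stimuli = as.integer(n_stimuli), n_reps = as.integer(n_reps),
    n_train_blocks = as.integer(n_train_blocks),
    n_test_blocks = as.integer(n_test_blocks),
    stim_duration = stim_duration, iti = iti,
    p300_amplitude = p300_amplitude, p300_latency = p300_latency,
    p300_width = p300_width, noise_sd = noise_sd,
    latency_jitter_sd = latency_jitter_sd, noise_type = noise_type,
    n_noise_sources = as.integer(n_noise_sources),
    sensor_noise_frac = sensor_noise_frac,
    channel_topography = as.numeric(channel_topography), seed = seed
  ), class = "synthetic_config")
}

#' Default evoked topography
#'
#' A fixed Gaussian profile over channel index, peaked at 70% of the
#' montage (channels are taken to be ordered frontal to parietal, so the
#' peak sits centro-parietally, where the P300 is maximal), normalized to
#' a maximum weight of 1. The profile is deliberately non-uniform across
#' channels: a perfectly uniform topography would be removed by the
#' common average reference.
#'
#' @param n_channels Number of channels.
#' @return Numeric weight vector of length `n_channels`.
#' @export
default_topography <- function(n_channels) {
  if (n_channels == 1) return(1)
  idx <- seq_len(n_channels)
  center <- 0.7 * (n_channels + 1)
  w <- exp(-0.5 * ((idx - center) / (n_channels / 3))^2)
  w / max(w)
}

# Trial onsets with exact average spacing: spacing in samples may be
# fractional (125 ms at 500 Hz = 62.5), so the k-th onset is round(k * sp),
# which alternates 62/63-sample gaps and keeps the mean gap exact.
trial_onsets <- function(n_trials, spacing_samples, pad_pre) {
  pad_pre + round((seq_len(n_trials) - 1) * spacing_samples)
}

evoked_bump <- function(config) {
  fs <- config$sampling_rate
  support_ms <- config$p300_latency + 4 * config$p300_width
  n <- round(support_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000
  config$p300_amplitude *
    exp(-0.5 * ((t_ms - config$p300_latency) / config$p300_width)^2)
}

# One unit-variance noise waveform; pink waveforms get the 1/sqrt(f)
# amplitude spectrum of resting EEG.
noise_waveform <- function(n_samples, type) {
  x <- stats::rnorm(n_samples)
  if (type == "pink") {
    sp <- stats::fft(x)
    f <- c(1, seq_len(n_samples - 1))
    f <- pmin(f, n_samples - f + 1)
    sp <- sp / sqrt(f)
    x <- Re(stats::fft(sp, inverse = TRUE)) / n_samples
  }
  x / stats::sd(x)
}

# Background EEG for one block: a few latent sources mixed into all
# channels (the spatial correlation of volume-conducted EEG) plus an
# independent sensor-noise floor. The per-channel standard deviation is
# `sd` overall. With `n_sources = 0` the noise is independent per channel.
background_noise <- function(n_channels, n_samples, sd, type,
                             mixing = NULL, sensor_frac = 0.1) {
  if (sd == 0) return(matrix(0, n_channels, n_samples))
  if (is.null(mixing)) {
    x <- matrix(0, n_channels, n_samples)
    for (ch in seq_len(n_channels)) {
      x[ch, ] <- noise_waveform(n_samples, type) * sd
    }
    return(x)
  }
  sources <- matrix(0, ncol(mixing), n_samples)
  for (s in seq_len(ncol(mixing))) {
    sources[s, ] <- noise_waveform(n_samples, type)
  }
  mixed <- mixing %*% sources
  sensor <- matrix(stats::rnorm(n_channels * n_samples),
                   n_channels, n_samples)
  sd * (sqrt(1 - sensor_frac^2) * mixed + sensor_frac * sensor)
}

# Fixed per-subject source-to-channel mixing (the stand-in for head
# geometry); rows are unit norm so every channel keeps variance sd^2.
source_mixing <- function(n_channels, n_sources) {
  if (n_sources == 0) return(NULL)
  m <- matrix(stats::rnorm(n_channels * n_sources), n_channels)
  m / sqrt(rowSums(m^2))
}

generate_block <- function(config, block_id, phase, mixing = NULL) {
  fs <- config$sampling_rate
  n_trials <- config$n_stimuli * config$n_reps
  sp <- (config$stim_duration + config$iti) / 1000 * fs
  pad_pre <- round(0.4 * fs)
  pad_post <- round(0.8 * fs)
  onsets <- trial_onsets(n_trials, sp, pad_pre)
  n_samples <- max(onsets) + pad_post
  target_id <- sample.int(config$n_stimuli, 1)
  order <- sample(rep(seq_len(config$n_stimuli), config$n_reps))
  signal <- background_noise(config$n_channels, n_samples,
                             config$noise_sd, config$noise_type,
                             mixing, config$sensor_noise_frac)
  bump <- evoked_bump(config)
  topo <- config$channel_topography
  for (k in which(order == target_id)) {
    shift <- 0L
    if (config$latency_jitter_sd > 0) {
      shift <- round(stats::rnorm(1, sd = config$latency_jitter_sd) / 1000 * fs)
    }
    idx <- onsets[k] + shift + seq_along(bump) - 1L
    keep <- idx >= 1 & idx <= n_samples
    if (any(keep)) {
      signal[, idx[keep]] <- signal[, idx[keep]] +
        outer(topo, bump[keep])
    }
  }
  list(
    block_id = block_id, phase = phase, target_id = target_id,
    signal = signal,
    events = data.frame(stimulus_id = order, onset_sample = onsets,
                        is_target = order == target_id)
  )
}

#' Generate one synthetic oddball EEG session
#'
#' Simulates `n_train_blocks + n_test_blocks` blocks. Each block randomly
#' draws a target stimulus, presents every stimulus exactly `n_reps` times in
#' random order at a fixed 125 ms pace (`stim_duration + iti`), and adds the
#' evoked P300 template to target trials only.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; fixed seeds give bit-identical sessions.
#' @return An object of class `session_recording`: a list with `blocks`
#'   (each holding `signal` channels x samples in microvolts, an event table,
#'   the block's `target_id`, and its `phase` of `"train"` or `"test"`),
#'   the `config`, and the `seed`.
#' @export
generate_session <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  run <- function() {
    n_tr <- config$n_train_blocks
    n_te <- config$n_test_blocks
    mixing <- source_mixing(config$n_channels, config$n_noise_sources)
    blocks <- vector("list", n_tr + n_te)
    for (b in seq_len(n_tr + n_te)) {
      phase <- if (b <= n_tr) "train" else "test"
      blocks[[b]] <- generate_block(config, b, phase, mixing)
    }
    structure(list(blocks = blocks, config = config, seed = seed),
              class = "session_recording")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.session_recording <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<session_recording> %d blocks (%d train, %d test), %d stimuli x %d reps, %d ch @ %g Hz\n",
    length(x$blocks), cfg$n_train_blocks, cfg$n_test_blocks,
    cfg$n_stimuli, cfg$n_reps, cfg$n_channels, cfg$sampling_rate))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' Each subject gets an independent session whose seed is derived
#' deterministically from the master seed (a single `sample.int` draw under
#' the master seed yields one sub-seed per subject), so a cohort is
#' reproducible as a whole and per subject.
#'
#' @param configs A list of [synthetic_config()] objects, one per subject,
#'   typically varying `p300_amplitude` to mix good and poor performers.
#' @param seed Master integer seed.
#' @return A list of `session_recording` objects.
#' @export
generate_cohort <- function(configs, seed) {
  if (length(configs) < 1) stop("need at least one subject config")
  if (inherits(configs, "synthetic_config")) configs <- list(configs)
  sub_seeds <- withr::with_seed(
    seed, sample.int(.Machine$integer.max, length(configs)))
  Map(function(cfg, s) generate_session(cfg, seed = s), configs, sub_seeds)
}

#' Generate a 2-D two-cluster toy dataset with class imbalance
#'
#' Two isotropic Gaussian clusters in the plane: a minority cluster at the
#' origin and a majority cluster offset by `separation` (in units of the
#' cluster spread) along the x axis. Low separation gives the overlapping
#' borderline structure that the DANGER-set samplers act on; very large
#' separation makes the DANGER set empty.
#'
#' @param n_minority,n_majority Cluster sizes (non-negative).
#' @param separation Distance between cluster means in spread units.
#' @param seed Integer seed.
#' @param spread Cluster standard deviation (default 1).
#' @return An object of class `toy_dataset`: list with `x` (n x 2 matrix),
#'   `labels` (factor `minority`/`majority`) and the generating parameters.
#' @export
generate_toy_2d <- function(n_minority, n_majority, separation = 2,
                            seed = NULL, spread = 1) {
  if (n_minority < 0 || n_majority < 0) stop("cluster sizes must be >= 0")
  run <- function() {
    pts <- rbind(
      matrix(stats::rnorm(2 * n_minority, sd = spread), ncol = 2),
      matrix(stats::rnorm(2 * n_majority, sd = spread), ncol = 2)
    )
    if (n_majority > 0) {
      maj <- n_minority + seq_len(n_majority)
      pts[maj, 1] <- pts[maj, 1] + separation * spread
    }
    colnames(pts) <- c("x", "y")
    structure(list(
      x = pts,
      labels = factor(rep(c("minority", "majority"),
                          c(n_minority, n_majority)),
                      levels = c("minority", "majority")),
      n_minority = n_minority, n_majority = n_majority,
      separation = separation, spread = spread, seed = seed
    ), class = "toy_dataset")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write / read a session recording
#'
#' A session is stored as one directory: `session.json` holds the config,
#' seed, and per-block event tables; each block's signal is a raw
#' little-endian double array `block_<id>.bin` (channels x samples,
#' channel-major), so the round trip is exact.
#'
#' @param session A `session_recording`.
#' @param dir Directory to create/fill.
#' @return `write_session` returns `dir` invisibly; `read_session` returns
#'   the reconstructed `session_recording`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "session_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    config = unclass(session$config), seed = session$seed,
    blocks = lapply(session$blocks, function(b) {
      list(block_id = b$block_id, phase = b$phase, target_id = b$target_id,
           n_samples = ncol(b$signal), events = b$events)
    })
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  for (b in session$blocks) {
    con <- file(file.path(dir, sprintf("block_%03d.bin", b$block_id)), "wb")
    writeBin(as.vector(b$signal), con, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  config <- synthetic_config(
    n_channels = cfg$n_channels, sampling_rate = cfg$sampling_rate,
    n_stimuli = cfg$n_stimuli, n_reps = cfg$n_reps,
    n_train_blocks = cfg$n_train_blocks, n_test_blocks = cfg$n_test_blocks,
    stim_duration = cfg$stim_duration, iti = cfg$iti,
    p300_amplitude = cfg$p300_amplitude, p300_latency = cfg$p300_latency,
    p300_width = cfg$p300_width, noise_sd = cfg$noise_sd,
    latency_jitter_sd = cfg$latency_jitter_sd, noise_type = cfg$noise_type,
    n_noise_sources = cfg$n_noise_sources,
    sensor_noise_frac = cfg$sensor_noise_frac,
    channel_topography = cfg$channel_topography, seed = cfg$seed
  )
  blocks <- lapply(seq_len(nrow(meta$blocks)), function(i) {
    bid <- meta$blocks$block_id[i]
    n_samples <- meta$blocks$n_samples[i]
    con <- file(file.path(dir, sprintf("block_%03d.bin", bid)), "rb")
    sig <- readBin(con, "double", n = config$n_channels * n_samples,
                   endian = "little")
    close(con)
    ev <- meta$blocks$events[[i]]
    list(block_id = bid, phase = meta$blocks$phase[i],
         target_id = meta$blocks$target_id[i],
         signal = matrix(sig, config$n_channels, n_samples),
         events = data.frame(stimulus_id = ev$stimulus_id,
                             onset_sample = ev$onset_sample,
                             is_target = ev$is_target))
  })
  structure(list(blocks = blocks, config = config, seed = meta$seed),
            class = "session_recording")
}

#' Write / read a 2-D toy dataset as delimited text
#'
#' Tab-separated columns `x`, `y`, `label`.
#'
#' @param toy A `toy_dataset` (or any list with `x` matrix and `labels`).
#' @param path File path.
#' @export
write_toy_dataset <- function(toy, path) {
  df <- data.frame(x = toy$x[, 1], y = toy$x[, 2], label = toy$labels)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_toy_dataset
#' @export
read_toy_dataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  structure(list(
    x = cbind(x = df$x, y = df$y),
    labels = factor(df$label, levels = c("minority", "majority")),
    n_minority = sum(df$label == "minority"),
    n_majority = sum(df$label == "majority"),
    separation = NA_real_, spread = NA_real_, seed = NULL
  ), class = "toy_dataset")
}
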