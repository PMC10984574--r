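# Synthesis of multichannel oscillatory recordings that realize a planted
# connectivity graph through band-limited, phase-lagged shared sources.

#' Standard 60-channel montage labels
#'
#' Electrode labels for a 60-channel equidistant cap following the extended
#' 10 percent system naming.
#'
#' @return Character vector of length 60.
#' @export
eeg_montage60 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "O1", "O2")
}

# Gaussian noise band-limited to [lo, hi] Hz by Fourier masking, unit SD.
band_limited_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f_abs <- pmin(k, n - k) * fs / n
  keep <- f_abs >= lo & f_abs <= hi
  W[!keep] <- 0
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# 1/f (pink) background noise via Fourier shaping, unit SD.
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  k <- 0:(n - 1)
  f_abs <- pmin(k, n - k) * fs / n
  amp <- ifelse(f_abs > 0, 1 / sqrt(f_abs), 0)
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Synthesize a multichannel recording realizing a planted network
#'
#' Each node carries a band-limited latent oscillation. For every planted
#' edge, one endpoint (the "sender", chosen at random per edge) contributes
#' its latent signal to the other endpoint delayed by `lag_ms`, so that
#' exactly the planted pairs show non-zero imaginary coherency. Indirect
#' leakage (two receivers sharing a sender) arrives at zero relative lag and
#' is therefore invisible to the imaginary part. Independent 1/f background
#' noise is added per channel at the requested signal-to-noise variance
#' ratio. Segments are generated independently and concatenated; an `R0`
#' event marks each segment onset.
#'
#' @param planted A [generate_planted_network()] object; `lag_ms` must be
#'   non-zero (zero-lag coupling is undetectable by design).
#' @param n_segments Number of independent segments (default 60).
#' @param segment_ms Segment length in ms (default 2000).
#' @param fs Sampling rate in Hz (default 500).
#' @param snr Ratio of per-channel signal variance to noise variance. `Inf`
#'   disables the noise.
#' @param seed Integer seed.
#' @param channel_labels Channel names; defaults to [eeg_montage60()] when 60
#'   nodes, otherwise `ch01`, `ch02`, ...
#' @return Object of class `eeg_recording`: `samples` (channels x time
#'   matrix), `fs`, `channel_labels`, `events` (data frame `sample`, `code`;
#'   1-based sample indices) and `provenance` (seed and parameter hash).
#' @export
synthesize_coupled_recording <- function(planted, n_segments = 60L,
                                         segment_ms = 2000, fs = 500,
                                         snr = 1, seed = NULL,
                                         channel_labels = NULL) {
  stopifnot(inherits(planted, "planted_network"))
  band <- planted$band
  if (band[1] <= 0 || band[2] >= fs / 2) {
    stop("planted band must lie within (0, fs/2)", call. = FALSE)
  }
  if (planted$lag_ms == 0) {
    stop("`lag_ms` must be non-zero: zero-lag coupling yields zero ",
         "imaginary coherency and the planted edges would be undetectable",
         call. = FALSE)
  }
  n_segments <- assert_count(n_segments, "n_segments")
  nch <- planted$n_nodes
  nseg_samp <- as.integer(round(segment_ms * fs / 1000))
  delay <- max(1L, as.integer(round(abs(planted$lag_ms) * fs / 1000)))
  edges <- adjacency_to_edges(planted$adjacency)
  if (is.null(channel_labels)) {
    channel_labels <- if (nch == 60L) eeg_montage60() else
      sprintf("ch%02d", seq_len(nch))
  }
  stopifnot(length(channel_labels) == nch)

  with_seed(seed, {
    # random orientation per edge: column gives the sending endpoint
    sender_is_first <- if (nrow(edges)) {
      stats::runif(nrow(edges)) < 0.5
    } else {
      logical(0)
    }
    senders <- ifelse(sender_is_first, edges[, 1L], edges[, 2L])
    receivers <- ifelse(sender_is_first, edges[, 2L], edges[, 1L])
    # A channel carries its own latent only when it sends on some edge;
    # receive-only channels are pure mixtures of delayed sender latents, so
    # an isolated planted pair reaches |Im C| ~ 1 at high SNR.
    sends <- seq_len(nch) %in% senders
    samples <- matrix(0, nch, nseg_samp * n_segments)
    for (s in seq_len(n_segments)) {
      latent <- matrix(0, nch, nseg_samp + delay)
      for (ch in seq_len(nch)) {
        latent[ch, ] <- band_limited_noise(nseg_samp + delay, fs,
                                           band[1], band[2])
      }
      sig <- latent[, (delay + 1L):(delay + nseg_samp), drop = FALSE]
      sig[!sends, ] <- 0
      for (k in seq_along(senders)) {
        sig[receivers[k], ] <- sig[receivers[k], ] +
          latent[senders[k], 1:nseg_samp]
      }
      for (ch in seq_len(nch)) {
        if (is.finite(snr)) {
          sv <- max(stats::var(sig[ch, ]), 1)
          sig[ch, ] <- sig[ch, ] +
            sqrt(sv / snr) * pink_noise(nseg_samp, fs)
        }
      }
      samples[, ((s - 1L) * nseg_samp + 1L):(s * nseg_samp)] <- sig
    }
    structure(
      list(samples = samples,
           fs = fs,
           channel_labels = channel_labels,
           events = data.frame(
             sample = (seq_len(n_segments) - 1L) * nseg_samp + 1L,
             code = "R0"
           ),
           provenance = list(
             seed = seed,
             hash = config_hash(list(planted$topology, planted$n_edges,
                                     n_segments, segment_ms, fs, snr, seed))
           )),
      class = "eeg_recording"
    )
  })
}

#' Synthesize a stimulus-locked task recording
#'
#' Generates a continuous recording for a (scored) ASRT stream with the same
#' coupled-oscillator model as [synthesize_coupled_recording()], placing one
#' stimulus event per trial at the task's fixed pace (stimulus + response
#' window + fixed delay). Event codes follow the trial's triplet label:
#' `S1` = high-probability random, `S2` = low-probability random,
#' `S3` = pattern.
#'
#' @param planted A [generate_planted_network()] object.
#' @param records Trial records (an `asrt_records` data frame, or any stream
#'   with a `design` attribute).
#' @param fs Sampling rate in Hz.
#' @param snr Signal-to-noise variance ratio.
#' @param seed Integer seed.
#' @param pad_ms Padding before the first and after the last stimulus.
#' @return An `eeg_recording` whose `events` carry `sample`, `code` and the
#'   originating `trial` index.
#' @export
synthesize_task_recording <- function(planted, records, fs = 500, snr = 1,
                                      seed = NULL, pad_ms = 600) {
  stopifnot(inherits(planted, "planted_network"))
  design <- attr(records, "design")
  if (is.null(design)) {
    stop("`records` must carry an ASRT design attribute", call. = FALSE)
  }
  labels <- categorize_triplets(records)
  trial_ms <- design$timing$stimulus_ms + design$timing$response_window_ms +
    design$timing$fixed_delay_ms
  n_trials <- nrow(records)
  total_ms <- 2 * pad_ms + n_trials * trial_ms
  base <- synthesize_coupled_recording(
    planted, n_segments = 1L, segment_ms = total_ms, fs = fs, snr = snr,
    seed = seed, channel_labels = NULL
  )
  onset <- as.integer(round((pad_ms + (seq_len(n_trials) - 1L) * trial_ms) *
                              fs / 1000)) + 1L
  code <- ifelse(records$trial_class == "pattern", "S3",
                 ifelse(!is.na(labels$probability) &
                          labels$probability == "high", "S1", "S2"))
  base$events <- data.frame(sample = onset, code = code,
                            trial = records$trial)
  base
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat(sprintf("  events: %d (%s)\n", nrow(x$events),
              paste(utils::head(unique(x$events$code), 5), collapse = ", ")))
  invisible(x)
}
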