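# Cutting continuous recordings into resting segments and stimulus-locked
# task epochs.

new_eeg_epochs <- function(data, fs, channel_labels, condition, t0_ms,
                           segment_info = NULL) {
  stopifnot(length(dim(data)) == 3L)
  if (any(!is.finite(data))) {
    stop("epochs must not contain NaN or infinite samples", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs, channel_labels = channel_labels,
         condition = condition, t0_ms = t0_ms,
         segment_info = segment_info),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eeg_epochs '%s': %d segments x %d channels x %d samples (%g Hz)\n",
              x$condition, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Segment a resting recording into fixed-length epochs
#'
#' Cuts the continuous recording into non-overlapping consecutive segments
#' of `segment_ms`; a trailing remainder shorter than one segment is
#' dropped.
#'
#' @param recording An `eeg_recording`.
#' @param segment_ms Segment length, ms (default 2000).
#' @param condition Condition tag stored with the epochs.
#' @return An `eeg_epochs` object with `data[segment, channel, time]`.
#' @examples
#' net <- generate_planted_network("erdos_renyi", 8, 0.3, seed = 1)
#' rec <- synthesize_coupled_recording(net, n_segments = 3, seed = 1)
#' dim(segment_resting(rec)$data)
#' @export
segment_resting <- function(recording, segment_ms = 2000,
                            condition = "rest") {
  stopifnot(inherits(recording, "eeg_recording"))
  nsamp <- as.integer(round(segment_ms * recording$fs / 1000))
  total <- ncol(recording$samples)
  if (total < nsamp) {
    stop(sprintf("recording (%d samples) is shorter than one %g-ms segment",
                 total, segment_ms), call. = FALSE)
  }
  n_seg <- total %/% nsamp
  nch <- nrow(recording$samples)
  data <- array(0, dim = c(n_seg, nch, nsamp))
  for (s in seq_len(n_seg)) {
    data[s, , ] <- recording$samples[, ((s - 1L) * nsamp + 1L):(s * nsamp)]
  }
  new_eeg_epochs(data, recording$fs, recording$channel_labels, condition,
                 t0_ms = 0,
                 segment_info = data.frame(segment = seq_len(n_seg)))
}

#' Stimulus-locked task epochs split by probability and task half
#'
#' Extracts epochs around stimulus onsets of correct high-probability random
#' and low-probability random trials, split into the first and second half
#' of the task by block number. Epochs whose window would exceed the
#' recording bounds are skipped with a message. A condition bin with zero
#' epochs is kept (flagged) so downstream code can exclude the subject.
#'
#' @param recording An `eeg_recording` whose `events` carry `sample`, `code`
#'   (`S1` high-probability random, `S2` low-probability random, `S3`
#'   pattern) and `trial`.
#' @param records Scored trial records aligned by `trial` index; must
#'   contain `block`, `responded`, `correct`.
#' @param window_ms Epoch window relative to stimulus onset (default
#'   `c(-500, 1000)`).
#' @param half_size_blocks Blocks per task half (default 10).
#' @return Named list of `eeg_epochs` (`high_h1`, `high_h2`, `low_h1`,
#'   `low_h2`); empty bins carry attribute `empty = TRUE`.
#' @export
segment_task <- function(recording, records, window_ms = c(-500, 1000),
                         half_size_blocks = 10L) {
  stopifnot(inherits(recording, "eeg_recording"))
  ev <- recording$events
  if (is.null(ev$trial)) {
    stop("recording events must carry a `trial` index", call. = FALSE)
  }
  idx <- match(ev$trial, records$trial %||% seq_len(nrow(records)))
  ok_resp <- as.logical(records$responded[idx]) &
    records$correct[idx] %in% 1
  half <- ifelse(records$block[idx] <= half_size_blocks, "h1", "h2")
  prob <- ifelse(ev$code == "S1", "high",
                 ifelse(ev$code == "S2", "low", NA_character_))
  fs <- recording$fs
  pre <- as.integer(round(abs(window_ms[1]) * fs / 1000))
  post <- as.integer(round(window_ms[2] * fs / 1000))
  nsamp <- pre + post
  total <- ncol(recording$samples)
  in_bounds <- (ev$sample - pre) >= 1L & (ev$sample + post - 1L) <= total
  n_skipped <- sum(!in_bounds & !is.na(prob) & ok_resp, na.rm = TRUE)
  if (n_skipped > 0) {
    message(sprintf("%d epoch(s) skipped: window exceeds recording bounds",
                    n_skipped))
  }
  nch <- nrow(recording$samples)
  out <- list()
  for (p in c("high", "low")) {
    for (h in c("h1", "h2")) {
      sel <- which(!is.na(prob) & prob == p & half == h & ok_resp & in_bounds)
      data <- array(0, dim = c(length(sel), nch, nsamp))
      for (s in seq_along(sel)) {
        from <- ev$sample[sel[s]] - pre
        data[s, , ] <- recording$samples[, from:(from + nsamp - 1L)]
      }
      ep <- new_eeg_epochs(
        data, fs, recording$channel_labels,
        condition = paste0(p, "prob_", h), t0_ms = window_ms[1],
        segment_info = data.frame(trial = ev$trial[sel])
      )
      if (length(sel) == 0L) {
        attr(ep, "empty") <- TRUE
        warning(sprintf("condition bin %s_%s has no epochs", p, h),
                call. = FALSE)
      }
      out[[paste(p, h, sep = "_")]] <- ep
    }
  }
  out
}
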