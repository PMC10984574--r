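#' Define a cued ASRT task design
#'
#' The Alternating Serial Reaction Time (ASRT) task presents an eight-element
#' alternating sequence in which pattern and random elements take turns
#' (`1-r-2-r-3-r-4-r`): odd elements follow a fixed permutation of the four
#' spatial directions, even elements are drawn uniformly at random. Each block
#' opens with a short run of random practice trials, after which the
#' eight-element sequence is cycled a fixed number of times, so the default
#' block length is `5 + 8 * 10 = 85` trials.
#'
#' @param pattern Integer vector of length 4, a permutation of `1:4`, giving
#'   the fixed order of the pattern elements.
#' @param n_blocks Number of blocks in the session (default 20).
#' @param practice_trials Random practice trials at the start of each block.
#' @param sequence_repeats How many times the eight-element sequence is cycled
#'   per block.
#' @param timing Stimulus timing in milliseconds: stimulus duration, response
#'   window, and the fixed inter-trial delay. Only `response_window_ms` is
#'   consumed by the response simulator; the rest documents the paradigm and
#'   sets event spacing in synthetic task recordings.
#' @return An object of class `asrt_design`.
#' @examples
#' d <- asrt_design()
#' d$trials_per_block  # 85
#' @export
asrt_design <- function(pattern = c(1L, 2L, 3L, 4L),
                        n_blocks = 20L,
                        practice_trials = 5L,
                        sequence_repeats = 10L,
                        timing = list(stimulus_ms = 200,
                                      response_window_ms = 500,
                                      fixed_delay_ms = 700)) {
  pattern <- as.integer(pattern)
  if (length(pattern) != 4L || !setequal(pattern, 1:4)) {
    stop("`pattern` must be a permutation of 1:4", call. = FALSE)
  }
  n_blocks <- assert_count(n_blocks, "n_blocks")
  practice_trials <- assert_count(practice_trials, "practice_trials", min = 0L)
  sequence_repeats <- assert_count(sequence_repeats, "sequence_repeats")
  stopifnot(is.list(timing))
  timing <- utils::modifyList(
    list(stimulus_ms = 200, response_window_ms = 500, fixed_delay_ms = 700),
    timing
  )
  structure(
    list(pattern = pattern,
         n_blocks = n_blocks,
         trials_per_block = practice_trials + 8L * sequence_repeats,
         practice_trials = practice_trials,
         sequence_repeats = sequence_repeats,
         timing = timing),
    class = "asrt_design"
  )
}

#' @export
print.asrt_design <- function(x, ...) {
  cat("ASRT design\n")
  cat("  pattern:         ", paste(x$pattern, collapse = "-"), "\n")
  cat("  blocks:          ", x$n_blocks, "\n")
  cat("  trials per block:", x$trials_per_block,
      sprintf("(%d practice + 8 x %d)", x$practice_trials, x$sequence_repeats),
      "\n")
  cat("  timing (ms):      stimulus", x$timing$stimulus_ms,
      "| response window", x$timing$response_window_ms,
      "| fixed delay", x$timing$fixed_delay_ms, "\n")
  invisible(x)
}

#' Generate an ASRT stimulus stream
#'
#' Builds the trial-by-trial stimulus sequence for a whole session. Every
#' block starts with uniformly random practice trials (tagged `random`), then
#' alternates pattern and random elements; pattern elements cycle through
#' `design$pattern` starting afresh in each block. In the cued task version
#' pattern trials are displayed in black and random trials in red, which is
#' recorded in the `cue` column.
#'
#' @param design An [asrt_design()].
#' @param seed Integer seed; the stream is reproducible under a fixed seed.
#' @return A data frame of class `asrt_stream` with columns `block`,
#'   `position` (1-based within block), `trial` (1-based within session),
#'   `direction` (1-4), `trial_class` (`"pattern"`/`"random"`) and `cue`
#'   (`"black"`/`"red"`). The design is attached as attribute `design`.
#' @examples
#' s <- generate_asrt_sequence(asrt_design(n_blocks = 2), seed = 1)
#' table(s$trial_class)
#' @export
generate_asrt_sequence <- function(design, seed = NULL) {
  stopifnot(inherits(design, "asrt_design"))
  with_seed(seed, {
    tpb <- design$trials_per_block
    n_rand_per_block <- design$practice_trials + 4L * design$sequence_repeats
    pattern_pos <- design$practice_trials +
      seq(1L, 8L * design$sequence_repeats, by = 2L)
    blocks <- rep(seq_len(design$n_blocks), each = tpb)
    position <- rep(seq_len(tpb), times = design$n_blocks)
    direction <- integer(length(blocks))
    is_pattern <- position %in% pattern_pos
    direction[is_pattern] <- rep(
      rep(design$pattern, design$sequence_repeats), design$n_blocks
    )
    direction[!is_pattern] <- sample.int(
      4L, n_rand_per_block * design$n_blocks, replace = TRUE
    )
    out <- data.frame(
      block = blocks,
      position = position,
      trial = seq_along(blocks),
      direction = direction,
      trial_class = factor(ifelse(is_pattern, "pattern", "random"),
                           levels = c("pattern", "random")),
      cue = ifelse(is_pattern, "black", "red")
    )
    attr(out, "design") <- design
    class(out) <- c("asrt_stream", "data.frame")
    out
  })
}

# Successor of each direction in the alternating sequence, as a lookup
# vector: succ[d] is the pattern element that follows pattern element d.
pattern_successor <- function(pattern) {
  succ <- integer(4L)
  succ[pattern] <- pattern[c(2L, 3L, 4L, 1L)]
  succ
}
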