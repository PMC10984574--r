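#' Categorize ASRT trials by triplet probability
#'
#' Labels every trial as the terminal element of the triplet formed with the
#' two preceding trials of the same block (moving window). A triplet
#' `(d1, d2, d3)` is high-probability when `d3` equals the alternating
#' sequence's successor of `d1`; pattern trials complete high-probability
#' triplets by construction of the task. Performance is always scored on the
#' terminal trial of a triplet, so only the terminal label matters downstream;
#' the first two trials of each block carry `NA` probability.
#'
#' @param stream An `asrt_stream` (or a data frame with columns `block`,
#'   `position`, `direction`, `trial_class`) with the sequence pattern either
#'   attached as the `design` attribute or supplied via `pattern`.
#' @param pattern Optional integer permutation of `1:4` overriding the
#'   pattern stored in `stream`.
#' @return A data frame aligned with `stream` rows: `probability`
#'   (`"high"`/`"low"`, `NA` while the window is incomplete), `structure`
#'   (the trial's own class), `trill_or_repetition` (`TRUE` when the first
#'   and terminal elements coincide, covering both trills `a-b-a` and
#'   repetitions `a-a-a`), and `categorizable`.
#' @examples
#' s <- generate_asrt_sequence(asrt_design(n_blocks = 1), seed = 1)
#' labs <- categorize_triplets(s)
#' table(labs$probability, labs$structure)
#' @export
categorize_triplets <- function(stream, pattern = NULL) {
  if (is.null(pattern)) {
    design <- attr(stream, "design")
    if (is.null(design)) {
      stop("no `pattern` supplied and `stream` carries no design attribute",
           call. = FALSE)
    }
    pattern <- design$pattern
  }
  pattern <- as.integer(pattern)
  if (length(pattern) != 4L || !setequal(pattern, 1:4)) {
    stop("`pattern` must be a permutation of 1:4", call. = FALSE)
  }
  d <- stream$direction
  if (any(!d %in% 1:4)) {
    stop("directions must take values in 1:4", call. = FALSE)
  }
  if (min(table(stream$block)) < 3L) {
    stop("each block needs at least 3 trials to form a triplet",
         call. = FALSE)
  }
  succ <- pattern_successor(pattern)
  n <- length(d)
  first <- c(NA_integer_, NA_integer_, d[seq_len(n - 2L)])
  # windows never straddle blocks
  same_block <- c(FALSE, FALSE,
                  stream$block[seq_len(n - 2L)] == stream$block[-(1:2)])
  categorizable <- same_block & stream$position >= 3L
  is_pattern <- stream$trial_class == "pattern"
  prob <- ifelse(categorizable,
                 ifelse(is_pattern | d == succ[ifelse(is.na(first), 1L, first)],
                        "high", "low"),
                 NA_character_)
  prob[!categorizable] <- NA_character_
  data.frame(
    probability = factor(prob, levels = c("high", "low")),
    structure = stream$trial_class,
    triplet_first = ifelse(categorizable, first, NA_integer_),
    trill_or_repetition = categorizable & !is.na(first) & first == d,
    categorizable = categorizable
  )
}

#' Apply trial exclusions before scoring
#'
#' Removes, per block, the first seven trials (the practice trials plus the
#' first two elements of the first complete triplet), terminal trials of
#' trills and repetitions (first and last triplet elements equal), and trials
#' without a response. Reaction-time analyses are additionally restricted to
#' correct responses; that restriction is applied by
#' [compute_learning_scores()], not here.
#'
#' @param records Trial records aligned with `labels`: must contain `block`,
#'   `position` and `responded`; typically the output of
#'   [simulate_responses()] or a behavioural log read with
#'   [read_behavior_csv()].
#' @param labels Triplet labels from [categorize_triplets()]; computed from
#'   `records` when `NULL` (requires the stream columns to be present).
#' @param first_n Number of leading trials per block to drop (default 7).
#' @return The filtered records with `probability` and `structure` columns
#'   bound on, plus an `exclusions` attribute counting dropped trials by
#'   reason (`first_seven`, `trill_or_repetition`, `no_response`).
#' @export
apply_exclusions <- function(records, labels = NULL, first_n = 7L) {
  if (is.null(labels)) {
    labels <- categorize_triplets(records)
  }
  if (nrow(records) != nrow(labels)) {
    stop("`records` and `labels` must be aligned row by row", call. = FALSE)
  }
  if (min(table(records$block)) < 8L) {
    stop("blocks with fewer than 8 trials cannot be scored", call. = FALSE)
  }
  keep_first <- records$position > first_n
  keep_trill <- !labels$trill_or_repetition
  responded <- as.logical(records$responded)
  reason <- rep.int("kept", nrow(records))
  reason[!responded] <- "no_response"
  reason[!keep_trill] <- "trill_or_repetition"
  reason[!keep_first] <- "first_seven"
  keep <- keep_first & keep_trill & responded & !is.na(labels$probability)
  out <- cbind(records,
               probability = labels$probability,
               structure = labels$structure)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- table(factor(
    reason[!keep],
    levels = c("first_seven", "trill_or_repetition", "no_response", "kept")
  ))
  out
}

#' Compute statistical-learning scores in five-block units
#'
#' Splits the session into consecutive units of `unit_size_blocks` blocks and
#' computes, per unit and trial type (high-probability pattern,
#' high-probability random, low-probability random), the mean accuracy over
#' responded trials and the median RT over correct responses. The
#' statistical-learning contrasts use random trials only:
#' `acc_learning = high-probability random accuracy - low-probability random
#' accuracy` (percentage points) and `rt_learning = low-probability random
#' RT - high-probability random RT` (ms). Overall scores are unweighted means
#' of the unit-level contrasts.
#'
#' @param filtered Output of [apply_exclusions()]; needs `block`, `correct`,
#'   `rt_ms`, `probability`, `structure`.
#' @param unit_size_blocks Blocks per analysis unit (default 5).
#' @param n_blocks Total number of blocks in the session; defaults to the
#'   maximum block index present.
#' @return An object of class `learning_scores`: a list with the per-unit
#'   long table `units` (`unit`, `trial_type`, `n_trials`, `mean_acc_pct`,
#'   `median_rt_ms`), per-unit contrasts `acc_learning` and `rt_learning`,
#'   their means `overall_acc_learning` / `overall_rt_learning`, and
#'   `baseline_accuracy` (percent correct over all filtered trials,
#'   irrespective of trial type).
#' @export
compute_learning_scores <- function(filtered, unit_size_blocks = 5L,
                                    n_blocks = NULL) {
  unit_size_blocks <- assert_count(unit_size_blocks, "unit_size_blocks")
  n_blocks <- n_blocks %||% max(filtered$block)
  if (n_blocks %% unit_size_blocks != 0L) {
    stop("`n_blocks` must be divisible by `unit_size_blocks`", call. = FALSE)
  }
  n_units <- n_blocks %/% unit_size_blocks
  unit <- (filtered$block - 1L) %/% unit_size_blocks + 1L
  type <- trial_type(filtered$probability, filtered$structure)
  correct <- as.numeric(filtered$correct)

  cells <- expand.grid(
    trial_type = levels(type), unit = seq_len(n_units),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  key <- interaction(type, unit, drop = FALSE)
  acc <- tapply(correct, key, mean) * 100
  rt <- tapply(filtered$rt_ms[correct == 1],
               droplevels(key[correct == 1]), stats::median)
  nt <- tapply(correct, key, length)
  ckey <- paste(cells$trial_type, cells$unit, sep = ".")
  units <- data.frame(
    unit = cells$unit,
    trial_type = factor(cells$trial_type, levels = levels(type)),
    n_trials = as.integer(ifelse(is.na(nt[ckey]), 0L, nt[ckey])),
    mean_acc_pct = as.numeric(acc[ckey]),
    median_rt_ms = as.numeric(rt[ckey])
  )
  undefined <- units$n_trials == 0L &
    units$trial_type %in% c("high_random", "low_random")
  if (any(undefined)) {
    warning("some units have no eligible trials of a needed type; ",
            "their scores are undefined (NA)", call. = FALSE)
  }
  hi <- units[units$trial_type == "high_random", ]
  lo <- units[units$trial_type == "low_random", ]
  acc_learning <- hi$mean_acc_pct[order(hi$unit)] -
    lo$mean_acc_pct[order(lo$unit)]
  rt_learning <- lo$median_rt_ms[order(lo$unit)] -
    hi$median_rt_ms[order(hi$unit)]
  structure(
    list(units = units,
         acc_learning = acc_learning,
         rt_learning = rt_learning,
         overall_acc_learning = mean(acc_learning),
         overall_rt_learning = mean(rt_learning),
         baseline_accuracy = 100 * mean(correct),
         unit_size_blocks = unit_size_blocks,
         n_units = n_units),
    class = "learning_scores"
  )
}

trial_type <- function(probability, structure) {
  factor(
    ifelse(structure == "pattern", "high_pattern",
           ifelse(probability == "high", "high_random", "low_random")),
    levels = c("high_pattern", "high_random", "low_random")
  )
}

#' @export
print.learning_scores <- function(x, ...) {
  cat("ASRT learning scores (", x$n_units, " units of ",
      x$unit_size_blocks, " blocks)\n", sep = "")
  cat(sprintf("  accuracy learning: %.3f pp (per unit: %s)\n",
              x$overall_acc_learning,
              paste(sprintf("%.2f", x$acc_learning), collapse = ", ")))
  cat(sprintf("  RT learning:       %.1f ms (per unit: %s)\n",
              x$overall_rt_learning,
              paste(sprintf("%.1f", x$rt_learning), collapse = ", ")))
  cat(sprintf("  baseline accuracy: %.1f%%\n", x$baseline_accuracy))
  invisible(x)
}

#' Baseline-accuracy engagement gate
#'
#' Flags a subject for exclusion when accuracy irrespective of trial type is
#' below the threshold (strictly), indicating low task engagement. Accuracy
#' is computed over responded trials; a subject with no responded trials is
#' excluded with a warning.
#'
#' @param records Trial records with `responded` and `correct`.
#' @param threshold_pct Exclusion threshold in percent (default 70).
#' @return `TRUE` when the subject should be kept; the observed accuracy is
#'   attached as attribute `accuracy_pct`.
#' @export
baseline_accuracy_gate <- function(records, threshold_pct = 70) {
  if (nrow(records) == 0L) {
    stop("`records` is empty", call. = FALSE)
  }
  responded <- as.logical(records$responded)
  if (!any(responded)) {
    warning("no responded trials; subject excluded", call. = FALSE)
    return(structure(FALSE, accuracy_pct = NA_real_))
  }
  acc <- 100 * mean(records$correct[responded])
  structure(acc >= threshold_pct, accuracy_pct = acc)
}
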