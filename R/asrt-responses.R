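#' Parameters of a simulated ASRT responder
#'
#' Describes the generative response model of one synthetic participant. The
#' planted statistical-learning effect is an accuracy advantage (in
#' percentage points) and an RT advantage (in ms) on trials that complete
#' high-probability triplets; both ramp up across blocks at `learning_ramp`
#' (fraction of the asymptote gained per block, capped at 1).
#'
#' @param base_accuracy Probability of a correct response on trials without
#'   the planted advantage.
#' @param base_rt_ms Mean RT without the planted advantage.
#' @param acc_learning_pp Asymptotic accuracy advantage on high-probability
#'   trials, percentage points.
#' @param rt_learning_ms Asymptotic RT advantage (speed-up) on
#'   high-probability trials, ms.
#' @param learning_ramp Fraction of the asymptote reached per block; e.g.
#'   0.25 reaches the asymptote at block 4.
#' @param lapse_rate Probability of giving no response on a trial.
#' @param rt_noise_sd_ms SD of Gaussian RT noise.
#' @param group Group label, `"GTS"` or `"HC"`.
#' @param medicated Whether the simulated subject carries a medication flag.
#' @return An object of class `subject_params`.
#' @export
subject_params <- function(base_accuracy = 0.95,
                           base_rt_ms = 350,
                           acc_learning_pp = 2,
                           rt_learning_ms = 8,
                           learning_ramp = 0.25,
                           lapse_rate = 0.02,
                           rt_noise_sd_ms = 80,
                           group = c("GTS", "HC"),
                           medicated = FALSE) {
  group <- match.arg(group)
  structure(
    list(base_accuracy = assert_number(base_accuracy, "base_accuracy", 0, 1),
         base_rt_ms = assert_number(base_rt_ms, "base_rt_ms", lower = 1),
         acc_learning_pp = assert_number(acc_learning_pp, "acc_learning_pp"),
         rt_learning_ms = assert_number(rt_learning_ms, "rt_learning_ms"),
         learning_ramp = assert_number(learning_ramp, "learning_ramp", 0),
         lapse_rate = assert_number(lapse_rate, "lapse_rate", 0, 1),
         rt_noise_sd_ms = assert_number(rt_noise_sd_ms, "rt_noise_sd_ms", 0),
         group = group,
         medicated = assert_flag(medicated, "medicated")),
    class = "subject_params"
  )
}

#' Simulate button-press responses for an ASRT stream
#'
#' Draws, per trial, a response flag (`1 - lapse_rate`), a correctness
#' indicator and an RT. The planted learning advantage applies to trials
#' whose true triplet probability is high, exactly as labelled by
#' [categorize_triplets()] (both pattern and random structures, so the
#' random-only learning contrast stays unbiased); trials without a complete
#' triplet window receive no advantage. RTs exceeding the response window are
#' converted to unresponded trials, mirroring the task's response deadline.
#'
#' @param stream An `asrt_stream`.
#' @param params A [subject_params()].
#' @param seed Integer seed.
#' @return The stream with columns `responded` (0/1), `correct` (0/1, NA when
#'   unresponded) and `rt_ms` (NA when unresponded) added. Expected per-trial
#'   correctness probabilities are attached as attribute `p_correct` so that
#'   recovery tests can compare against the generating model.
#' @export
simulate_responses <- function(stream, params, seed = NULL) {
  stopifnot(inherits(params, "subject_params"))
  if (nrow(stream) == 0L) {
    stop("`stream` is empty", call. = FALSE)
  }
  design <- attr(stream, "design")
  window_ms <- if (!is.null(design)) design$timing$response_window_ms else 500
  labels <- categorize_triplets(stream)
  high <- !is.na(labels$probability) & labels$probability == "high"
  ramp <- pmin(1, params$learning_ramp * stream$block)
  p_correct <- params$base_accuracy +
    ifelse(high, ramp * params$acc_learning_pp / 100, 0)
  if (any(p_correct > 1 | p_correct < 0)) {
    warning("correctness probabilities clipped to [0, 1]", call. = FALSE)
    p_correct <- pmin(1, pmax(0, p_correct))
  }
  mean_rt <- params$base_rt_ms -
    ifelse(high, ramp * params$rt_learning_ms, 0)
  with_seed(seed, {
    n <- nrow(stream)
    responded <- stats::runif(n) >= params$lapse_rate
    correct <- stats::rbinom(n, 1L, p_correct)
    rt <- mean_rt + stats::rnorm(n, 0, params$rt_noise_sd_ms)
    rt <- pmax(rt, 1)
    late <- rt > window_ms
    responded <- responded & !late
    out <- stream
    out$responded <- as.integer(responded)
    out$correct <- ifelse(responded, correct, NA_integer_)
    out$rt_ms <- ifelse(responded, rt, NA_real_)
    attr(out, "design") <- design
    attr(out, "p_correct") <- p_correct
    attr(out, "params") <- params
    class(out) <- c("asrt_records", class(stream))
    out
  })
}
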