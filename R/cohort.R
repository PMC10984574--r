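# Simulated cohorts: per-subject behavioural records, optional resting
# recordings realizing group-specific planted topologies, and the long
# score table feeding the group statistics.

#' Default cohort configuration
#'
#' Describes a two-group cohort of 25 patients (GTS) and 25 matched
#' controls (HC). The planted statistical-learning effects default to a
#' 2.0 vs 0.7 percentage-point asymptotic accuracy advantage; 13 of the
#' patients carry a medication flag, each control is matched to one
#' patient. When EEG generation is enabled, each subject receives pre- and
#' post-task resting recordings realizing a Watts-Strogatz topology in the
#' theta band whose rewiring probability differs by group and time
#' (patients start more lattice-like and randomize after learning,
#' controls stay put).
#'
#' @param n_per_group Subjects per group.
#' @param design An [asrt_design()].
#' @param gts,hc Named lists overriding [subject_params()] defaults per
#'   group.
#' @param n_medicated Number of patients flagged as medicated.
#' @param eeg List: `enabled`, `n_segments`, `segment_ms`, `fs`, `snr`,
#'   `lag_ms`, `band`, `density`, `n_nodes`, `rewire` (named list with
#'   `gts_pre`, `gts_post`, `hc_pre`, `hc_post`).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 25L,
                          design = asrt_design(),
                          gts = list(acc_learning_pp = 2.0,
                                     rt_learning_ms = 8),
                          hc = list(acc_learning_pp = 0.7,
                                    rt_learning_ms = 6),
                          n_medicated = 13L,
                          eeg = list()) {
  eeg <- utils::modifyList(
    list(enabled = FALSE, n_segments = 60L, segment_ms = 2000, fs = 500,
         snr = 1, lag_ms = 20, band = c(4, 7), density = 0.15,
         n_nodes = 60L,
         rewire = list(gts_pre = 0.15, gts_post = 0.30,
                       hc_pre = 0.35, hc_post = 0.35)),
    eeg
  )
  structure(
    list(n_per_group = assert_count(n_per_group, "n_per_group"),
         design = design,
         gts = gts, hc = hc,
         n_medicated = assert_count(n_medicated, "n_medicated", min = 0L),
         eeg = eeg),
    class = c("cohort_config", "list")
  )
}

#' Simulate a full cohort
#'
#' Generates, reproducibly under one seed, behavioural records for every
#' subject (and resting recordings when enabled in the configuration).
#' Sub-seeds for the stimulus sequence, the responses, the planted network
#' and the recording noise are derived deterministically from the one
#' seed, so the whole cohort is reproducible and components can be
#' regenerated independently.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed.
#' @param out_dir Optional directory; when given, behavioural CSVs (one per
#'   subject) and raw-format recordings are written there.
#' @return List of class `cohort`: `info` (subject, group, medicated,
#'   matched_to), `records` (named list of per-subject trial records),
#'   `recordings` (named list of per-subject named recording lists, when
#'   enabled), `config`, `seed`.
#' @export
make_cohort <- function(config = cohort_config(), seed = 1L,
                        out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  n <- config$n_per_group
  ids <- c(sprintf("gts%02d", seq_len(n)), sprintf("hc%02d", seq_len(n)))
  groups <- rep(c("GTS", "HC"), each = n)
  medicated <- c(seq_len(n) <= config$n_medicated, rep(FALSE, n))
  matched_to <- c(rep(NA_character_, n), sprintf("gts%02d", seq_len(n)))
  info <- data.frame(subject = ids, group = groups, medicated = medicated,
                     matched_to = matched_to, stringsAsFactors = FALSE)
  records <- list()
  recordings <- list()
  for (i in seq_along(ids)) {
    grp <- groups[i]
    overrides <- if (grp == "GTS") config$gts else config$hc
    params <- do.call(subject_params,
                      c(overrides,
                        list(group = grp, medicated = medicated[i])))
    stream <- generate_asrt_sequence(config$design,
                                     seed = derive_seed(seed, i, 1L))
    rec <- simulate_responses(stream, params,
                              seed = derive_seed(seed, i, 2L))
    records[[ids[i]]] <- rec
    if (!is.null(out_dir)) {
      write_behavior_csv(rec, file.path(out_dir,
                                        paste0(ids[i], "_behavior.csv")),
                         subject = ids[i], group = grp,
                         medicated = medicated[i])
    }
    if (isTRUE(config$eeg$enabled)) {
      e <- config$eeg
      subj_recs <- list()
      for (cond in c("rest_pre", "rest_post")) {
        rw_key <- paste(tolower(grp),
                        if (cond == "rest_pre") "pre" else "post", sep = "_")
        net <- generate_planted_network(
          "watts_strogatz", n_nodes = e$n_nodes, density = e$density,
          rewire_p = e$rewire[[rw_key]], lag_ms = e$lag_ms, band = e$band,
          seed = derive_seed(seed, i, 3L, match(cond, c("rest_pre",
                                                        "rest_post")))
        )
        subj_recs[[cond]] <- synthesize_coupled_recording(
          net, n_segments = e$n_segments, segment_ms = e$segment_ms,
          fs = e$fs, snr = e$snr,
          seed = derive_seed(seed, i, 4L, match(cond, c("rest_pre",
                                                        "rest_post")))
        )
        if (!is.null(out_dir)) {
          write_recording(subj_recs[[cond]],
                          file.path(out_dir, paste0(ids[i], "_", cond)))
        }
      }
      recordings[[ids[i]]] <- subj_recs
    }
  }
  structure(
    list(info = info, records = records,
         recordings = if (length(recordings)) recordings else NULL,
         config = config, seed = seed),
    class = c("cohort", "list")
  )
}

#' Score a cohort into the long learning table
#'
#' Applies the baseline-accuracy gate, the trial exclusions and the
#' five-block-unit scoring to every subject and assembles the long table
#' that the mixed ANOVA consumes: one row per subject, probability level
#' (high- vs low-probability random) and unit, with mean accuracy and
#' median RT.
#'
#' @param cohort A [make_cohort()] result.
#' @param unit_size_blocks Blocks per unit (default 5).
#' @param baseline_threshold_pct Engagement gate in percent (default 70).
#' @return List: `long` (subject, group, medicated, unit, probability,
#'   mean_acc_pct, median_rt_ms), `subjects` (per-subject overall learning
#'   scores and baseline accuracy), `excluded` (subjects failing the
#'   gate).
#' @export
score_cohort <- function(cohort, unit_size_blocks = 5L,
                         baseline_threshold_pct = 70) {
  long <- list()
  subj_rows <- list()
  excluded <- character()
  for (id in names(cohort$records)) {
    rec <- cohort$records[[id]]
    keep <- baseline_accuracy_gate(rec, baseline_threshold_pct)
    meta <- cohort$info[cohort$info$subject == id, ]
    if (!keep) {
      excluded <- c(excluded, id)
      next
    }
    filtered <- apply_exclusions(rec)
    ls <- compute_learning_scores(filtered, unit_size_blocks)
    u <- ls$units[ls$units$trial_type %in% c("high_random", "low_random"), ]
    long[[id]] <- data.frame(
      subject = id, group = meta$group, medicated = meta$medicated,
      unit = u$unit,
      probability = ifelse(u$trial_type == "high_random", "high", "low"),
      mean_acc_pct = u$mean_acc_pct,
      median_rt_ms = u$median_rt_ms
    )
    subj_rows[[id]] <- data.frame(
      subject = id, group = meta$group, medicated = meta$medicated,
      acc_learning = ls$overall_acc_learning,
      rt_learning = ls$overall_rt_learning,
      baseline_accuracy = ls$baseline_accuracy
    )
  }
  list(long = do.call(rbind, c(long, list(make.row.names = FALSE))),
       subjects = do.call(rbind, c(subj_rows, list(make.row.names = FALSE))),
       excluded = excluded)
}
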