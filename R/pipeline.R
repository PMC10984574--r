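# End-to-end orchestration: simulate -> score -> connectivity -> graphs ->
# group statistics, with CSV outputs stamped by seed and configuration
# hash. The exported functions are the programmatic interface; this
# wrapper chains them for reproducible one-call runs.

#' Run the full simulated-study pipeline
#'
#' Simulates a cohort, scores the behaviour, runs the behavioural mixed
#' ANOVA (Group x Probability x Unit on accuracy), and — when EEG
#' generation is enabled in the cohort configuration — computes per-subject
#' theta-band imaginary-coherence graphs and the Group x Time mixed ANOVA
#' on the small-world coefficient across the two resting states. All
#' tables are returned and optionally written as CSV.
#'
#' @param cohort_cfg A [cohort_config()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for CSV artifacts.
#' @return List: `cohort`, `scores`, `behavior_anova`, and (with EEG)
#'   `network_metrics` (long table) and `network_anova`.
#' @export
run_pipeline <- function(cohort_cfg = cohort_config(),
                         config = pipeline_config(),
                         out_dir = NULL) {
  seed <- config$seed
  cohort <- make_cohort(cohort_cfg, seed = seed)
  scores <- score_cohort(cohort, config$unit_size_blocks)
  behavior_anova <- mixed_anova(scores$long, dv = "mean_acc_pct",
                                subject = "subject", between = "group",
                                within = c("probability", "unit"))
  out <- list(cohort = cohort, scores = scores,
              behavior_anova = behavior_anova,
              seed = seed, config_hash = attr(config, "hash"))
  if (isTRUE(cohort_cfg$eeg$enabled)) {
    rows <- list()
    for (id in names(cohort$recordings)) {
      meta <- cohort$info[cohort$info$subject == id, ]
      for (cond in names(cohort$recordings[[id]])) {
        epochs <- segment_resting(cohort$recordings[[id]][[cond]],
                                  config$segment_ms, condition = cond)
        coh <- coherence_matrices(epochs, band = config$band,
                                  nw = config$nw,
                                  n_tapers = config$n_tapers)
        sm <- subject_condition_metrics(
          coh, percentile = config$percentile,
          null_reps = config$null_reps,
          seed = derive_seed(seed, 999L),
          average_first = config$average_first,
          type = config$percentile_type
        )
        rows[[paste(id, cond)]] <- data.frame(
          subject = id, group = meta$group, medicated = meta$medicated,
          condition = cond, band = config$band,
          mean_degree_2k = sm$mean_degree_2k, L_real = sm$L_real,
          C_real = sm$C_real, L_rand = sm$L_rand, C_latt = sm$C_latt,
          omega = sm$omega, n_segments = sm$n_segments
        )
      }
    }
    out$network_metrics <- do.call(rbind,
                                   c(rows, list(make.row.names = FALSE)))
    out$network_anova <- mixed_anova(out$network_metrics, dv = "omega",
                                     subject = "subject",
                                     between = "group",
                                     within = "condition")
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
    }
    stamp <- function(df) {
      df$seed <- seed
      df$config_hash <- attr(config, "hash")
      df
    }
    utils::write.csv(stamp(scores$long),
                     file.path(out_dir, "learning_long.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(scores$subjects),
                     file.path(out_dir, "learning_subjects.csv"),
                     row.names = FALSE)
    utils::write.csv(stamp(as.data.frame(behavior_anova)),
                     file.path(out_dir, "behavior_anova.csv"),
                     row.names = FALSE)
    if (!is.null(out$network_metrics)) {
      utils::write.csv(stamp(out$network_metrics),
                       file.path(out_dir, "network_metrics.csv"),
                       row.names = FALSE)
      utils::write.csv(stamp(as.data.frame(out$network_anova)),
                       file.path(out_dir, "network_anova.csv"),
                       row.names = FALSE)
    }
  }
  out
}

#' Export a binary network as an edge list or GraphML
#'
#' @param adj An `adjacency_network`.
#' @param path Output file; format chosen by extension (`.graphml` or
#'   anything else for a two-column edge-list text file).
#' @return The path, invisibly.
#' @export
write_network <- function(adj, path) {
  adj <- as_adjacency_network(adj)
  g <- as_igraph(adj)
  igraph::V(g)$name <- adj$node_labels
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(g)
    utils::write.table(el, path, row.names = FALSE, col.names = FALSE,
                       quote = FALSE, sep = "\t")
  }
  invisible(path)
}

#' Plot a thresholded coherence network
#'
#' Draws the strong-coherence graph with nodes coloured by degree, in the
#' style of topographic network summaries (circular layout by default as
#' electrode coordinates are not modelled).
#'
#' @param adj An `adjacency_network`.
#' @param layout An igraph layout function (default
#'   [igraph::layout_in_circle]).
#' @param ... Passed to [igraph::plot.igraph()].
#' @return The igraph object, invisibly.
#' @export
plot_network <- function(adj, layout = igraph::layout_in_circle, ...) {
  adj <- as_adjacency_network(adj)
  g <- as_igraph(adj)
  igraph::V(g)$name <- adj$node_labels
  deg <- igraph::degree(g)
  pal <- grDevices::hcl.colors(max(deg) + 1L, "YlOrRd", rev = TRUE)
  igraph::plot.igraph(
    g, layout = layout, vertex.size = 6,
    vertex.color = pal[deg + 1L], vertex.label.cex = 0.5,
    edge.color = grDevices::adjustcolor("grey40", 0.5), ...
  )
  invisible(g)
}
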