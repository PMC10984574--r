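# Readers and writers: behavioural CSV logs, recordings (raw binary matrix
# with JSON sidecar, and the BrainVision triplet), pipeline configuration.
#
# Sample indices are 1-based in R objects; the BrainVision marker file uses
# the format's own 1-based convention.

#' Write trial records to a behavioural CSV
#'
#' Long-format log with columns `subject`, `group`, `medicated`, `block`,
#' `trial`, `direction`, `trial_class`, `responded`, `correct`, `rt_ms`.
#'
#' @param records An `asrt_records` data frame (see [simulate_responses()]).
#' @param path Output file.
#' @param subject,group,medicated Identifiers stored with every row.
#' @return The path, invisibly.
#' @export
write_behavior_csv <- function(records, path, subject = "s01",
                               group = "GTS", medicated = FALSE) {
  out <- data.frame(
    subject = subject,
    group = group,
    medicated = as.integer(medicated),
    block = records$block,
    trial = records$trial,
    direction = records$direction,
    trial_class = as.character(records$trial_class),
    responded = records$responded,
    correct = records$correct,
    rt_ms = records$rt_ms
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a behavioural CSV
#'
#' @param path File written by [write_behavior_csv()] (or any log with the
#'   same columns).
#' @param pattern The session's 4-element sequence pattern; when supplied,
#'   the returned records carry an ASRT design attribute (with `position`
#'   reconstructed from `trial` and the block length) so they can be scored
#'   directly.
#' @return Data frame of trial records.
#' @export
read_behavior_csv <- function(path, pattern = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$trial_class <- factor(df$trial_class, levels = c("pattern", "random"))
  if (!"position" %in% names(df)) {
    df$position <- stats::ave(df$trial, df$block, df$subject,
                              FUN = seq_along)
  }
  if (!is.null(pattern)) {
    tpb <- max(df$position)
    reps <- (tpb - 5L) %/% 8L
    attr(df, "design") <- asrt_design(
      pattern = pattern, n_blocks = length(unique(df$block)),
      practice_trials = tpb - 8L * reps, sequence_repeats = reps
    )
  }
  df
}

#' Write a recording
#'
#' `format = "raw"` writes `<prefix>.dat` (float64 little-endian,
#' multiplexed: sample 1 of all channels, sample 2, ...) plus a JSON
#' sidecar `<prefix>.json` holding `fs`, channel labels, dimensions and
#' events; this round-trips bit-exactly. `format = "brainvision"` writes
#' the `.vhdr`/`.eeg`/`.vmrk` triplet with IEEE float32 multiplexed data
#' (the format's standard binary layout, hence not bit-exact for float64
#' input).
#'
#' @param recording An `eeg_recording`.
#' @param prefix Output path without extension.
#' @param format `"raw"` or `"brainvision"`.
#' @return The prefix, invisibly.
#' @export
write_recording <- function(recording, prefix,
                            format = c("raw", "brainvision")) {
  format <- match.arg(format)
  if (format == "raw") {
    con <- file(paste0(prefix, ".dat"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(recording$samples), con, size = 8,
             endian = "little")
    meta <- list(
      fs = recording$fs,
      n_channels = nrow(recording$samples),
      n_samples = ncol(recording$samples),
      channel_labels = recording$channel_labels,
      orientation = "channel-major",
      dtype = "float64le",
      events = recording$events
    )
    jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    write_brainvision(recording, prefix)
  }
  invisible(prefix)
}

#' Read a recording
#'
#' Counterpart of [write_recording()]. Header/data consistency is checked;
#' a truncated data file raises an explicit integrity error.
#'
#' @param prefix Path without extension.
#' @param format `"raw"` or `"brainvision"`.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(prefix, format = c("raw", "brainvision")) {
  format <- match.arg(format)
  if (format == "brainvision") {
    return(read_brainvision(prefix))
  }
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  path <- paste0(prefix, ".dat")
  expected <- meta$n_channels * meta$n_samples
  actual <- file.size(path) / 8
  if (actual != expected) {
    stop(sprintf(
      "integrity error: %s holds %g values but the sidecar declares %d",
      path, actual, expected), call. = FALSE)
  }
  if (length(meta$channel_labels) != meta$n_channels) {
    stop("sidecar label count does not match channel count", call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = expected, size = 8, endian = "little")
  samples <- matrix(x, nrow = meta$n_channels)
  events <- as.data.frame(meta$events)
  structure(
    list(samples = samples, fs = meta$fs,
         channel_labels = meta$channel_labels,
         events = events,
         provenance = list(source = path)),
    class = "eeg_recording"
  )
}

# --- BrainVision triplet -------------------------------------------------
# Minimal writer/reader for the BrainVision Core format: INI-style text
# header (.vhdr), IEEE float32 multiplexed binary data (.eeg), text marker
# file (.vmrk). Covers exactly the dialect this package writes.

write_brainvision <- function(recording, prefix) {
  base <- basename(prefix)
  nch <- nrow(recording$samples)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nch),
    paste0("SamplingInterval=", format(1e6 / recording$fs)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nch), recording$channel_labels)
  )
  writeLines(hdr, paste0(prefix, ".vhdr"), useBytes = TRUE)
  con <- file(paste0(prefix, ".eeg"), "wb")
  writeBin(as.numeric(recording$samples), con, size = 4, endian = "little")
  close(con)
  ev <- recording$events
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    if (nrow(ev)) sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(ev)),
                          ev$code, ev$sample)
  )
  writeLines(mrk, paste0(prefix, ".vmrk"))
  invisible(prefix)
}

read_brainvision <- function(prefix) {
  hdr <- readLines(paste0(prefix, ".vhdr"), warn = FALSE)
  get_field <- function(key) {
    line <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(line) != 1L) {
      stop(sprintf("header field '%s' missing or duplicated", key),
           call. = FALSE)
    }
    sub(paste0("^", key, "="), "", line)
  }
  if (get_field("BinaryFormat") != "IEEE_FLOAT_32" ||
      get_field("DataOrientation") != "MULTIPLEXED") {
    stop("only IEEE_FLOAT_32 multiplexed BrainVision data is supported",
         call. = FALSE)
  }
  nch <- as.integer(get_field("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_field("SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, character(1), 1)
  if (length(labels) != nch) {
    stop("channel label count does not match NumberOfChannels",
         call. = FALSE)
  }
  path <- paste0(prefix, ".eeg")
  nvals <- file.size(path) / 4
  if (nvals %% nch != 0) {
    stop(sprintf("integrity error: %s does not hold a whole number of %d-channel samples",
                 path, nch), call. = FALSE)
  }
  con <- file(path, "rb")
  x <- readBin(con, "numeric", n = nvals, size = 4, endian = "little")
  close(con)
  samples <- matrix(x, nrow = nch)
  mrk <- readLines(paste0(prefix, ".vmrk"), warn = FALSE)
  mk_lines <- grep("^Mk[0-9]+=", mrk, value = TRUE)
  events <- if (length(mk_lines)) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", mk_lines), ",")
    data.frame(sample = as.integer(vapply(parts, `[`, character(1), 3)),
               code = vapply(parts, `[`, character(1), 2))
  } else {
    data.frame(sample = integer(), code = character())
  }
  structure(
    list(samples = samples, fs = fs, channel_labels = labels,
         events = events, provenance = list(source = path)),
    class = "eeg_recording"
  )
}

#' Pipeline configuration
#'
#' Assembles the analysis configuration with every default at the value the
#' procedure is defined with: 85th-percentile thresholding, 2000-replicate
#' null ensembles, five-block behavioural units, ten-block task-EEG halves,
#' the four analysis bands, per-segment (not averaged-first) thresholding
#' and the MATLAB-convention percentile. A YAML file and/or an override
#' list can replace any entry; the configuration hash is stamped into
#' pipeline outputs.
#'
#' @param path Optional YAML file.
#' @param overrides Optional named list applied after the file.
#' @return List of class `pipeline_config` with a `hash` attribute.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L,
    percentile = 85,
    percentile_type = 5,
    null_reps = 2000L,
    unit_size_blocks = 5L,
    eeg_block_half_size = 10L,
    bands = eeg_bands(),
    band = "theta",
    average_first = FALSE,
    random_reference = "gnm",
    n_tapers = 3L,
    nw = 2,
    rest_segments = 60L,
    segment_ms = 2000,
    fs = 500
  )
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, file_cfg)
  }
  cfg <- utils::modifyList(cfg, overrides)
  attr(cfg, "hash") <- config_hash(cfg[setdiff(names(cfg), "bands")])
  class(cfg) <- c("pipeline_config", "list")
  cfg
}
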