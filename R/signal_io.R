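# Data model and disk formats: multi-channel EMG recordings (CSV + JSON
# sidecar), clinical score tables, cohort manifests.

#' MDS-UPDRS III upper-limb item labels
#'
#' The nine Part-III items whose sum forms the upper-limb subtotal: rigidity
#' of each upper extremity (3.3b, 3.3c), finger tapping (3.4), hand movements
#' (3.5), pronation-supination (3.6), postural tremor (3.15), kinetic tremor
#' (3.16) and rest tremor amplitude of each upper extremity (3.17a, 3.17b).
#'
#' @export
upper_limb_items <- c("3.3b", "3.3c", "3.4", "3.5", "3.6",
                      "3.15", "3.16", "3.17a", "3.17b")

#' Construct a multi-channel surface EMG recording
#'
#' An `emg_recording` bundles the raw signal matrix with the acquisition
#' metadata needed downstream: sampling rate, channel placement (forearm
#' muscle group and side), subject, clinical group, medication condition and
#' motor task.
#'
#' @param samples numeric matrix, one row per channel, one column per sample,
#'   in millivolts.
#' @param sampling_rate_hz positive sampling rate in Hz (the hardware's
#'   nominal rate; the time axis is derived from it, not the reverse).
#' @param channels data.frame with columns `muscle` (`"flexors"` or
#'   `"extensors"`) and `side` (`"left"` or `"right"`), one row per signal
#'   row. `(muscle, side)` pairs must be unique.
#' @param subject_id subject identifier string.
#' @param group `"pd"` or `"healthy"`.
#' @param condition `"off"`, `"on"`, or `"na"`. Must be `"na"` exactly for
#'   healthy subjects (they are measured once, unmedicated).
#' @param task `"finger_tapping"` or `"hand_movements"`.
#' @param t0_s start time of the first sample in seconds (default 0).
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sampling_rate_hz, channels, subject_id,
                          group = c("pd", "healthy"),
                          condition = c("off", "on", "na"),
                          task = c("finger_tapping", "hand_movements"),
                          t0_s = 0) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  task <- match.arg(task)
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  rec <- structure(list(samples = samples,
                        sampling_rate_hz = sampling_rate_hz,
                        channels = channels,
                        subject_id = as.character(subject_id),
                        group = group, condition = condition, task = task,
                        t0_s = t0_s),
                   class = "emg_recording")
  validate_recording(rec)
  rec
}

#' Validate an EMG recording against its structural invariants
#'
#' Checks: numeric signal matrix, positive sampling rate, one channel
#' descriptor per signal row with unique `(muscle, side)` pairs, and the
#' group/condition consistency rule (condition is `"na"` if and only if the
#' subject is healthy).
#'
#' @param rec an `emg_recording`.
#' @return `rec`, invisibly; errors describe the violated invariant.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "emg_recording")) stop("not an emg_recording")
  if (!is.matrix(rec$samples) || !is.numeric(rec$samples))
    stop("samples must be a numeric matrix (channels x time)")
  if (ncol(rec$samples) < 1L) stop("recording has no samples")
  if (!is.numeric(rec$sampling_rate_hz) || length(rec$sampling_rate_hz) != 1L ||
      rec$sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive scalar")
  ch <- rec$channels
  if (!all(c("muscle", "side") %in% names(ch)))
    stop("channels must have columns muscle and side")
  if (nrow(ch) != nrow(rec$samples))
    stop("channel descriptors do not match signal rows")
  if (!all(ch$muscle %in% c("flexors", "extensors")))
    stop("muscle must be flexors or extensors")
  if (!all(ch$side %in% c("left", "right")))
    stop("side must be left or right")
  if (anyDuplicated(paste(ch$muscle, ch$side)))
    stop("duplicate (muscle, side) channel labels")
  if ((rec$group == "healthy") != (rec$condition == "na"))
    stop("condition must be 'na' exactly when group is 'healthy'")
  invisible(rec)
}

#' Channel labels of a recording
#'
#' @param rec an `emg_recording` (or its `channels` data.frame).
#' @return character vector `"<muscle>_<side>"`, one per channel.
#' @export
channel_labels <- function(rec) {
  ch <- if (inherits(rec, "emg_recording")) rec$channels else rec
  paste(ch$muscle, ch$side, sep = "_")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> subject %s (%s, %s, %s)\n",
              x$subject_id, x$group, x$condition, x$task))
  cat(sprintf("  %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
              ncol(x$samples) / x$sampling_rate_hz))
  cat("  channels:", paste(channel_labels(x), collapse = ", "), "\n")
  invisible(x)
}

#' Write a recording as CSV plus a JSON metadata sidecar
#'
#' The CSV has a `time_s` column followed by one column per channel (named
#' `<muscle>_<side>`), amplitudes in millivolts. The sidecar JSON carries
#' `subject_id`, `group`, `condition`, `task`, `sampling_rate_hz`, `t0_s` and
#' the ordered channel table.
#'
#' @param rec a valid `emg_recording`.
#' @param path CSV output path.
#' @param meta_path JSON sidecar output path.
#' @return invisibly, the two paths.
#' @export
save_recording <- function(rec, path, meta_path) {
  validate_recording(rec)
  n <- ncol(rec$samples)
  df <- data.frame(time_s = rec$t0_s + (seq_len(n) - 1) / rec$sampling_rate_hz)
  sig <- as.data.frame(t(rec$samples))
  names(sig) <- channel_labels(rec)
  df <- cbind(df, sig)
  write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, group = rec$group,
               condition = rec$condition, task = rec$task,
               sampling_rate_hz = rec$sampling_rate_hz, t0_s = rec$t0_s,
               channels = rec$channels)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, meta_path))
}

#' Load a recording from CSV plus its JSON metadata sidecar
#'
#' The sampling rate is taken from the metadata (the hardware's declared
#' rate); the CSV time column is checked for strict monotonicity only. The
#' CSV channel columns must match the sidecar's channel table exactly (same
#' set, same order).
#'
#' @param path CSV path (`time_s` column + one column per channel).
#' @param meta_path JSON sidecar path.
#' @return an `emg_recording`.
#' @export
load_recording <- function(path, meta_path) {
  meta <- jsonlite::fromJSON(meta_path)
  df <- read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("recording CSV is empty: ", path)
  if (!"time_s" %in% names(df)) stop("recording CSV lacks a time_s column")
  tm <- df$time_s
  if (any(diff(tm) <= 0)) stop("time column is not strictly increasing")
  chans <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
  want <- paste(chans$muscle, chans$side, sep = "_")
  have <- setdiff(names(df), "time_s")
  if (!identical(sort(want), sort(have)))
    stop("CSV channels [", paste(have, collapse = ", "),
         "] do not match metadata channels [", paste(want, collapse = ", "), "]")
  samples <- t(as.matrix(df[, want, drop = FALSE]))
  rownames(samples) <- NULL
  emg_recording(samples = samples,
                sampling_rate_hz = meta$sampling_rate_hz,
                channels = chans, subject_id = meta$subject_id,
                group = meta$group, condition = meta$condition,
                task = meta$task,
                t0_s = if (is.null(meta$t0_s)) 0 else meta$t0_s)
}

#' Load and validate a clinical score table
#'
#' Expects one row per (subject, condition) with the nine upper-limb item
#' columns named `item_<id>` (e.g. `item_3.3b`), each scored 0-4, plus
#' `total_part3`. The upper-limb subtotal is recomputed from the items when
#' absent, and checked against them when present.
#'
#' @param path CSV path, or a data.frame already in memory.
#' @return validated data.frame with columns `subject_id`, `condition`, the
#'   nine `item_*` columns, `upper_limb_subtotal` and `total_part3`.
#' @export
load_scores <- function(path) {
  df <- if (is.data.frame(path)) path else read.csv(path, check.names = FALSE)
  item_cols <- paste0("item_", upper_limb_items)
  need <- c("subject_id", "condition", item_cols)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!all(df$condition %in% c("off", "on")))
    stop("condition must be 'off' or 'on'")
  items <- as.matrix(df[, item_cols])
  if (any(items != round(items)) || any(items < 0) || any(items > 4))
    stop("item scores must be integers in [0, 4]")
  subtotal <- as.integer(rowSums(items))
  if ("upper_limb_subtotal" %in% names(df)) {
    if (any(df$upper_limb_subtotal != subtotal))
      stop("upper_limb_subtotal does not equal the sum of the nine items")
  }
  df$upper_limb_subtotal <- subtotal
  if (!"total_part3" %in% names(df)) df$total_part3 <- subtotal
  if (any(df$total_part3 < df$upper_limb_subtotal))
    stop("total_part3 must be >= upper_limb_subtotal")
  if (anyDuplicated(paste(df$subject_id, df$condition)))
    stop("duplicate (subject, condition) score rows")
  df[, c("subject_id", "condition", item_cols,
         "upper_limb_subtotal", "total_part3")]
}

#' Write a cohort to disk (recordings, scores, manifest, ground truth)
#'
#' Materialises an in-memory cohort (see [generate_cohort()]) as the on-disk
#' layout the loaders understand: per-recording CSV + JSON pairs, a
#' `scores.csv`, a `manifest.csv` linking every (subject, condition, task) to
#' its files, and `sim_truth.json` when simulation ground truth is present.
#'
#' @param cohort an `emg_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  man$recording_csv <- paste0(man$recording_id, ".csv")
  man$recording_json <- paste0(man$recording_id, ".json")
  for (i in seq_len(nrow(man))) {
    rec <- cohort$recordings[[man$recording_id[i]]]
    save_recording(rec, file.path(dir, man$recording_csv[i]),
                   file.path(dir, man$recording_json[i]))
  }
  if (!is.null(cohort$scores))
    write.csv(cohort$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "sim_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(file.path(dir, "manifest.csv"))
}

#' Load a cohort from a manifest directory
#'
#' Reads `manifest.csv`, every referenced recording (paths resolved relative
#' to the manifest), and `scores.csv` if present. Fails if any referenced
#' file is missing or if a (subject, condition, task) combination occurs
#' twice.
#'
#' @param dir directory containing `manifest.csv`, or the manifest path.
#' @return an `emg_cohort` list with `recordings`, `manifest`, `scores`.
#' @export
load_cohort <- function(dir) {
  man_path <- if (dir.exists(dir)) file.path(dir, "manifest.csv") else dir
  base <- dirname(man_path)
  man <- read.csv(man_path, check.names = FALSE)
  key <- paste(man$subject_id, man$condition, man$task)
  if (anyDuplicated(key))
    stop("manifest lists duplicate (subject, condition, task) entries")
  paths <- file.path(base, man$recording_csv)
  metas <- file.path(base, man$recording_json)
  missing <- !file.exists(paths) | !file.exists(metas)
  if (any(missing))
    stop("manifest references missing files: ",
         paste(man$recording_id[missing], collapse = ", "))
  recs <- lapply(seq_len(nrow(man)),
                 function(i) load_recording(paths[i], metas[i]))
  names(recs) <- man$recording_id
  scores_path <- file.path(base, "scores.csv")
  scores <- if (file.exists(scores_path)) load_scores(scores_path) else NULL
  structure(list(recordings = recs, manifest = man, scores = scores,
                 truth = NULL, config = NULL),
            class = "emg_cohort")
}
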