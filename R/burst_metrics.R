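# Prominence-based detection of muscle-activation bursts on the linear
# envelope, and the three burst metrics: peak count, median peak amplitude,
# mean inter-peak interval.

#' Local maxima of a signal, with plateau handling
#'
#' A peak is a sample strictly above its left neighbour and not below its
#' right neighbour; a run of equal samples bounded by a strictly lower sample
#' on each side counts once, at the plateau midpoint (the left-of-centre
#' index when the plateau width is even). Signal endpoints are never peaks.
#'
#' @param x numeric vector, length >= 3.
#' @return integer vector of peak indices (1-based), strictly increasing.
#' @export
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) stop("signal must have length >= 3")
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # plateau [i, j]
      if (j < n && x[j + 1L] < x[i])
        peaks <- c(peaks, as.integer(floor((i + j) / 2)))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  peaks
}

#' Topographic prominence of a peak
#'
#' The prominence of a peak is its height minus the higher of its two base
#' minima, where each base is the minimum of the signal between the peak and
#' the nearest strictly higher sample on that side (or the signal edge when
#' no higher sample exists). It measures how far the envelope must descend
#' before rising to a higher point, i.e. how much the activation burst
#' stands out from its surroundings.
#'
#' @param x numeric vector.
#' @param peak_index index of a local maximum of `x` (see [local_maxima()]).
#' @return prominence (positive scalar).
#' @export
peak_prominence <- function(x, peak_index) {
  n <- length(x)
  i <- peak_index
  if (i < 2L || i > n - 1L || x[i] < x[i - 1L] || x[i] < x[i + 1L] ||
      (x[i] == x[i - 1L] && x[i] == x[i + 1L] && all(x == x[i])))
    stop("peak_index is not a local maximum")
  if (x[i] == x[i - 1L]) {
    # plateau member: accept only if part of a genuine plateau peak
    if (!(i %in% local_maxima(x))) stop("peak_index is not a local maximum")
  }
  h <- x[i]
  higher_left <- which(x[seq_len(i - 1L)] > h)
  lo <- if (length(higher_left)) max(higher_left) + 1L else 1L
  base_left <- min(x[seq(lo, i - 1L)])
  higher_right <- which(x[seq(i + 1L, n)] > h) + i
  hi <- if (length(higher_right)) min(higher_right) - 1L else n
  base_right <- min(x[seq(i + 1L, hi)])
  h - max(base_left, base_right)
}

#' Select activation peaks by relative prominence threshold
#'
#' Finds all local maxima of the envelope and keeps those whose prominence
#' reaches `rel_threshold` times the envelope's dynamic range (max - min).
#' The per-signal normalisation makes the selection unit-free: adding a
#' constant changes nothing, and rescaling the envelope rescales threshold
#' and prominences together, preserving the selected set.
#'
#' @param envelope numeric vector (linear envelope), length >= 3.
#' @param rel_threshold fraction of the envelope dynamic range used as the
#'   prominence threshold (default 0.1).
#' @return object of class `peak_set`: list with `indices`, `magnitudes`,
#'   `prominences`, `threshold_mv`, `rel_threshold`.
#' @export
select_peaks <- function(envelope, rel_threshold = 0.1) {
  rng <- max(envelope) - min(envelope)
  if (rng == 0) {
    warning("flat envelope: no peaks selected")
    return(structure(list(indices = integer(0), magnitudes = numeric(0),
                          prominences = numeric(0), threshold_mv = 0,
                          rel_threshold = rel_threshold),
                     class = "peak_set"))
  }
  thr <- rel_threshold * rng
  idx <- local_maxima(envelope)
  prom <- vapply(idx, function(i) peak_prominence(envelope, i), numeric(1))
  keep <- prom >= thr
  structure(list(indices = idx[keep], magnitudes = envelope[idx[keep]],
                 prominences = prom[keep], threshold_mv = thr,
                 rel_threshold = rel_threshold),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s), prominence threshold %.4g mV\n",
              length(x$indices), x$threshold_mv))
  invisible(x)
}

#' Peak table of a peak set
#'
#' @param x a `peak_set`.
#' @param fs sampling rate in Hz (for the `time_s` column); the time axis
#'   starts at `t0_s`.
#' @param t0_s time of the first envelope sample (default 0).
#' @param ... unused.
#' @return data.frame with columns `index`, `time_s`, `magnitude_mv`,
#'   `prominence_mv`.
#' @export
peak_table <- function(x, fs, t0_s = 0, ...) {
  data.frame(index = x$indices,
             time_s = t0_s + (x$indices - 1) / fs,
             magnitude_mv = x$magnitudes,
             prominence_mv = x$prominences)
}

#' Burst metrics of a peak set
#'
#' The three whole-recording activation metrics: number of peaks (moments of
#' muscle activation), median peak amplitude (power of the contractions) and
#' mean inter-peak interval (time between activations). Median and interval
#' are `NA` when fewer than 1 or 2 peaks exist, respectively.
#'
#' @param peaks a `peak_set`.
#' @param fs sampling rate in Hz.
#' @return list of class `burst_features`: `n_peaks`,
#'   `median_peak_amplitude_mv`, `mean_inter_peak_interval_s`.
#' @export
burst_features <- function(peaks, fs) {
  n <- length(peaks$indices)
  structure(list(
    n_peaks = n,
    median_peak_amplitude_mv = if (n >= 1L) median(peaks$magnitudes) else NA_real_,
    mean_inter_peak_interval_s =
      if (n >= 2L) mean(diff(peaks$indices)) / fs else NA_real_),
    class = "burst_features")
}

#' Burst metrics for every channel of every recording in a cohort
#'
#' Runs the conditioning chain and prominence-based peak selection on each
#' channel and tabulates the three burst metrics, one row per
#' recording x channel.
#'
#' @param cohort an `emg_cohort` (or plain list of `emg_recording`s).
#' @param params a [preprocess_params()].
#' @param rel_threshold relative prominence threshold (default 0.1).
#' @return data.frame with columns `subject_id`, `group`, `condition`,
#'   `task`, `channel`, `n_peaks`, `median_amp_mv`, `mean_ipi_s`.
#' @export
cohort_burst_features <- function(cohort, params = preprocess_params(),
                                  rel_threshold = 0.1) {
  recs <- if (inherits(cohort, "emg_cohort")) cohort$recordings else cohort
  rows <- lapply(recs, function(rec) {
    proc <- preprocess_recording(rec, params)
    labs <- channel_labels(rec)
    do.call(rbind, lapply(seq_along(labs), function(i) {
      ps <- select_peaks(proc$envelope[i, ], rel_threshold)
      bf <- burst_features(ps, proc$sampling_rate_hz)
      data.frame(subject_id = rec$subject_id, group = rec$group,
                 condition = rec$condition, task = rec$task,
                 channel = labs[i], n_peaks = bf$n_peaks,
                 median_amp_mv = bf$median_peak_amplitude_mv,
                 mean_ipi_s = bf$mean_inter_peak_interval_s)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
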