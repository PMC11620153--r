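# Signal conditioning chain: DC-offset removal -> Butterworth band-pass ->
# edge trimming -> rectification -> linear envelope.

#' Band-pass filter specification
#'
#' An even-order Butterworth band-pass. `order` is the overall filter order
#' (the underlying low/high prototype order is `order/2`). With
#' `zero_phase = TRUE` the filter is applied forward and backward, which
#' cancels group delay (burst peak timing is preserved) at the cost of
#' doubling the effective magnitude order.
#'
#' @param order overall filter order; even, >= 2 (default 8).
#' @param low_hz lower passband edge in Hz (default 10).
#' @param high_hz upper passband edge in Hz (default 100).
#' @param zero_phase apply forward-backward (default TRUE).
#' @return a `filter_spec` list.
#' @export
filter_spec <- function(order = 8, low_hz = 10, high_hz = 100,
                        zero_phase = TRUE) {
  if (order < 2 || order %% 2 != 0) stop("order must be even and >= 2")
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("need 0 < low_hz < high_hz")
  structure(list(order = order, low_hz = low_hz, high_hz = high_hz,
                 zero_phase = zero_phase), class = "filter_spec")
}

# Zero-phase IIR filtering with odd-reflection edge padding. signal::filtfilt
# starts both passes from zero initial conditions, which leaves long edge
# transients for filters with slow poles (the 6 Hz envelope low-pass has a
# ~26 ms time constant); reflecting the signal about its endpoints before
# filtering pushes the transient into the discarded pad.
zero_phase_filter <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad > 0L) {
    left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    xe <- c(left, x, right)
  } else xe <- x
  y <- as.numeric(signal::filter(filt, xe))
  y <- rev(as.numeric(signal::filter(filt, rev(y))))
  y[seq(pad + 1L, pad + n)]
}

#' Remove the baseline DC offset of a signal
#'
#' Subtracts the sample mean, so the output has mean zero. A constant signal
#' maps to all zeros.
#'
#' @param x numeric vector, length >= 1.
#' @return `x - mean(x)`.
#' @export
remove_dc_offset <- function(x) {
  if (length(x) < 1L) stop("empty signal")
  x - mean(x)
}

#' Butterworth band-pass filter a signal
#'
#' Applies the band-pass described by `spec` at sampling rate `fs`. In
#' zero-phase mode (the default) the filter runs forward and backward with
#' odd-reflection edge padding, so a symmetric pulse keeps its peak sample.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param spec a [filter_spec()].
#' @return filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, spec = filter_spec()) {
  if (spec$high_hz >= fs / 2)
    stop("high_hz must be below the Nyquist frequency fs/2")
  bf <- signal::butter(spec$order / 2,
                       c(spec$low_hz, spec$high_hz) / (fs / 2), type = "pass")
  if (spec$zero_phase) {
    pad <- ceiling(3 * fs / spec$low_hz)
    zero_phase_filter(bf, x, pad)
  } else {
    as.numeric(signal::filter(bf, x))
  }
}

#' Trim movement-initiation and -termination artifacts from both ends
#'
#' Drops `round(trim_s * fs)` samples from each edge (half-open sample
#' indexing), removing segments contaminated by the start/stop of the motor
#' task.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param trim_s seconds to cut from each end (default 2).
#' @return the central portion of `x`.
#' @export
trim_edges <- function(x, fs, trim_s = 2.0) {
  k <- round(trim_s * fs)
  if (k < 0) stop("trim_s must be >= 0")
  if (length(x) <= 2 * k)
    stop("signal shorter than twice the trim duration")
  if (k == 0) return(x)
  x[seq(k + 1L, length(x) - k)]
}

#' Full-wave rectification
#'
#' @param x numeric vector.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' Linear envelope of a rectified signal
#'
#' Low-pass filters the rectified signal to trace overall activation
#' intensity. Default: 2nd-order zero-phase Butterworth at 6 Hz (DC gain 1),
#' which preserves burst trains up to ~5 Hz while smoothing the carrier.
#' Negative excursions introduced by filtering are clipped to zero. A moving
#' root-mean-square alternative is available via `method = "rms"`.
#'
#' @param x non-negative numeric vector (rectified signal).
#' @param fs sampling rate in Hz.
#' @param cutoff_hz low-pass cutoff in Hz (default 6); for `method = "rms"`,
#'   the RMS window is `1 / cutoff_hz` seconds.
#' @param order low-pass order (default 2).
#' @param zero_phase forward-backward filtering (default TRUE).
#' @param method `"lowpass"` (default) or `"rms"`.
#' @return non-negative envelope, same length as `x`.
#' @export
linear_envelope <- function(x, fs, cutoff_hz = 6.0, order = 2,
                            zero_phase = TRUE, method = c("lowpass", "rms")) {
  method <- match.arg(method)
  if (cutoff_hz >= fs / 2) stop("cutoff_hz must be below Nyquist")
  if (any(x < 0)) stop("input must be rectified (non-negative)")
  if (method == "rms") {
    w <- max(1L, round(fs / cutoff_hz))
    k <- rep(1 / w, w)
    env <- sqrt(pmax(0, as.numeric(stats::filter(x^2, k, sides = 2))))
    # stats::filter leaves NAs at the edges; hold the nearest defined value
    idx <- which(!is.na(env))
    env[seq_len(idx[1] - 1L)] <- env[idx[1]]
    env[seq(idx[length(idx)] + 1L, length.out = length(env) - idx[length(idx)])] <-
      env[idx[length(idx)]]
    return(env)
  }
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  y <- if (zero_phase) {
    zero_phase_filter(bf, x, pad = ceiling(3 * fs / cutoff_hz))
  } else {
    as.numeric(signal::filter(bf, x))
  }
  pmax(y, 0)
}

#' Preprocessing parameter block
#'
#' @param filter a [filter_spec()].
#' @param trim_s seconds trimmed from each edge (default 2).
#' @param envelope_cutoff_hz envelope low-pass cutoff (default 6).
#' @param envelope_order envelope filter order (default 2).
#' @param envelope_method `"lowpass"` or `"rms"`.
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(filter = filter_spec(), trim_s = 2.0,
                              envelope_cutoff_hz = 6.0, envelope_order = 2,
                              envelope_method = "lowpass") {
  structure(list(filter = filter, trim_s = trim_s,
                 envelope_cutoff_hz = envelope_cutoff_hz,
                 envelope_order = envelope_order,
                 envelope_method = envelope_method),
            class = "preprocess_params")
}

#' Run the full conditioning chain on every channel of a recording
#'
#' Chain order: DC-offset removal, band-pass, edge trimming, rectification,
#' linear envelope. Returns both the band-passed/trimmed (signed) signals,
#' used for windowed feature extraction, and the envelopes, used for burst
#' detection.
#'
#' @param rec an `emg_recording`.
#' @param params a [preprocess_params()].
#' @return list of class `emg_processed`: `filtered` and `envelope`
#'   (channels x time matrices over the trimmed support), `sampling_rate_hz`,
#'   `channels`, `t0_s` (start of the trimmed support), `params`, and the
#'   provenance fields `subject_id`, `group`, `condition`, `task`.
#' @export
preprocess_recording <- function(rec, params = preprocess_params()) {
  validate_recording(rec)
  fs <- rec$sampling_rate_hz
  out_f <- NULL
  out_e <- NULL
  for (i in seq_len(nrow(rec$samples))) {
    x <- remove_dc_offset(rec$samples[i, ])
    x <- bandpass(x, fs, params$filter)
    x <- trim_edges(x, fs, params$trim_s)
    r <- rectify(x)
    env <- linear_envelope(r, fs, cutoff_hz = params$envelope_cutoff_hz,
                           order = params$envelope_order,
                           zero_phase = params$filter$zero_phase,
                           method = params$envelope_method)
    if (is.null(out_f)) {
      out_f <- matrix(0, nrow(rec$samples), length(x))
      out_e <- matrix(0, nrow(rec$samples), length(env))
    }
    out_f[i, ] <- x
    out_e[i, ] <- env
  }
  structure(list(filtered = out_f, envelope = out_e,
                 sampling_rate_hz = fs, channels = rec$channels,
                 t0_s = rec$t0_s + round(params$trim_s * fs) / fs,
                 params = params, subject_id = rec$subject_id,
                 group = rec$group, condition = rec$condition,
                 task = rec$task),
            class = "emg_processed")
}
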