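# Forward model: EMG-like cohorts with known ground truth. Repetitive-task
# muscle activity is emulated as burst-modulated band-limited noise whose
# burst (tap) rate encodes bradykinesia severity; clinical scores are a
# noisy antitone function of the rate.

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 6 PD patients recorded OFF and ON
#' medication plus 7 healthy controls, 23-second recordings at 1260 Hz with
#' a 20-450 Hz sensor band. Tap rates: PD OFF 1.5 Hz, PD ON 3.0 Hz, healthy
#' 4.0 Hz, between-subject SD 0.3 Hz; timing jitter CV 0.1; 120 ms bursts of
#' 0.5 mV against 0.02 mV baseline noise. An optional amplitude-decrement
#' slope models the parkinsonian sequence effect, and an optional 4-6 Hz
#' amplitude-modulated component models rest tremor (both 0 by default).
#'
#' @param n_pd,n_healthy cohort sizes (defaults 6 and 7).
#' @param duration_s recording length in seconds (default 23).
#' @param fs_hz sampling rate in Hz (default 1260).
#' @param rate_pd_off_hz,rate_pd_on_hz,rate_healthy_hz mean tap rates per
#'   group/condition in Hz.
#' @param rate_between_sd_hz between-subject SD of the subject rate trait.
#' @param jitter_cv coefficient of variation of inter-tap intervals.
#' @param burst_width_s Hann burst width in seconds (default 0.12).
#' @param burst_amplitude_mv burst amplitude in mV (default 0.5).
#' @param decrement_slope sequence-effect slope delta in \[0, 1): burst k of
#'   K has amplitude `a0 * (1 - delta * (k-1)/(K-1))` (default 0).
#' @param carrier_low_hz,carrier_high_hz band of the EMG carrier noise
#'   (defaults 20 and 450; `fs_hz` must exceed twice the upper edge).
#' @param baseline_noise_sd_mv additive baseline noise SD (default 0.02).
#' @param tremor_amplitude_mv amplitude of the 4-6 Hz tremor component
#'   (default 0).
#' @param tremor_freq_hz tremor frequency (default 5).
#' @param score_noise_sd SD of the noise added to each simulated item score
#'   (default 0.3).
#' @param tasks motor tasks to simulate (default both).
#' @param channels channel table (default the four forearm channels).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pd = 6, n_healthy = 7, duration_s = 23,
                       fs_hz = 1260,
                       rate_pd_off_hz = 1.5, rate_pd_on_hz = 3.0,
                       rate_healthy_hz = 4.0, rate_between_sd_hz = 0.3,
                       jitter_cv = 0.1, burst_width_s = 0.12,
                       burst_amplitude_mv = 0.5, decrement_slope = 0,
                       carrier_low_hz = 20, carrier_high_hz = 450,
                       baseline_noise_sd_mv = 0.02,
                       tremor_amplitude_mv = 0, tremor_freq_hz = 5,
                       score_noise_sd = 0.3,
                       tasks = c("finger_tapping", "hand_movements"),
                       channels = data.frame(
                         muscle = rep(c("flexors", "extensors"), 2),
                         side = rep(c("left", "right"), each = 2))) {
  if (any(c(rate_pd_off_hz, rate_pd_on_hz, rate_healthy_hz) <= 0))
    stop("tap rates must be positive")
  if (!(rate_pd_off_hz < rate_pd_on_hz && rate_pd_on_hz <= rate_healthy_hz))
    stop("need rate_pd_off < rate_pd_on <= rate_healthy")
  if (fs_hz <= 2 * carrier_high_hz)
    stop("fs_hz must exceed twice the carrier upper edge")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate tap (burst) times as a Gamma renewal process
#'
#' Inter-tap intervals are Gamma distributed with mean `1/rate_hz` and
#' coefficient of variation `jitter_cv` (quasi-periodic tapping); with
#' `jitter_cv = 0` spacing is exact. Times are truncated to
#' `(0, duration_s)`.
#'
#' @param rate_hz mean tap rate, > 0.
#' @param duration_s recording duration.
#' @param jitter_cv interval CV (>= 0).
#' @return strictly increasing numeric vector of tap times in seconds.
#' @export
simulate_tap_times <- function(rate_hz, duration_s, jitter_cv = 0.1) {
  if (rate_hz <= 0) stop("rate must be positive")
  n_max <- ceiling(rate_hz * duration_s * 2) + 20L
  if (jitter_cv == 0) {
    iv <- rep(1 / rate_hz, n_max)
  } else {
    shape <- 1 / jitter_cv^2
    iv <- rgamma(n_max, shape = shape, rate = shape * rate_hz)
  }
  t <- cumsum(iv)
  t[t > 0 & t < duration_s]
}

bandlimited_noise <- function(n, fs, low_hz, high_hz) {
  x <- rnorm(n)
  bf <- signal::butter(2, c(low_hz, high_hz) / (fs / 2), type = "pass")
  y <- zero_phase_filter(bf, x, pad = ceiling(3 * fs / low_hz))
  y / sd(y)
}

#' Render one sEMG-like channel from tap times
#'
#' The signal is a sum of Hann-shaped activation bursts centred on the tap
#' times, multiplying unit-variance band-limited carrier noise, plus
#' baseline noise and an optional amplitude-modulated tremor component.
#' Burst k of K has amplitude `a0 * (1 - delta * (k-1)/(K-1))` (the sequence
#' effect; constant `a0` when `delta = 0`).
#'
#' @param tap_times tap times in seconds.
#' @param config a [sim_config()].
#' @return numeric vector of `round(duration_s * fs_hz)` samples (mV).
#' @export
render_emg <- function(tap_times, config = sim_config()) {
  fs <- config$fs_hz
  n <- round(config$duration_s * fs)
  envelope <- numeric(n)
  K <- length(tap_times)
  wlen <- max(3L, round(config$burst_width_s * fs))
  pulse <- hann_window(wlen)
  for (k in seq_len(K)) {
    a <- config$burst_amplitude_mv *
      (1 - if (K > 1) config$decrement_slope * (k - 1) / (K - 1) else 0)
    c0 <- round(tap_times[k] * fs)
    lo <- c0 - floor(wlen / 2)
    idx <- seq(lo, lo + wlen - 1L)
    ok <- idx >= 1L & idx <= n
    envelope[idx[ok]] <- envelope[idx[ok]] + a * pulse[ok]
  }
  sig <- envelope * bandlimited_noise(n, fs, config$carrier_low_hz,
                                      config$carrier_high_hz) +
    rnorm(n, 0, config$baseline_noise_sd_mv)
  if (config$tremor_amplitude_mv > 0) {
    t <- (seq_len(n) - 1) / fs
    trem_env <- config$tremor_amplitude_mv *
      (0.5 - 0.5 * cos(2 * pi * config$tremor_freq_hz * t))
    sig <- sig + trem_env * bandlimited_noise(n, fs, config$carrier_low_hz,
                                              config$carrier_high_hz)
  }
  sig
}

#' Simulate MDS-UPDRS-like item scores antitone in the tap rate
#'
#' Each of the nine upper-limb motor items is
#' `clip(round(4.5 - rate + N(0, score_noise_sd)), 0, 4)`, so slower tapping
#' maps to worse (higher) scores; the subtotal and Part-III total are the
#' item sum. Deterministic when `score_noise_sd = 0`.
#'
#' @param true_rate_hz the subject-condition tap rate in Hz.
#' @param config a [sim_config()].
#' @param subject_id,condition metadata stamped on the row.
#' @return one-row data.frame in the [load_scores()] schema.
#' @export
simulate_scores <- function(true_rate_hz, config = sim_config(),
                            subject_id = "s1", condition = "off") {
  if (true_rate_hz <= 0) stop("rate must be positive")
  items <- vapply(upper_limb_items, function(it) {
    raw <- 4.5 - true_rate_hz +
      if (config$score_noise_sd > 0) rnorm(1, 0, config$score_noise_sd) else 0
    min(4L, max(0L, as.integer(round(raw))))
  }, integer(1))
  df <- data.frame(subject_id = subject_id, condition = condition)
  for (i in seq_along(items)) df[[paste0("item_", upper_limb_items[i])]] <- items[i]
  df$upper_limb_subtotal <- sum(items)
  df$total_part3 <- sum(items)
  df
}

#' Generate a full synthetic cohort with ground truth
#'
#' PD subjects get OFF and ON recordings for every task; healthy subjects
#' one recording per task (condition `"na"`). Each subject carries a rate
#' trait (N(0, between-subject SD)) added to the group/condition mean rate;
#' all channels of a recording share the tap times but have independent
#' carrier noise. PD clinical scores are generated from the same rates.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (the only source of randomness).
#' @return object of class `emg_cohort`: `recordings` (named list of
#'   `emg_recording`), `scores` (PD rows, [load_scores()] schema),
#'   `manifest` (one row per recording), `truth` (per-recording tap times
#'   and rates, per-subject traits), `config`, `seed`.
#' @export
generate_cohort <- function(config = sim_config(), seed = 1) {
  set.seed(seed)
  subjects <- data.frame(
    subject_id = c(sprintf("pd%02d", seq_len(config$n_pd)),
                   sprintf("hc%02d", seq_len(config$n_healthy))),
    group = rep(c("pd", "healthy"), c(config$n_pd, config$n_healthy)))
  subjects$trait <- rnorm(nrow(subjects), 0, config$rate_between_sd_hz)

  recordings <- list()
  manifest <- list()
  truth <- list(subjects = subjects, recordings = list())
  scores <- list()
  min_rate <- 0.2

  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    grp <- subjects$group[i]
    conds <- if (grp == "pd") c("off", "on") else "na"
    for (cond in conds) {
      rate <- max(min_rate, subjects$trait[i] + switch(
        cond,
        off = config$rate_pd_off_hz,
        on = config$rate_pd_on_hz,
        na = config$rate_healthy_hz))
      if (grp == "pd")
        scores[[paste(sid, cond)]] <-
          simulate_scores(rate, config, subject_id = sid, condition = cond)
      for (task in config$tasks) {
        taps <- simulate_tap_times(rate, config$duration_s, config$jitter_cv)
        samples <- t(vapply(seq_len(nrow(config$channels)),
                            function(j) render_emg(taps, config),
                            numeric(round(config$duration_s * config$fs_hz))))
        rec <- emg_recording(samples, config$fs_hz, config$channels,
                             subject_id = sid, group = grp,
                             condition = cond, task = task)
        rid <- paste(sid, cond, task, sep = "_")
        recordings[[rid]] <- rec
        manifest[[rid]] <- data.frame(subject_id = sid, group = grp,
                                      condition = cond, task = task,
                                      recording_id = rid)
        truth$recordings[[rid]] <- list(tap_times = taps, rate_hz = rate,
                                        n_taps = length(taps))
      }
    }
  }
  man <- do.call(rbind, manifest)
  rownames(man) <- NULL
  structure(list(recordings = recordings,
                 scores = if (length(scores)) do.call(rbind, c(scores, list(make.row.names = FALSE))) else NULL,
                 manifest = man, truth = truth, config = config,
                 seed = seed),
            class = "emg_cohort")
}

#' @export
print.emg_cohort <- function(x, ...) {
  cat(sprintf("<emg_cohort> %d recording(s), %d subject(s)\n",
              length(x$recordings), length(unique(x$manifest$subject_id))))
  invisible(x)
}
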