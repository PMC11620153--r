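# Windowed time-domain feature extraction: Hudgins set {MAV, ZC, WL, SSC},
# Du set {IAV, VAR, WL, ZC, SSC, WAMP}, extended additions {MAV1, MAV2,
# ApEn, SampEn}; per-channel aggregation and z-score standardization.

#' Segmentation window specification
#'
#' @param length_s window length in seconds (default 1).
#' @param step_s hop between window starts in seconds (default 0.5, i.e.
#'   50 percent overlap).
#' @param taper `"hann"` (default; the window function is applied
#'   multiplicatively to every segment) or `"rect"` (plain slices).
#' @return a `window_spec` list.
#' @export
window_spec <- function(length_s = 1.0, step_s = 0.5,
                        taper = c("hann", "rect")) {
  taper <- match.arg(taper)
  if (!(step_s > 0 && step_s <= length_s))
    stop("need 0 < step_s <= length_s")
  structure(list(length_s = length_s, step_s = step_s, taper = taper),
            class = "window_spec")
}

#' Feature computation parameters
#'
#' Amplitude thresholds for the counting features and embedding parameters
#' for the entropies. Thresholds given as `NULL` (the default) resolve
#' per-window to `eps_factor` times the window standard deviation, which
#' keeps the counts invariant under rescaling of the signal; absolute values
#' may be supplied instead.
#'
#' @param eps_zc,eps_ssc,eps_wamp absolute thresholds in mV, or `NULL` for
#'   the scale-free default.
#' @param eps_factor multiplier of the window SD used when a threshold is
#'   `NULL` (default 0.05).
#' @param entropy_m embedding dimension for ApEn/SampEn (default 2).
#' @param entropy_r_factor tolerance radius as a multiple of the window SD
#'   (default 0.2); Chebyshev distance.
#' @return a `feature_params` list.
#' @export
feature_params <- function(eps_zc = NULL, eps_ssc = NULL, eps_wamp = NULL,
                           eps_factor = 0.05, entropy_m = 2,
                           entropy_r_factor = 0.2) {
  if (entropy_m < 1) stop("entropy_m must be >= 1")
  if (entropy_r_factor <= 0) stop("entropy_r_factor must be > 0")
  structure(list(eps_zc = eps_zc, eps_ssc = eps_ssc, eps_wamp = eps_wamp,
                 eps_factor = eps_factor, entropy_m = entropy_m,
                 entropy_r_factor = entropy_r_factor),
            class = "feature_params")
}

hann_window <- function(n) {
  if (n < 2L) return(rep(1, n))
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Segment a signal into overlapping (optionally tapered) windows
#'
#' Window k covers samples `[k*step, k*step + len)` (0-based starts), giving
#' `floor((N - len)/step) + 1` windows; with `taper = "hann"` each segment is
#' multiplied by the Hann window.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param spec a [window_spec()].
#' @return numeric matrix, one column per window.
#' @export
segment_windows <- function(x, fs, spec = window_spec()) {
  len <- round(spec$length_s * fs)
  step <- round(spec$step_s * fs)
  if (length(x) < len) stop("signal shorter than one window")
  starts <- seq(1L, length(x) - len + 1L, by = step)
  w <- if (spec$taper == "hann") hann_window(len) else rep(1, len)
  vapply(starts, function(s) x[seq(s, s + len - 1L)] * w, numeric(len))
}

resolve_eps <- function(eps, factor, w) {
  if (is.null(eps)) factor * sd(w) else eps
}

#' Hudgins time-domain feature set of one window
#'
#' MAV = mean(|x|); WL = sum(|diff(x)|); ZC counts sign changes between
#' consecutive samples whose amplitude jump reaches `eps_zc`; SSC counts
#' slope sign changes `(x_i - x_{i-1})(x_i - x_{i+1}) > 0` whose larger
#' adjacent jump reaches `eps_ssc`.
#'
#' @param w numeric window, length >= 3.
#' @param params a [feature_params()].
#' @return named numeric vector `c(MAV, ZC, WL, SSC)`.
#' @export
feat_hudgins <- function(w, params = feature_params()) {
  n <- length(w)
  if (n < 3L) stop("window must have length >= 3")
  d <- diff(w)
  eps_zc <- resolve_eps(params$eps_zc, params$eps_factor, w)
  eps_ssc <- resolve_eps(params$eps_ssc, params$eps_factor, w)
  zc <- sum(w[-n] * w[-1] < 0 & abs(d) >= eps_zc)
  mid <- seq(2L, n - 1L)
  dl <- w[mid] - w[mid - 1L]
  dr <- w[mid] - w[mid + 1L]
  ssc <- sum(dl * dr > 0 & pmax(abs(dl), abs(dr)) >= eps_ssc)
  c(MAV = mean(abs(w)), ZC = zc, WL = sum(abs(d)), SSC = ssc)
}

#' Du time-domain feature set of one window
#'
#' IAV = sum(|x|); VAR = sum(x^2)/(N-1) (the EMG convention assumes a
#' zero-mean signal); WAMP counts consecutive-sample jumps of at least
#' `eps_wamp`; WL, ZC, SSC as in [feat_hudgins()].
#'
#' @inheritParams feat_hudgins
#' @return named numeric vector `c(IAV, VAR, WL, ZC, SSC, WAMP)`.
#' @export
feat_du <- function(w, params = feature_params()) {
  h <- feat_hudgins(w, params)
  eps_wamp <- resolve_eps(params$eps_wamp, params$eps_factor, w)
  c(IAV = sum(abs(w)), VAR = sum(w^2) / (length(w) - 1),
    WL = unname(h["WL"]), ZC = unname(h["ZC"]), SSC = unname(h["SSC"]),
    # the d != 0 guard only matters for the degenerate eps_wamp = 0 case
    # (a flat signal has no Willison activity)
    WAMP = sum(abs(diff(w)) >= eps_wamp & diff(w) != 0))
}

#' Extended feature set of one window: MAV1, MAV2, ApEn, SampEn
#'
#' MAV1 and MAV2 are weighted mean absolute values emphasising the central
#' half of the window: MAV1 weights are 1 for `0.25N <= i <= 0.75N` and 0.5
#' outside; MAV2 tapers linearly, `4i/N` below the central band and
#' `4(N-i)/N` above it. ApEn and SampEn use embedding dimension
#' `entropy_m`, Chebyshev radius `entropy_r_factor * sd(w)`; ApEn includes
#' self-matches, SampEn excludes them and is `NA` when no template pair
#' matches.
#'
#' @param w numeric window, length >= `entropy_m + 2`.
#' @param params a [feature_params()].
#' @return named numeric vector `c(MAV1, MAV2, ApEn, SampEn)`.
#' @export
feat_extended <- function(w, params = feature_params()) {
  n <- length(w)
  if (n < params$entropy_m + 2L) stop("window too short for the entropies")
  i <- seq_len(n)
  central <- i >= 0.25 * n & i <= 0.75 * n
  w1 <- ifelse(central, 1, 0.5)
  w2 <- ifelse(central, 1, ifelse(i < 0.25 * n, 4 * i / n, 4 * (n - i) / n))
  r <- params$entropy_r_factor * sd(w)
  ent <- entropy_pair_cpp(as.numeric(w), as.integer(params$entropy_m), r)
  c(MAV1 = mean(w1 * abs(w)), MAV2 = mean(w2 * abs(w)),
    ApEn = ent[1], SampEn = ent[2])
}

#' Approximate entropy ApEn(m, r)
#'
#' Regularity statistic: phi(m) - phi(m+1) with self-matches included and
#' Chebyshev template distance. Low values indicate a predictable signal.
#'
#' @param x numeric vector, length >= m + 2.
#' @param m embedding dimension (default 2).
#' @param r tolerance radius on the scale of `x`.
#' @return scalar ApEn.
#' @export
approx_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  entropy_pair_cpp(as.numeric(x), as.integer(m), r)[1]
}

#' Sample entropy SampEn(m, r)
#'
#' `-log(A/B)` where B counts template pairs of length `m` within Chebyshev
#' radius `r` (self-matches excluded) and A the subset that still match at
#' length `m + 1`. `NA` when A or B is zero.
#'
#' @inheritParams approx_entropy
#' @return scalar SampEn, possibly `NA`.
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * sd(x)) {
  entropy_pair_cpp(as.numeric(x), as.integer(m), r)[2]
}

standard_feature_names <- c("MAV", "ZC", "WL", "SSC", "IAV", "VAR", "WAMP")
extended_feature_names <- c(standard_feature_names,
                            "MAV1", "MAV2", "ApEn", "SampEn")

window_features <- function(w, params, feature_set) {
  h <- feat_hudgins(w, params)
  d <- feat_du(w, params)
  out <- c(MAV = unname(h["MAV"]), ZC = unname(h["ZC"]),
           WL = unname(h["WL"]), SSC = unname(h["SSC"]),
           IAV = unname(d["IAV"]), VAR = unname(d["VAR"]),
           WAMP = unname(d["WAMP"]))
  if (feature_set == "extended") out <- c(out, feat_extended(w, params))
  out[if (feature_set == "extended") extended_feature_names
      else standard_feature_names]
}

#' Per-channel feature vector: windowed features averaged over windows
#'
#' Segments the signal, computes the chosen feature set in every window and
#' averages each feature across windows. Windows where an entropy is
#' undefined are excluded from that feature's mean; if a feature is
#' undefined in every window it falls back to 0 and the returned vector
#' carries an `undefined_features` attribute naming it.
#'
#' @param x numeric vector (a conditioned, signed signal).
#' @param fs sampling rate in Hz.
#' @param spec a [window_spec()].
#' @param params a [feature_params()].
#' @param feature_set `"standard"` or `"extended"`.
#' @return named numeric feature vector.
#' @export
channel_features <- function(x, fs, spec = window_spec(),
                             params = feature_params(),
                             feature_set = c("standard", "extended")) {
  feature_set <- match.arg(feature_set)
  W <- segment_windows(x, fs, spec)
  mat <- apply(W, 2, window_features, params = params,
               feature_set = feature_set)
  out <- rowMeans(mat, na.rm = TRUE)
  all_na <- apply(mat, 1, function(v) all(is.na(v)))
  if (any(all_na)) {
    out[all_na] <- 0
    attr(out, "undefined_features") <- names(out)[all_na]
  }
  out
}

#' Build the cohort feature table
#'
#' One row per recording (keyed by subject, condition, task), one column per
#' feature x channel (`<FEATURE>_<muscle>_<side>`). Features are computed on
#' the band-passed, trimmed signal of each channel; with
#' `include_burst = TRUE` the whole-recording burst metrics `n_peaks` and
#' `mean_ipi_s` from the envelope are appended per channel.
#'
#' @param cohort an `emg_cohort` or list of `emg_recording`s.
#' @param preproc a [preprocess_params()].
#' @param spec a [window_spec()].
#' @param params a [feature_params()].
#' @param feature_set `"standard"` or `"extended"`.
#' @param include_burst append burst metrics per channel (default TRUE for
#'   the extended set, FALSE for the standard set).
#' @param rel_threshold prominence threshold for the burst metrics.
#' @return data.frame: `subject_id`, `condition`, `task`, then numeric
#'   feature columns.
#' @export
build_feature_table <- function(cohort, preproc = preprocess_params(),
                                spec = window_spec(),
                                params = feature_params(),
                                feature_set = c("standard", "extended"),
                                include_burst = NULL, rel_threshold = 0.1) {
  feature_set <- match.arg(feature_set)
  if (is.null(include_burst)) include_burst <- feature_set == "extended"
  recs <- if (inherits(cohort, "emg_cohort")) cohort$recordings else cohort
  if (!length(recs)) stop("empty cohort")
  rows <- lapply(recs, function(rec) {
    proc <- preprocess_recording(rec, preproc)
    labs <- channel_labels(rec)
    vals <- numeric(0)
    for (i in seq_along(labs)) {
      fv <- channel_features(proc$filtered[i, ], proc$sampling_rate_hz,
                             spec, params, feature_set)
      nm <- paste(names(fv), labs[i], sep = "_")
      if (include_burst) {
        ps <- select_peaks(proc$envelope[i, ], rel_threshold)
        bf <- burst_features(ps, proc$sampling_rate_hz)
        fv <- c(as.numeric(fv), bf$n_peaks,
                ifelse(is.na(bf$mean_inter_peak_interval_s), 0,
                       bf$mean_inter_peak_interval_s))
        nm <- c(nm, paste(c("n_peaks", "mean_ipi_s"), labs[i], sep = "_"))
      }
      v <- as.numeric(fv)
      names(v) <- nm
      vals <- c(vals, v)
    }
    cbind(data.frame(subject_id = rec$subject_id, condition = rec$condition,
                     task = rec$task),
          as.data.frame(as.list(vals), check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "feature_set") <- feature_set
  out
}

feature_columns <- function(table) {
  setdiff(names(table), c("subject_id", "condition", "task", "group"))
}

#' Z-score standardization fitted on a subset of rows
#'
#' Column means and standard deviations are estimated on `fit_rows` only and
#' applied to every row, so held-out rows are transformed with training
#' statistics (leakage-free use inside cross-validation). Columns with zero
#' SD on the fit subset map to 0 with a warning.
#'
#' @param table a feature table from [build_feature_table()].
#' @param fit_rows integer row indices used to fit the transform (default:
#'   all rows).
#' @return the standardized table; the fitted transform is stored in the
#'   `standardization` attribute (`means`, `sds`, `fit_rows`).
#' @export
standardize_features <- function(table, fit_rows = seq_len(nrow(table))) {
  if (!length(fit_rows)) stop("fit_rows must be non-empty")
  cols <- feature_columns(table)
  mu <- vapply(table[fit_rows, cols, drop = FALSE], mean, numeric(1))
  sg <- vapply(table[fit_rows, cols, drop = FALSE], sd, numeric(1))
  if (length(fit_rows) == 1L) sg[] <- 0
  zero <- sg == 0 | is.na(sg)
  if (any(zero))
    warning("constant feature column(s) on the fit subset mapped to 0: ",
            paste(cols[zero], collapse = ", "))
  for (j in seq_along(cols)) {
    v <- table[[cols[j]]]
    table[[cols[j]]] <- if (zero[j]) rep(0, length(v)) else (v - mu[j]) / sg[j]
  }
  attr(table, "standardization") <- list(means = mu, sds = sg,
                                         fit_rows = fit_rows)
  table
}
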