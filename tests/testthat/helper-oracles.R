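# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles re-derive each quantity from its definition by a
# different route than the package implementation.

# --- prominence / peak oracles -------------------------------------------

# Local maxima by explicit run-length scan over plateaus.
oracle_local_maxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (k in seq_along(r$values)) {
    if (k == 1L || k == length(r$values)) next
    if (r$values[k] > r$values[k - 1L] && r$values[k] > r$values[k + 1L])
      out <- c(out, as.integer((starts[k] + ends[k]) %/% 2))
  }
  out
}

# Prominence by walking outwards sample-by-sample until a strictly higher
# sample (or the edge) is met on each side.
oracle_prominence <- function(x, i) {
  h <- x[i]
  n <- length(x)
  lmin <- Inf
  j <- i - 1L
  while (j >= 1L && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1L }
  rmin <- Inf
  j <- i + 1L
  while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1L }
  h - max(lmin, rmin)
}

oracle_select_peaks <- function(x, rel_threshold) {
  idx <- oracle_local_maxima(x)
  thr <- rel_threshold * (max(x) - min(x))
  prom <- vapply(idx, function(i) oracle_prominence(x, i), numeric(1))
  list(indices = idx[prom >= thr], prominences = prom[prom >= thr],
       threshold = thr)
}

# Random envelope-like signals; integer-valued variants exercise plateaus.
random_envelope <- function(n, integer_valued = FALSE) {
  x <- abs(stats::filter(rnorm(n + 20), rep(1 / 5, 5), sides = 2))
  x <- as.numeric(x[!is.na(x)])[seq_len(n)]
  if (integer_valued) x <- round(3 * x)
  x
}

# --- entropy oracle -------------------------------------------------------

# O(N^2) template counting via explicit distance matrices.
oracle_entropy <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nt <- N - mm + 1L
    Tm <- sapply(seq_len(mm), function(k) x[k:(k + nt - 1L)])
    if (nt == 1L) Tm <- matrix(Tm, 1L)
    D <- matrix(0, nt, nt)
    for (k in seq_len(mm)) D <- pmax(D, abs(outer(Tm[, k], Tm[, k], "-")))
    mean(log(rowSums(D <= r) / nt))
  }
  apen <- phi(m) - phi(m + 1L)
  nt <- N - m
  Tm <- sapply(seq_len(m + 1L), function(k) x[k:(k + nt - 1L)])
  Dm <- matrix(0, nt, nt)
  for (k in seq_len(m)) Dm <- pmax(Dm, abs(outer(Tm[, k], Tm[, k], "-")))
  Dm1 <- pmax(Dm, abs(outer(Tm[, m + 1L], Tm[, m + 1L], "-")))
  B <- (sum(Dm <= r) - nt) / 2
  A <- (sum(Dm1 <= r) - nt) / 2
  c(apen = apen, sampen = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# --- mixed ANOVA oracle ---------------------------------------------------

# Observation-level deviational sums of squares for the 2x2 mixed design.
oracle_mixed_anova <- function(d) {
  d$subject_id <- as.character(d$subject_id)
  gm <- mean(d$value)
  subj_mean <- tapply(d$value, d$subject_id, mean)[d$subject_id]
  grp_mean <- tapply(d$value, d$group, mean)[d$group]
  cond_mean <- tapply(d$value, d$condition, mean)[d$condition]
  cell_mean <- tapply(d$value, paste(d$group, d$condition), mean)[
    paste(d$group, d$condition)]
  ss_group <- sum((grp_mean - gm)^2)
  ss_subj_w <- sum((subj_mean - grp_mean)^2)
  ss_cond <- sum((cond_mean - gm)^2)
  ss_int <- sum((cell_mean - grp_mean - cond_mean + gm)^2)
  ss_err_w <- sum((d$value - subj_mean - cell_mean + grp_mean)^2)
  n_subj <- length(unique(d$subject_id))
  df2 <- n_subj - 2
  f <- c(ss_group / (ss_subj_w / df2),
         ss_cond / (ss_err_w / df2),
         ss_int / (ss_err_w / df2))
  data.frame(source = c("group", "condition", "interaction"),
             df1 = 1L, df2 = df2, F = f,
             p = pf(f, 1, df2, lower.tail = FALSE), row.names = NULL)
}

random_anova_data <- function(n_a, n_b) {
  subjects <- sprintf("s%02d", seq_len(n_a + n_b))
  d <- expand.grid(subject_id = subjects, condition = c("off", "on"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(match(d$subject_id, subjects) <= n_a, "pd", "healthy")
  d$value <- rnorm(nrow(d))
  d
}

# --- fixtures -------------------------------------------------------------

make_test_recording <- function(n_channels = 2, n = 600, fs = 200,
                                subject = "s1", group = "pd",
                                condition = "off") {
  channels <- data.frame(
    muscle = rep(c("flexors", "extensors"), length.out = n_channels),
    side = rep(c("left", "right"), each = 2)[seq_len(n_channels)])
  emg_recording(matrix(rnorm(n_channels * n), n_channels), fs, channels,
                subject_id = subject, group = group, condition = condition,
                task = "finger_tapping")
}

# Fast small-scale simulation settings for IO / pipeline tests. Short
# recordings with a narrower carrier band and lower sampling rate; effect
# structure (rate ordering) is kept.
tiny_sim_config <- function(n_pd = 3, n_healthy = 3, ...) {
  sim_config(n_pd = n_pd, n_healthy = n_healthy, duration_s = 8,
             fs_hz = 400, carrier_low_hz = 20, carrier_high_hz = 150,
             tasks = "finger_tapping",
             channels = data.frame(muscle = "flexors", side = "left"), ...)
}

# Score table in the load_scores() schema with all items equal to `val`.
flat_scores <- function(subject_id, condition, val) {
  df <- data.frame(subject_id = subject_id, condition = condition)
  for (it in upper_limb_items) df[[paste0("item_", it)]] <- val
  df
}
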