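eps0 <- feature_params(eps_zc = 0, eps_ssc = 0, eps_wamp = 0)

test_that("window segmentation count and content are exact", {
  x <- rnorm(23940)
  W <- segment_windows(x, 1260, window_spec(1, 0.5, taper = "rect"))
  expect_equal(ncol(W), 37)
  expect_equal(nrow(W), 1260)
  expect_equal(W[, 1], x[1:1260])
  expect_equal(W[, 2], x[631:1890])

  # window-length signal gives exactly one window
  W1 <- segment_windows(rnorm(100), 100, window_spec(1, 0.5, taper = "rect"))
  expect_equal(ncol(W1), 1)

  # hann taper multiplies the segment and vanishes at the edges
  Wh <- segment_windows(x, 1260, window_spec(1, 0.5, taper = "hann"))
  expect_equal(Wh[1, 1], 0)
  expect_equal(Wh[630, 3], x[630 + 2 * 630] * (0.5 - 0.5 * cos(2 * pi * 629 / 1259)))

  # count formula over a parameter grid
  set.seed(2)
  for (i in 1:15) {
    n <- sample(200:5000, 1)
    fs <- 100
    len_s <- sample(c(0.5, 1, 1.5), 1)
    step_s <- runif(1, 0.1, len_s)
    len <- round(len_s * fs); step <- round(step_s * fs)
    if (n < len) next
    W <- segment_windows(rnorm(n), fs, window_spec(len_s, step_s))
    expect_equal(ncol(W), floor((n - len) / step) + 1)
  }
  expect_error(segment_windows(rnorm(50), 100, window_spec(1, 0.5)), "shorter")
})

test_that("Hudgins features match hand evaluation of the formulas", {
  h <- feat_hudgins(c(1, -1, 2, -2), eps0)
  expect_equal(h[["MAV"]], 1.5)
  expect_equal(h[["WL"]], 9)       # |−1−1| + |2+1| + |−2−2| = 2 + 3 + 4
  expect_equal(h[["ZC"]], 3)
  expect_equal(h[["SSC"]], 2)

  const <- feat_hudgins(rep(-3, 10), eps0)
  expect_equal(const[["MAV"]], 3)
  expect_equal(const[["WL"]], 0)
  expect_equal(const[["ZC"]], 0)
  expect_equal(const[["SSC"]], 0)

  ramp <- feat_hudgins(seq(-1, 1, length.out = 11), eps0)
  expect_equal(ramp[["SSC"]], 0)
  expect_lte(ramp[["ZC"]], 1)
})

test_that("Du features match hand evaluation", {
  d <- feat_du(c(1, -1, 2, -2), eps0)
  expect_equal(d[["IAV"]], 6)
  expect_equal(d[["VAR"]], 10 / 3)
  expect_equal(d[["WL"]], 9)
  expect_equal(feat_du(c(0, 1, 0, 1),
                       feature_params(eps_wamp = 0.5))[["WAMP"]], 3)
  expect_true(all(feat_du(rep(0, 8), eps0) == 0))
})

test_that("MAV1/MAV2 weighting and the entropies behave as defined", {
  e <- feat_extended(c(1, -1, 2, -2))
  expect_equal(e[["MAV1"]], 1.25)           # (1 + 1 + 2 + 0.5*2) / 4
  expect_equal(e[["MAV2"]], 1)              # weight 4(N-i)/N = 0 at i = N

  cst <- feat_extended(rep(2, 30))
  expect_equal(cst[["ApEn"]], 0)
  expect_equal(cst[["SampEn"]], 0)

  # an irregular series is less predictable than a periodic one
  set.seed(8)
  per <- sin(2 * pi * (1:150) / 15)
  rnd <- rnorm(150, sd = sd(per))
  expect_gt(approx_entropy(rnd, r = 0.2 * sd(rnd)),
            approx_entropy(per, r = 0.2 * sd(per)))

  # SampEn undefined marker when no templates match
  expect_true(is.na(sample_entropy(2^(1:15), m = 2, r = 0.01)))
})

test_that("entropies equal the O(N^2) template-count oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    x <- rnorm(n)
    r <- runif(1, 0.1, 0.4) * sd(x)
    got <- c(approx_entropy(x, 2, r), sample_entropy(x, 2, r))
    want <- oracle_entropy(x, 2, r)
    expect_equal(got, unname(want), tolerance = 1e-10)
  }
  # also at m = 3
  x <- rnorm(120)
  expect_equal(approx_entropy(x, 3, 0.3 * sd(x)),
               unname(oracle_entropy(x, 3, 0.3 * sd(x))["apen"]),
               tolerance = 1e-10)
})

test_that("features scale correctly under amplitude rescaling", {
  set.seed(12)
  w <- rnorm(200)
  cc <- 3.7
  a <- feat_du(w); b <- feat_du(cc * w)
  expect_equal(b[["IAV"]], cc * a[["IAV"]])
  expect_equal(b[["VAR"]], cc^2 * a[["VAR"]])
  expect_equal(b[["WL"]], cc * a[["WL"]])
  # counting features invariant when thresholds track the window SD
  expect_equal(b[["ZC"]], a[["ZC"]])
  expect_equal(b[["SSC"]], a[["SSC"]])
  expect_equal(b[["WAMP"]], a[["WAMP"]])
  expect_equal(feat_hudgins(cc * w)[["MAV"]], cc * feat_hudgins(w)[["MAV"]])
})

test_that("channel aggregation averages windows and applies the NA policy", {
  # identical non-overlapping windows: the mean equals one window's features
  w <- rnorm(100)
  x <- rep(w, 4)
  spec <- window_spec(1, 1, taper = "rect")
  cf <- channel_features(x, 100, spec, feature_set = "standard")
  expect_equal(unname(cf),
               unname(bradyemg:::window_features(w, feature_params(),
                                                 "standard")))

  # SampEn undefined in some windows: mean over the defined ones only
  x2 <- c(2^(1:100 / 10) * 1e6, sin(2 * pi * (1:300) / 20))
  cf2 <- channel_features(x2, 100, spec, feature_params(),
                          feature_set = "extended")
  expect_true(is.finite(cf2[["SampEn"]]))

  # all windows undefined: fallback 0 with a flag
  x3 <- 2^(1:200 / 4) * 1e8
  cf3 <- channel_features(x3, 100, spec, feature_params(entropy_r_factor = 1e-9),
                          feature_set = "extended")
  expect_equal(cf3[["SampEn"]], 0)
  expect_true("SampEn" %in% attr(cf3, "undefined_features"))
})

test_that("the cohort feature table has one row per recording", {
  co <- generate_cohort(tiny_sim_config(n_pd = 2, n_healthy = 0), seed = 2)
  tab <- build_feature_table(co, feature_set = "standard")
  expect_equal(nrow(tab), 4)   # 2 PD x 2 conditions x 1 task
  expect_true(all(c("subject_id", "condition", "task") %in% names(tab)))
  expect_true(all(paste0(c("MAV", "ZC", "WL", "SSC", "IAV", "VAR", "WAMP"),
                         "_flexors_left") %in% names(tab)))

  tab_e <- build_feature_table(co, feature_set = "extended")
  expect_true(all(c("MAV1_flexors_left", "ApEn_flexors_left",
                    "n_peaks_flexors_left") %in% names(tab_e)))
  expect_gt(ncol(tab_e), ncol(tab))
  expect_identical(tab_e[, c("subject_id", "condition", "task")],
                   tab[, c("subject_id", "condition", "task")])

  # include_burst = FALSE strictly shrinks the column set, rows unchanged
  tab_nb <- build_feature_table(co, feature_set = "extended",
                                include_burst = FALSE)
  expect_true(all(names(tab_nb) %in% names(tab_e)))
  expect_lt(ncol(tab_nb), ncol(tab_e))

  # deterministic under fixed inputs
  tab2 <- build_feature_table(co, feature_set = "standard")
  expect_identical(tab, tab2)
})

test_that("standardization fits on the requested rows only", {
  tab <- data.frame(subject_id = c("a", "b", "c"),
                    condition = c("off", "off", "off"),
                    task = "finger_tapping",
                    f1 = c(1, 2, 3), f2 = c(10, 20, 60))
  z <- standardize_features(tab)
  expect_equal(mean(z$f1), 0, tolerance = 1e-9)
  expect_equal(sd(z$f1), 1, tolerance = 1e-9)

  # held-out third row transformed with the training statistics
  z2 <- standardize_features(tab, fit_rows = 1:2)
  expect_equal(z2$f1[3], (3 - 1.5) / sd(c(1, 2)))
  expect_equal(z2$f2[3], (60 - 15) / sd(c(10, 20)))

  tab$f3 <- 5
  expect_warning(z3 <- standardize_features(tab), "constant")
  expect_equal(z3$f3, c(0, 0, 0))
})
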