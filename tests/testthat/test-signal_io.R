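test_that("recording constructor enforces the structural invariants", {
  rec <- make_test_recording()
  expect_s3_class(rec, "emg_recording")
  expect_equal(ncol(rec$samples), 600)

  # duplicate (muscle, side) labels
  expect_error(emg_recording(matrix(rnorm(20), 2), 100,
                             data.frame(muscle = c("flexors", "flexors"),
                                        side = c("left", "left")),
                             "s1", "pd", "off", "finger_tapping"),
               "duplicate")
  # healthy <-> condition 'na' coupling, both directions
  expect_error(emg_recording(matrix(rnorm(10), 1), 100,
                             data.frame(muscle = "flexors", side = "left"),
                             "s1", "healthy", "off", "finger_tapping"),
               "condition")
  expect_error(emg_recording(matrix(rnorm(10), 1), 100,
                             data.frame(muscle = "flexors", side = "left"),
                             "s1", "pd", "na", "finger_tapping"),
               "condition")
  expect_error(emg_recording(matrix(rnorm(10), 1), -5,
                             data.frame(muscle = "flexors", side = "left"),
                             "s1", "pd", "off", "finger_tapping"),
               "sampling_rate")
})

test_that("a 23 s recording at 1260 Hz holds 28980 samples per channel", {
  n <- round(23 * 1260)
  expect_equal(n, 28980)
  rec <- emg_recording(matrix(rnorm(4 * n), 4), 1260,
                       data.frame(muscle = rep(c("flexors", "extensors"), 2),
                                  side = rep(c("left", "right"), each = 2)),
                       "s1", "pd", "off", "finger_tapping")
  expect_equal(ncol(rec$samples), 28980)
})

test_that("save/load round-trips metadata exactly and samples to precision", {
  rec <- make_test_recording(n_channels = 2, n = 300)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  save_recording(rec, csv, js)
  back <- load_recording(csv, js)
  expect_identical(back$subject_id, rec$subject_id)
  expect_identical(back$group, rec$group)
  expect_identical(back$condition, rec$condition)
  expect_identical(back$task, rec$task)
  expect_equal(back$sampling_rate_hz, rec$sampling_rate_hz)
  expect_equal(back$channels$muscle, rec$channels$muscle)
  expect_equal(back$channels$side, rec$channels$side)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("loader rejects malformed recordings", {
  rec <- make_test_recording(n_channels = 2, n = 50)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  save_recording(rec, csv, js)

  # empty CSV
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(readLines(csv)[1], empty)
  expect_error(load_recording(empty, js), "empty")

  # non-monotone time column
  df <- read.csv(csv, check.names = FALSE)
  df$time_s[10] <- df$time_s[5]
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(load_recording(bad, js), "increasing")

  # channel set mismatch vs metadata
  df <- read.csv(csv, check.names = FALSE)
  df$flexors_left <- NULL
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, bad2, row.names = FALSE)
  expect_error(load_recording(bad2, js), "channels")
})

test_that("saving refuses a recording violating its invariants", {
  rec <- make_test_recording(n_channels = 2, n = 50)
  rec$channels$muscle <- c("flexors", "flexors")
  rec$channels$side <- c("left", "left")
  csv <- withr::local_tempfile(fileext = ".csv")
  expect_error(save_recording(rec, csv, paste0(csv, ".json")), "duplicate")
  expect_false(file.exists(csv))
})

test_that("score loading computes the subtotal and enforces item ranges", {
  z <- flat_scores("s1", "off", 0L)
  expect_equal(load_scores(z)$upper_limb_subtotal, 0L)
  f <- flat_scores("s1", "off", 4L)
  expect_equal(load_scores(f)$upper_limb_subtotal, 36L)

  bad <- flat_scores("s1", "off", 2L)
  bad$item_3.4 <- 5L
  expect_error(load_scores(bad), "\\[0, 4\\]")

  neg <- flat_scores("s1", "off", 2L)
  neg$item_3.15 <- -1L
  expect_error(load_scores(neg), "\\[0, 4\\]")

  tot <- flat_scores("s1", "off", 2L)
  tot$total_part3 <- 10L    # below the subtotal of 18
  expect_error(load_scores(tot), "total_part3")

  sub <- flat_scores("s1", "off", 2L)
  sub$upper_limb_subtotal <- 7L
  expect_error(load_scores(sub), "subtotal")
})

test_that("score loading works from a CSV file with dotted column names", {
  df <- flat_scores(c("s1", "s1"), c("off", "on"), c(3L, 1L))
  df$total_part3 <- df$upper_limb_subtotal <- NULL
  df$total_part3 <- rowSums(df[, grep("^item_", names(df))]) + 5L
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, p, row.names = FALSE)
  sc <- load_scores(p)
  expect_equal(nrow(sc), 2)
  expect_equal(sc$upper_limb_subtotal, c(27L, 9L))
  expect_equal(sc$total_part3, sc$upper_limb_subtotal + 5L)
})

test_that("cohort write/load round-trips through the manifest", {
  co <- generate_cohort(tiny_sim_config(n_pd = 2, n_healthy = 2), seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort(dir)
  expect_setequal(names(back$recordings), names(co$recordings))
  id <- names(co$recordings)[1]
  expect_equal(back$recordings[[id]]$samples, co$recordings[[id]]$samples,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(nrow(back$scores), nrow(load_scores(co$scores)))

  # a missing referenced file is detected at load
  file.remove(file.path(dir, paste0(id, ".csv")))
  expect_error(load_cohort(dir), "missing")
})
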