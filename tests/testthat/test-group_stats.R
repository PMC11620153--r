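test_that("healthy-condition imputation duplicates the single measurement", {
  d <- data.frame(subject_id = c("p1", "p1", "h1"),
                  group = c("pd", "pd", "healthy"),
                  condition = c("off", "on", "na"),
                  value = c(3, 7, 5))
  long <- impute_healthy_condition(d)
  expect_equal(nrow(long), 4)
  h <- long[long$group == "healthy", ]
  expect_setequal(h$condition, c("off", "on"))
  expect_equal(h$value, c(5, 5))
  pd <- long[long$group == "pd", ]
  expect_equal(pd$value[pd$condition == "off"], 3)
  expect_equal(pd$value[pd$condition == "on"], 7)

  bad <- rbind(d, data.frame(subject_id = "h1", group = "healthy",
                             condition = "na", value = 6))
  expect_error(impute_healthy_condition(bad), "exactly one")
})

test_that("mixed ANOVA reports df1 = 1 and df2 = N - 2 for every source", {
  set.seed(21)
  d <- random_anova_data(6, 7)
  res <- mixed_anova_2x2(d)
  expect_equal(res$df1, rep(1L, 3))
  expect_equal(res$df2, rep(11L, 3))
  expect_equal(res$source, c("group", "condition", "interaction"))
  expect_true(all(res$F >= 0))
  expect_true(all(res$p > 0 & res$p <= 1))
})

test_that("a pure group shift with balanced within-subject changes gives condition F = 0", {
  subjects <- sprintf("s%d", 1:8)
  d <- expand.grid(subject_id = subjects, condition = c("off", "on"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(match(d$subject_id, subjects) <= 4, "pd", "healthy")
  base <- ifelse(d$group == "pd", 10, 0)
  # within-subject changes that cancel within each group
  delta <- ifelse(match(d$subject_id, subjects) %% 2 == 0, 1, -1)
  d$value <- base + ifelse(d$condition == "on", delta, 0)
  res <- mixed_anova_2x2(d)
  expect_equal(res$F[res$source == "condition"], 0)
  expect_equal(res$F[res$source == "interaction"], 0)
  expect_gt(res$F[res$source == "group"], 0)
})

test_that("mixed ANOVA equals the sums-of-squares oracle and aov", {
  set.seed(77)
  for (i in 1:20) {
    d <- random_anova_data(4, 4)
    got <- mixed_anova_2x2(d)
    want <- oracle_mixed_anova(d)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
  # independent cross-check against base aov strata, unbalanced groups
  d <- random_anova_data(5, 7)
  got <- mixed_anova_2x2(d)
  a <- summary(stats::aov(value ~ group * condition + Error(subject_id),
                          data = d))
  f_between <- a[["Error: subject_id"]][[1]]["group", "F value"]
  f_within <- a[["Error: Within"]][[1]][c("condition", "group:condition"),
                                        "F value"]
  expect_equal(got$F, unname(c(f_between, f_within)), tolerance = 1e-8)
})

test_that("mixed ANOVA rejects incomplete designs", {
  d <- random_anova_data(3, 3)
  expect_error(mixed_anova_2x2(d[-1, ]), "each condition")
  d2 <- d
  d2$group <- "pd"
  expect_error(mixed_anova_2x2(d2), "2 groups")
})

test_that("paired t statistic matches the closed form", {
  x_off <- c(0, 0, 0)
  x_on <- c(1, 2, 3)
  tt <- paired_t(x_off, x_on)
  expect_equal(tt$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tt$df, 2)

  # constant shift: zero-variance differences are flagged, not crashed
  dg <- paired_t(c(1, 2, 3), c(3, 4, 5))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$statistic))
  expect_false(dg$significant)

  # flipping the differences negates t and keeps p
  a <- paired_t(c(0, 0, 0, 0), c(1, 3, 2, 5))
  b <- paired_t(c(1, 3, 2, 5), c(0, 0, 0, 0))
  expect_equal(a$statistic, -b$statistic)
  expect_equal(a$p, b$p)
})

test_that("independent t is antisymmetric and matches the Welch formula", {
  x <- c(1, 2, 3)
  expect_equal(independent_t(x, x)$statistic, 0)
  expect_equal(independent_t(x, x)$p, 1)

  a <- c(1.2, 3.4, 0.8)
  b <- c(2.5, 4.1, 3.3, 5.0)
  r1 <- independent_t(a, b)
  r2 <- independent_t(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p, r2$p)

  # hand-computed Welch statistic and Welch-Satterthwaite df
  se2 <- var(a) / 3 + var(b) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 4)^2 / 3)
  expect_equal(r1$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r1$df, df_hand, tolerance = 1e-9)

  s <- independent_t(a, b, variant = "student")
  expect_equal(s$df, 5)
})

test_that("Bonferroni adjustment divides the family alpha", {
  expect_identical(bonferroni_alpha(0.05, 4), 0.0125)
  expect_identical(bonferroni_alpha(0.07, 1), 0.07)
  expect_identical(bonferroni_alpha(0.05, 5), 0.01)
  expect_error(bonferroni_alpha(0.05, 0), "m")
})

test_that("Spearman rho and exact permutation p behave correctly", {
  r <- spearman_cor(1:6, 6:1)
  expect_equal(r$rho, -1)
  expect_equal(r$p, 2 / factorial(6))   # only the two perfect orderings
  expect_equal(r$method, "exact permutation")

  # rank invariance under strictly monotone transforms
  set.seed(13)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman_cor(exp(x), y)$rho, spearman_cor(x, y)$rho)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, spearman_cor(x, y)$rho)

  # ties: average-rank rho matches cor.test's estimate
  xt <- c(1, 2, 2, 4, 7); yt <- c(3, 1, 5, 2, 9)
  expect_equal(spearman_cor(xt, yt)$rho,
               unname(cor.test(xt, yt, method = "spearman",
                               exact = FALSE)$estimate))

  # exact p equals an independent full enumeration (n = 4)
  x4 <- c(0.3, 1.2, 0.7, 2.0); y4 <- c(5, 2, 4, 1)
  obs <- spearman_cor(x4, y4)
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  rhos <- apply(perms, 1, function(p) cor(rank(x4), rank(y4)[p]))
  expect_equal(obs$p, mean(abs(rhos) >= abs(obs$rho) - 1e-12))

  # large n falls back to the t approximation
  set.seed(3)
  big <- spearman_cor(rnorm(30), rnorm(30))
  expect_equal(big$method, "t approximation")
  expect_true(big$p > 0 && big$p <= 1)
  expect_error(spearman_cor(1:2, 2:1), "3 observations")
})

test_that("delta correlation report captures constructed monotone links", {
  set.seed(41)
  n <- 6
  subs <- sprintf("p%d", 1:n)
  d_peaks <- c(30, 25, 20, 15, 10, 5)         # off - on peak change
  fo <- data.frame(subject_id = subs, n_peaks_flexors_left = 50 + d_peaks)
  fn <- data.frame(subject_id = subs, n_peaks_flexors_left = 50)
  so <- load_scores(flat_scores(subs, "off", 0L))
  so$total_part3 <- so$upper_limb_subtotal <- seq(36, 11, length.out = n)
  sn <- load_scores(flat_scores(subs, "on", 0L))
  sn$total_part3 <- sn$upper_limb_subtotal <- rep(5, n)
  # score change (off - on) increases while the peak change decreases
  so$total_part3 <- sn$total_part3 + c(1, 4, 8, 12, 16, 20)
  rep1 <- delta_correlation_report(fo, fn, so, sn, score_scope = "total")
  delta_row <- rep1[rep1$contrast == "delta", ]
  expect_equal(delta_row$rho, -1)

  # swapping OFF and ON labels negates both deltas, so the delta rho is
  # unchanged; negating only the feature delta flips its sign
  rep2 <- delta_correlation_report(fn, fo, sn, so, score_scope = "total")
  expect_equal(rep2$rho[rep2$contrast == "delta"],
               rep1$rho[rep1$contrast == "delta"])
  rep3 <- delta_correlation_report(fn, fo, so, sn, score_scope = "total")
  expect_equal(rep3$rho[rep3$contrast == "delta"],
               -rep1$rho[rep1$contrast == "delta"])
})

test_that("independent features show no spurious correlation on average", {
  set.seed(97)
  n <- 6
  subs <- sprintf("p%d", 1:n)
  score_delta <- c(20, 16, 12, 8, 4, 1)
  rhos <- replicate(200, {
    f <- sample(c(31, 27, 22, 18, 12, 7))
    spearman_cor(f, score_delta)$rho
  })
  # unbiased around zero (individual |rho| values are large at n = 6)
  expect_lt(abs(mean(rhos)), 0.2)
})
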