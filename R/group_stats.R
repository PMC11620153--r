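# Group-level statistical battery: 2x2 mixed-design ANOVA with
# healthy-condition imputation, paired/independent t tests under Bonferroni
# adjustment, and Spearman correlations with exact permutation p-values for
# small samples.

#' Duplicate healthy subjects' single measurement into both conditions
#'
#' Healthy controls are measured once (no medication state); to place them
#' in the 2x2 group-by-condition design their value is imputed into both the
#' OFF and ON cells. PD rows (one value per condition) pass through
#' unchanged.
#'
#' @param data long-format data.frame with columns `subject_id`, `group`
#'   (`"pd"`/`"healthy"`), `condition` (`"off"`/`"on"` for PD, `"na"` for
#'   healthy) and a value column.
#' @param value name of the value column (default `"value"`).
#' @return long-format data.frame where every subject has an `off` and an
#'   `on` row.
#' @export
impute_healthy_condition <- function(data, value = "value") {
  need <- c("subject_id", "group", "condition", value)
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  healthy <- data[data$group == "healthy", , drop = FALSE]
  pd <- data[data$group == "pd", , drop = FALSE]
  if (nrow(healthy)) {
    if (anyDuplicated(healthy$subject_id))
      stop("healthy subjects must have exactly one measurement")
    off <- healthy; off$condition <- "off"
    on <- healthy; on$condition <- "on"
    healthy <- rbind(off, on)
  }
  out <- rbind(pd, healthy)
  rownames(out) <- NULL
  out
}

#' Two-way mixed-design ANOVA for the 2x2 group-by-condition layout
#'
#' Classical univariate partition with subjects nested in group: the
#' between-subject error (subjects within groups, df = N - 2) tests the
#' group effect; the within-subject error (condition-by-subject within
#' groups, df = N - 2) tests the condition effect and the interaction. All
#' three sources have df1 = 1 in the 2x2 design. Group sizes may differ.
#'
#' @param data long-format data.frame with columns `subject_id`, `group` (2
#'   levels), `condition` (2 levels) and a value column; every subject needs
#'   exactly one value per condition.
#' @param value name of the value column (default `"value"`).
#' @return data.frame with rows `group`, `condition`, `interaction` and
#'   columns `source`, `df1`, `df2`, `F`, `p`.
#' @export
mixed_anova_2x2 <- function(data, value = "value") {
  g_lv <- sort(unique(data$group))
  c_lv <- sort(unique(data$condition))
  if (length(g_lv) != 2L || length(c_lv) != 2L)
    stop("need exactly 2 groups and 2 conditions")
  y <- data[[value]]
  if (anyNA(y)) stop("missing values in the response")
  subj <- as.character(data$subject_id)
  key <- paste(subj, data$condition)
  if (anyDuplicated(key))
    stop("more than one value per (subject, condition) cell")
  subjects <- unique(subj)
  n_subj <- length(subjects)
  sg <- data$group[match(subjects, subj)]
  if (any(table(subj) != 2L))
    stop("every subject needs one value in each condition")

  y1 <- y[data$condition == c_lv[1]][match(subjects, subj[data$condition == c_lv[1]])]
  y2 <- y[data$condition == c_lv[2]][match(subjects, subj[data$condition == c_lv[2]])]
  m_s <- (y1 + y2) / 2            # subject means
  z_s <- (y2 - y1) / 2            # subject half-differences
  gm <- mean(m_s)
  n_g <- as.numeric(table(factor(sg, levels = g_lv)))
  if (any(n_g < 2)) stop("each group needs at least 2 subjects")
  g_mean <- tapply(m_s, factor(sg, levels = g_lv), mean)
  z_mean <- tapply(z_s, factor(sg, levels = g_lv), mean)
  z_bar <- mean(z_s)

  ss_group <- 2 * sum(n_g * (g_mean - gm)^2)
  ss_subj_w <- 2 * sum((m_s - g_mean[match(sg, g_lv)])^2)
  ss_cond <- 2 * n_subj * z_bar^2
  ss_int <- 2 * sum(n_g * (z_mean - z_bar)^2)
  ss_err_w <- 2 * sum((z_s - z_mean[match(sg, g_lv)])^2)

  df2 <- n_subj - 2L
  ms_bw <- ss_subj_w / df2
  ms_ww <- ss_err_w / df2
  f <- c(group = ss_group / ms_bw, condition = ss_cond / ms_ww,
         interaction = ss_int / ms_ww)
  data.frame(source = c("group", "condition", "interaction"),
             df1 = 1L, df2 = df2, F = as.numeric(f),
             p = pf(as.numeric(f), 1, df2, lower.tail = FALSE),
             row.names = NULL)
}

#' Paired t test for the OFF vs ON within-subject comparison
#'
#' Two-sided t on the differences `x_on - x_off`, df = n - 1. Degenerate
#' zero-variance differences yield `NA` statistics with `degenerate = TRUE`.
#'
#' @param x_off,x_on paired numeric vectors (same subjects, same order).
#' @param alpha_adjusted significance threshold (default 0.0125, the
#'   Bonferroni-adjusted level for four muscle-group comparisons).
#' @return list of class `test_result`: `statistic`, `df`, `p`,
#'   `alpha_adjusted`, `significant`, `degenerate`.
#' @export
paired_t <- function(x_off, x_on, alpha_adjusted = 0.0125) {
  if (length(x_off) != length(x_on)) stop("paired vectors differ in length")
  if (length(x_off) < 2L) stop("need at least 2 pairs")
  d <- x_on - x_off
  if (sd(d) == 0) {
    return(structure(list(statistic = NA_real_, df = length(d) - 1L,
                          p = NA_real_, alpha_adjusted = alpha_adjusted,
                          significant = FALSE, degenerate = TRUE),
                     class = "test_result"))
  }
  tt <- t.test(x_on, x_off, paired = TRUE)
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, alpha_adjusted = alpha_adjusted,
                 significant = tt$p.value < alpha_adjusted,
                 degenerate = FALSE),
            class = "test_result")
}

#' Independent-samples t test (Welch by default)
#'
#' Two-sided comparison of two groups; Welch-Satterthwaite df by default,
#' Student's pooled-variance variant available.
#'
#' @param x_a,x_b numeric vectors, each of length >= 2.
#' @param variant `"welch"` (default) or `"student"`.
#' @param alpha_adjusted significance threshold (default 0.0125).
#' @return a `test_result` (see [paired_t()]).
#' @export
independent_t <- function(x_a, x_b, variant = c("welch", "student"),
                          alpha_adjusted = 0.0125) {
  variant <- match.arg(variant)
  if (length(x_a) < 2L || length(x_b) < 2L)
    stop("each group needs at least 2 values")
  if (sd(x_a) == 0 && sd(x_b) == 0 && x_a[1] == x_b[1]) {
    return(structure(list(statistic = NA_real_, df = NA_real_, p = NA_real_,
                          alpha_adjusted = alpha_adjusted,
                          significant = FALSE, degenerate = TRUE),
                     class = "test_result"))
  }
  tt <- t.test(x_a, x_b, var.equal = variant == "student")
  structure(list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, alpha_adjusted = alpha_adjusted,
                 significant = tt$p.value < alpha_adjusted,
                 degenerate = FALSE),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g (alpha = %g)%s\n",
              x$statistic, x$df, x$p, x$alpha_adjusted,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Bonferroni-adjusted per-comparison alpha
#'
#' With four muscle-group channels per family this gives the 0.05/4 = 0.0125
#' threshold used throughout the battery.
#'
#' @param family_alpha family-wise error rate (default 0.05).
#' @param m number of comparisons in the family (>= 1).
#' @return `family_alpha / m`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1")
  family_alpha / m
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    q <- p
    q[q >= k] <- q[q >= k] + 1L
    cbind(rep(k, nrow(q)), q, deparse.level = 0)
  }))
}

#' Spearman rank correlation with small-sample exact permutation p-value
#'
#' rho is the Pearson correlation of average (mid) ranks, so ties are
#' handled. For n <= `exact_n_max` the two-sided p-value is computed by full
#' enumeration of all n! permutations of one variable (the t-approximation
#' is unreliable at the n = 6 sample sizes typical here); larger n use the
#' t-approximation.
#'
#' @param x,y numeric vectors, length >= 3.
#' @param exact_n_max largest n for exact enumeration (default 8).
#' @return list of class `correlation_result`: `rho`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, exact_n_max = 8L) {
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length")
  if (n < 3L) stop("need at least 3 observations")
  rx <- rank(x)
  ry <- rank(y)
  rxc <- rx - mean(rx)
  ryc <- ry - mean(ry)
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  if (denom == 0) stop("a variable has zero rank variance")
  rho <- sum(rxc * ryc) / denom
  if (n <= exact_n_max) {
    P <- all_permutations(n)
    M <- matrix(ryc[P], nrow = nrow(P))
    rho_all <- as.numeric(M %*% rxc) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
    p <- min(1, p)
    method <- "t approximation"
  }
  structure(list(rho = rho, p = p, n = n, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("rho = %.4g, p = %.4g (n = %d, %s)\n",
              x$rho, x$p, x$n, x$method))
  invisible(x)
}

#' Spearman correlations between burst-feature changes and score changes
#'
#' For every feature column: the correlation between the OFF-minus-ON
#' feature difference and the OFF-minus-ON score difference, plus the
#' per-condition correlations (OFF features vs OFF scores, ON vs ON), for
#' the total Part-III score and/or the upper-limb subtotal.
#'
#' @param features_off,features_on data.frames with a `subject_id` column
#'   and numeric feature columns (e.g. `n_peaks_<channel>`), one row per
#'   subject, same subject set in both.
#' @param scores_off,scores_on data.frames with `subject_id`,
#'   `total_part3`, `upper_limb_subtotal` (as from [load_scores()]).
#' @param score_scope `"total"`, `"upper_limb"`, or both (default).
#' @return data.frame with columns `feature`, `contrast`
#'   (`delta`/`off`/`on`), `scope`, `rho`, `p`, `n`.
#' @export
delta_correlation_report <- function(features_off, features_on,
                                     scores_off, scores_on,
                                     score_scope = c("total", "upper_limb")) {
  score_scope <- match.arg(score_scope, several.ok = TRUE)
  subs <- features_off$subject_id
  if (!setequal(subs, features_on$subject_id))
    stop("OFF and ON feature tables cover different subjects")
  fo <- features_off[match(subs, features_off$subject_id), , drop = FALSE]
  fn <- features_on[match(subs, features_on$subject_id), , drop = FALSE]
  so <- scores_off[match(subs, scores_off$subject_id), , drop = FALSE]
  sn <- scores_on[match(subs, scores_on$subject_id), , drop = FALSE]
  if (anyNA(so$subject_id) || anyNA(sn$subject_id))
    stop("scores missing for some subjects")
  cols <- setdiff(names(fo), "subject_id")
  cols <- cols[vapply(fo[cols], is.numeric, logical(1))]
  score_col <- c(total = "total_part3", upper_limb = "upper_limb_subtotal")
  out <- list()
  for (scope in score_scope) {
    s_off <- so[[score_col[[scope]]]]
    s_on <- sn[[score_col[[scope]]]]
    for (cl in cols) {
      trip <- list(delta = list(f = fo[[cl]] - fn[[cl]], s = s_off - s_on),
                   off = list(f = fo[[cl]], s = s_off),
                   on = list(f = fn[[cl]], s = s_on))
      for (ct in names(trip)) {
        r <- tryCatch(spearman_cor(trip[[ct]]$f, trip[[ct]]$s),
                      error = function(e) NULL)
        out[[length(out) + 1L]] <- data.frame(
          feature = cl, contrast = ct, scope = scope,
          rho = if (is.null(r)) NA_real_ else r$rho,
          p = if (is.null(r)) NA_real_ else r$p,
          n = length(subs))
      }
    }
  }
  do.call(rbind, out)
}
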