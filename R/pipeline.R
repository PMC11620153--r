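# End-to-end orchestration: one configuration drives simulation (or manifest
# loading), preprocessing, burst metrics, the statistical battery and the
# model comparison, writing a reproducible report bundle.

#' Pipeline run configuration
#'
#' @param output_dir directory for the report bundle CSV/JSON files, or
#'   `NULL` to keep results in memory only.
#' @param seed root seed for every stochastic stage (default 42).
#' @param sim a [sim_config()] used when no manifest is given.
#' @param manifest_dir directory holding a cohort written by
#'   [write_cohort()]; overrides simulation when non-`NULL`.
#' @param preproc a [preprocess_params()].
#' @param window a [window_spec()].
#' @param features a [feature_params()].
#' @param rel_threshold relative prominence threshold (default 0.1).
#' @param ntree random-forest size (default 100).
#' @param family_alpha family-wise alpha (default 0.05).
#' @param n_comparisons Bonferroni family size (default 4, the four
#'   muscle-group channels).
#' @return a `run_config` list (validated).
#' @export
run_config <- function(output_dir = NULL, seed = 42, sim = sim_config(),
                       manifest_dir = NULL, preproc = preprocess_params(),
                       window = window_spec(), features = feature_params(),
                       rel_threshold = 0.1, ntree = 100,
                       family_alpha = 0.05, n_comparisons = 4) {
  stopifnot(inherits(sim, "sim_config"), inherits(preproc, "preprocess_params"),
            inherits(window, "window_spec"), inherits(features, "feature_params"))
  if (rel_threshold <= 0) stop("rel_threshold must be positive")
  if (ntree < 1) stop("ntree must be >= 1")
  structure(list(output_dir = output_dir, seed = seed, sim = sim,
                 manifest_dir = manifest_dir, preproc = preproc,
                 window = window, features = features,
                 rel_threshold = rel_threshold, ntree = ntree,
                 family_alpha = family_alpha,
                 n_comparisons = n_comparisons),
            class = "run_config")
}

check_cohort_complete <- function(cohort) {
  man <- cohort$manifest
  tasks <- unique(man$task)
  pd <- unique(man$subject_id[man$group == "pd"])
  for (s in pd) for (tk in tasks) for (cond in c("off", "on")) {
    hit <- man$subject_id == s & man$task == tk & man$condition == cond
    if (!any(hit))
      stop("cohort incomplete: subject ", s, " lacks the ", cond,
           " recording for task ", tk)
  }
  invisible(TRUE)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) a cohort, computes burst metrics per channel, runs
#' the mixed-ANOVA / post-hoc / correlation battery per task, feature
#' channel and metric, fits the standard and extended LOSO models per task,
#' and optionally writes everything as CSV/JSON with a provenance record.
#'
#' @param config a [run_config()].
#' @return list of class `emg_report_bundle`: `burst` (per-recording burst
#'   metrics), `anova`, `posthoc`, `correlations`, `model`, `alpha`,
#'   `provenance`.
#' @export
run_all <- function(config = run_config()) {
  cohort <- if (!is.null(config$manifest_dir)) load_cohort(config$manifest_dir)
            else generate_cohort(config$sim, seed = config$seed)
  check_cohort_complete(cohort)
  burst <- cohort_burst_features(cohort, config$preproc, config$rel_threshold)
  alpha <- bonferroni_alpha(config$family_alpha, config$n_comparisons)
  tasks <- unique(burst$task)
  channels <- unique(burst$channel)
  metrics <- c("n_peaks", "median_amp_mv", "mean_ipi_s")

  anova_rows <- list()
  posthoc_rows <- list()
  for (tk in tasks) for (ch in channels) for (mt in metrics) {
    d <- burst[burst$task == tk & burst$channel == ch,
               c("subject_id", "group", "condition", mt)]
    names(d)[4] <- "value"
    if (anyNA(d$value)) next
    long <- impute_healthy_condition(d)
    av <- mixed_anova_2x2(long)
    av$task <- tk; av$channel <- ch; av$metric <- mt
    av$alpha_adjusted <- alpha
    anova_rows[[length(anova_rows) + 1L]] <- av

    pd_off <- d$value[d$group == "pd" & d$condition == "off"][
      order(d$subject_id[d$group == "pd" & d$condition == "off"])]
    pd_on <- d$value[d$group == "pd" & d$condition == "on"][
      order(d$subject_id[d$group == "pd" & d$condition == "on"])]
    hc <- d$value[d$group == "healthy"]
    tests <- list(off_vs_on = paired_t(pd_off, pd_on, alpha),
                  off_vs_healthy = independent_t(pd_off, hc, alpha_adjusted = alpha),
                  on_vs_healthy = independent_t(pd_on, hc, alpha_adjusted = alpha))
    for (nm in names(tests)) {
      tt <- tests[[nm]]
      posthoc_rows[[length(posthoc_rows) + 1L]] <-
        data.frame(task = tk, channel = ch, metric = mt, comparison = nm,
                   statistic = tt$statistic, df = tt$df, p = tt$p,
                   alpha_adjusted = alpha, significant = tt$significant)
    }
  }
  anova_tab <- do.call(rbind, anova_rows)
  posthoc_tab <- do.call(rbind, posthoc_rows)

  corr_rows <- list()
  model_rows <- list()
  if (!is.null(cohort$scores)) {
    scores <- load_scores(cohort$scores)
    for (tk in tasks) {
      b <- burst[burst$task == tk & burst$group == "pd", ]
      wide <- function(cond, mt) {
        d <- b[b$condition == cond, c("subject_id", "channel", mt)]
        out <- data.frame(subject_id = unique(d$subject_id))
        for (ch in channels)
          out[[paste(mt, ch, sep = "_")]] <-
            d[[mt]][match(paste(out$subject_id, ch),
                          paste(d$subject_id, d$channel))]
        out
      }
      for (mt in c("n_peaks", "mean_ipi_s")) {
        fo <- wide("off", mt); fn <- wide("on", mt)
        cr <- delta_correlation_report(
          fo, fn, scores[scores$condition == "off", ],
          scores[scores$condition == "on", ])
        cr$task <- tk; cr$alpha_adjusted <- alpha
        corr_rows[[length(corr_rows) + 1L]] <- cr
      }
    }

    pd_recs <- cohort$recordings[cohort$manifest$recording_id[
      cohort$manifest$group == "pd"]]
    tab_s <- build_feature_table(pd_recs, config$preproc, config$window,
                                 config$features, "standard",
                                 rel_threshold = config$rel_threshold)
    tab_e <- build_feature_table(pd_recs, config$preproc, config$window,
                                 config$features, "extended",
                                 rel_threshold = config$rel_threshold)
    model_rows[[1]] <- compare_models(tab_s, tab_e, scores,
                                      ntree = config$ntree,
                                      seed = config$seed)
  }
  corr_tab <- if (length(corr_rows)) do.call(rbind, corr_rows) else NULL
  model_tab <- if (length(model_rows)) model_rows[[1]] else NULL

  provenance <- list(seed = config$seed,
                     rel_threshold = config$rel_threshold,
                     ntree = config$ntree, family_alpha = config$family_alpha,
                     n_comparisons = config$n_comparisons,
                     alpha_adjusted = alpha,
                     r_version = as.character(getRversion()),
                     package_version =
                       as.character(utils::packageVersion("bradyemg")))

  bundle <- structure(list(burst = burst, anova = anova_tab,
                           posthoc = posthoc_tab, correlations = corr_tab,
                           model = model_tab, alpha = alpha,
                           provenance = provenance),
                      class = "emg_report_bundle")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) if (!is.null(x))
      write.csv(x, file.path(config$output_dir, f), row.names = FALSE)
    wr(burst, "burst_metrics.csv")
    wr(anova_tab, "anova.csv")
    wr(posthoc_tab, "posthoc.csv")
    wr(corr_tab, "correlations.csv")
    wr(model_tab, "model_comparison.csv")
    if (!is.null(model_tab))
      wr(attr(model_tab, "predictions"),
         "model_predictions.csv")
    jsonlite::write_json(provenance,
                         file.path(config$output_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

#' Render a human-readable summary of a report bundle
#'
#' Lists the ANOVA sources, post-hoc comparisons and correlations with
#' significance flags at the Bonferroni-adjusted alpha, and the model
#' comparison per task. An empty bundle yields a single "no results" line
#' with attribute `status = "empty"`.
#'
#' @param bundle an `emg_report_bundle` from [run_all()].
#' @return character vector of report lines (invisibly printable); attribute
#'   `status` is `"ok"` or `"empty"`.
#' @export
report_bundle <- function(bundle) {
  if (is.null(bundle$anova) || !nrow(bundle$anova)) {
    out <- "no results"
    attr(out, "status") <- "empty"
    return(out)
  }
  flag <- function(p) ifelse(!is.na(p) & p < bundle$alpha, " *", "")
  lines <- c(sprintf("Bonferroni-adjusted alpha: %g", bundle$alpha),
             "", "Mixed 2x2 ANOVA:")
  a <- bundle$anova
  lines <- c(lines, sprintf(
    "  %s | %s | %s | %s: F(%d,%d) = %.2f, p = %.4g%s",
    a$task, a$channel, a$metric, a$source, a$df1, a$df2, a$F, a$p, flag(a$p)))
  ph <- bundle$posthoc
  lines <- c(lines, "", "Post-hoc t tests:",
             sprintf("  %s | %s | %s | %s: t = %.2f, p = %.4g%s",
                     ph$task, ph$channel, ph$metric, ph$comparison,
                     ph$statistic, ph$p, flag(ph$p)))
  if (!is.null(bundle$correlations)) {
    cr <- bundle$correlations
    lines <- c(lines, "", "Spearman correlations (features vs scores):",
               sprintf("  %s | %s | %s | %s: rho = %.2f, p = %.4g%s",
                       cr$task, cr$feature, cr$contrast, cr$scope,
                       cr$rho, cr$p, flag(cr$p)))
  }
  if (!is.null(bundle$model)) {
    m <- bundle$model
    lines <- c(lines, "", "LOSO model comparison (pooled r):",
               sprintf("  %s: standard %.3f, extended %.3f (delta %+.3f)",
                       m$task, m$r_standard, m$r_extended, m$delta_r))
  }
  attr(lines, "status") <- "ok"
  lines
}

#' @export
print.emg_report_bundle <- function(x, ...) {
  cat(report_bundle(x), sep = "\n")
  invisible(x)
}
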