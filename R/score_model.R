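# Leave-one-subject-out random-forest regression of clinical scores from
# feature tables, and the standard-vs-extended model comparison.

#' Leave-one-subject-out folds
#'
#' One fold per subject; each fold's test set is all of that subject's rows
#' (both medication conditions), the training set is everyone else.
#'
#' @param subjects character vector of subject ids (duplicates allowed;
#'   folds are over the unique set, in order of first appearance).
#' @return list of folds, each `list(test_subject = <id>)`.
#' @export
make_loso_folds <- function(subjects) {
  u <- unique(as.character(subjects))
  if (length(u) < 2L) stop("need at least 2 subjects")
  lapply(u, function(s) list(test_subject = s))
}

#' Run leave-one-subject-out random-forest regression
#'
#' For each fold, standardization is fitted on the training rows only and
#' applied to the held-out rows, then a random forest is trained on the
#' training rows and used to predict the held-out scores. Predictions from
#' all folds are pooled.
#'
#' @param table feature table ([build_feature_table()]); one row per
#'   (subject, condition), a single task.
#' @param scores score table ([load_scores()]) covering every table row.
#' @param target score column to predict (default `"total_part3"`).
#' @param ntree number of trees (default 100).
#' @param seed integer seed; each fold reseeds deterministically from it.
#' @return data.frame of class `cv_predictions`: `subject_id`, `condition`,
#'   `task`, `true`, `predicted`, `fold`; model configuration in the
#'   `config` attribute.
#' @export
run_loso <- function(table, scores, target = "total_part3", ntree = 100,
                     seed = 42) {
  key_t <- paste(table$subject_id, table$condition)
  key_s <- paste(scores$subject_id, scores$condition)
  hit <- match(key_t, key_s)
  if (anyNA(hit))
    stop("missing score for row(s): ", paste(key_t[is.na(hit)], collapse = "; "))
  y <- scores[[target]][hit]
  if (is.null(y)) stop("unknown target column: ", target)
  folds <- make_loso_folds(table$subject_id)
  cols <- feature_columns(table)
  preds <- rep(NA_real_, nrow(table))
  fold_id <- rep(NA_integer_, nrow(table))
  for (k in seq_along(folds)) {
    test <- which(table$subject_id == folds[[k]]$test_subject)
    train <- setdiff(seq_len(nrow(table)), test)
    std <- suppressWarnings(standardize_features(table, fit_rows = train))
    x <- as.matrix(std[, cols, drop = FALSE])
    set.seed(seed + k)
    fit <- randomForest::randomForest(x[train, , drop = FALSE], y[train],
                                      ntree = ntree)
    preds[test] <- predict(fit, x[test, , drop = FALSE])
    fold_id[test] <- k
  }
  out <- data.frame(subject_id = table$subject_id,
                    condition = table$condition,
                    task = if ("task" %in% names(table)) table$task else NA,
                    true = y, predicted = preds, fold = fold_id)
  attr(out, "config") <- list(target = target, ntree = ntree, seed = seed)
  class(out) <- c("cv_predictions", "data.frame")
  out
}

#' Pooled correlation between predicted and true scores
#'
#' @param preds a `cv_predictions` data.frame from [run_loso()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation coefficient in \[-1, 1\] (`NA` with a warning when a
#'   side has zero variance).
#' @export
evaluate_predictions <- function(preds, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(preds) < 3L) stop("need at least 3 prediction pairs")
  if (sd(preds$true) == 0 || sd(preds$predicted) == 0) {
    warning("zero variance in predictions or truth; correlation undefined")
    return(NA_real_)
  }
  cor(preds$predicted, preds$true, method = method)
}

#' Compare the standard and extended feature models
#'
#' Runs the same leave-one-subject-out regression on both feature tables
#' (same rows, same seed, so the comparison is paired) and reports the
#' pooled correlations per task.
#'
#' @param table_standard,table_extended feature tables with identical
#'   (subject, condition, task) rows.
#' @param scores score table covering every row.
#' @param target score column (default `"total_part3"`).
#' @param ntree trees per forest (default 100).
#' @param seed integer seed (default 42).
#' @param method correlation type (default `"pearson"`).
#' @return data.frame with one row per task: `task`, `r_standard`,
#'   `r_extended`, `delta_r`; pooled predictions for both models in the
#'   `predictions` attribute.
#' @export
compare_models <- function(table_standard, table_extended, scores,
                           target = "total_part3", ntree = 100, seed = 42,
                           method = "pearson") {
  id <- function(tb) paste(tb$subject_id, tb$condition, tb$task)
  if (!identical(id(table_standard), id(table_extended)))
    stop("the two tables must index identical rows")
  tasks <- unique(table_standard$task)
  rows <- list()
  pred_all <- list()
  for (tk in tasks) {
    sel <- table_standard$task == tk
    p_s <- run_loso(table_standard[sel, , drop = FALSE], scores, target,
                    ntree, seed)
    p_e <- run_loso(table_extended[sel, , drop = FALSE], scores, target,
                    ntree, seed)
    r_s <- evaluate_predictions(p_s, method)
    r_e <- evaluate_predictions(p_e, method)
    rows[[tk]] <- data.frame(task = tk, r_standard = r_s, r_extended = r_e,
                             delta_r = r_e - r_s)
    p_s$feature_set <- "standard"
    p_e$feature_set <- "extended"
    pred_all[[tk]] <- rbind(as.data.frame(p_s), as.data.frame(p_e))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "predictions") <- do.call(rbind, pred_all)
  out
}
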