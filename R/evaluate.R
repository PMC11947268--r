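#' Confusion counts for binary predictions
#'
#' The positive class is MT (label 1).
#'
#' @param truth Integer 0/1 true labels.
#' @param predicted Integer 0/1 predicted labels.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  structure(list(TP = sum(truth == 1 & predicted == 1),
                 TN = sum(truth == 0 & predicted == 0),
                 FP = sum(truth == 0 & predicted == 1),
                 FN = sum(truth == 1 & predicted == 0)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = 2 TP / (2 TP + FP + FN) (the harmonic mean of
#' precision and recall). A degenerate denominator (no predicted positives,
#' or no true positives in the data) yields 0 for the affected metric, with
#' a warning, so all metrics stay bounded in [0, 1].
#'
#' @param counts A [confusion_counts()] object (or list with TP/TN/FP/FN).
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("no evaluated epochs")
  accuracy <- (TP + TN) / total
  if (TP + FP == 0) {
    warning("no predicted positives: precision set to 0")
    precision <- 0
  } else precision <- TP / (TP + FP)
  if (TP + FN == 0) {
    warning("no positive examples: recall set to 0")
    recall <- 0
  } else recall <- TP / (TP + FN)
  f1 <- if (precision + recall == 0) 0 else 2 * TP / (2 * TP + FP + FN)
  list(accuracy = accuracy, precision = precision, recall = recall, f1 = f1)
}

#' Summarize per-fold metrics with Avg and Std rows
#'
#' Appends the arithmetic mean and the sample standard deviation
#' (denominator n - 1) of every numeric column — the convention that
#' reproduces the published fold tables.
#'
#' @param df Data frame of per-fold metric rows (column `fold` plus metrics).
#' @return Data frame with `Avg.` and `Std.` rows appended.
#' @export
summarize_folds <- function(df) {
  num <- vapply(df, is.numeric, TRUE) & names(df) != "fold"
  avg <- df[1, , drop = FALSE]
  std <- df[1, , drop = FALSE]
  avg[] <- NA; std[] <- NA
  for (cn in names(df)[num]) {
    avg[[cn]] <- mean(df[[cn]])
    std[[cn]] <- stats::sd(df[[cn]])
  }
  avg$fold <- "Avg."
  std$fold <- "Std."
  df$fold <- as.character(df$fold)
  rbind(df, avg, std)
}

# Fit one fold: standardize (optionally), train, evaluate on the test fold.
run_fold <- function(epochs, train_ids, test_ids, spec, cfg, fold_seed) {
  tr <- subset_epochs(epochs, epochs$subject_ids %in% train_ids)
  te <- subset_epochs(epochs, epochs$subject_ids %in% test_ids)
  if (cfg$standardize) {
    st <- standardize_epochs(tr, list(te))
    tr <- st$train
    te <- st$others[[1]]
  }
  model <- build_model(spec, dim(tr$epochs)[2], dim(tr$epochs)[3],
                       seed = fold_seed)
  cfg$seed <- fold_seed
  t0 <- proc.time()[3]
  model <- train_model(model, tr, te, cfg)
  wall <- proc.time()[3] - t0
  pr <- predict(model, te)
  m <- compute_metrics(confusion_counts(te$labels, pr$labels))
  eps <- 1e-12
  loss <- -mean(te$labels * log(pmax(pr$probabilities, eps)) +
                  (1 - te$labels) * log(pmax(1 - pr$probabilities, eps)))
  list(metrics = data.frame(accuracy = m$accuracy, loss = loss, f1 = m$f1,
                            precision = m$precision, recall = m$recall,
                            wall_s = wall),
       model = model)
}

#' Run subject-grouped cross-validation
#'
#' For every fold of `plan`: train `spec` on the training subjects' epochs,
#' evaluate on the held-out subjects' epochs, and record accuracy, test loss
#' (mean binary cross-entropy), F1, precision and recall; `Avg.` and `Std.`
#' rows are appended. Input is either a list of preprocessed recordings (each
#' is segmented) or an `epoch_set`.
#'
#' @param cohort List of preprocessed `eeg_recording`s, or an `epoch_set`.
#' @param plan A `fold_plan` covering the cohort's subjects.
#' @param spec An [architecture_spec()].
#' @param cfg A [train_config()].
#' @param subset Channel subset passed to [select_channels()].
#' @param keep_models Keep the per-fold trained models (default FALSE).
#' @return A `metrics_report`: list with `table` (fold rows + Avg/Std),
#'   `scheme`, and optionally `models`.
#' @export
run_cv <- function(cohort, plan, spec, cfg = train_config(), subset = "COGN-26",
                   keep_models = FALSE) {
  epochs <- if (inherits(cohort, "epoch_set")) cohort else
    bind_epoch_sets(lapply(cohort, segment_epochs))
  epochs <- select_channels(epochs, subset)
  covered <- unique(epochs$subject_ids)
  plan_subj <- unique(unlist(lapply(plan$folds, function(f) c(f$train, f$test))))
  if (!setequal(covered, plan_subj)) {
    stop("fold plan does not match the cohort's subjects")
  }
  rows <- list(); models <- list()
  for (i in seq_along(plan$folds)) {
    f <- plan$folds[[i]]
    res <- run_fold(epochs, f$train, f$test, spec, cfg,
                    fold_seed = derive_seed(cfg$seed, i))
    rows[[i]] <- cbind(data.frame(fold = i), res$metrics)
    if (keep_models) models[[i]] <- res$model
  }
  tab <- summarize_folds(do.call(rbind, rows))
  structure(list(table = tab, scheme = plan$scheme, family = spec$family,
                 subset = if (length(subset) == 1) subset else "custom",
                 models = if (keep_models) models),
            class = "metrics_report")
}

#' Run leave-one-subject-out cross-validation
#'
#' One fold per subject (the held-out subject's 120 epochs form the test
#' set); otherwise identical to [run_cv()].
#'
#' @inheritParams run_cv
#' @return A `metrics_report` with one row per subject plus Avg/Std.
#' @export
run_loso <- function(cohort, spec, cfg = train_config(), subset = "COGN-26",
                     keep_models = FALSE) {
  epochs <- if (inherits(cohort, "epoch_set")) cohort else
    bind_epoch_sets(lapply(cohort, segment_epochs))
  plan <- make_loso_folds(unique(epochs$subject_ids))
  run_cv(epochs, plan, spec, cfg, subset, keep_models)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s / %s / %s\n", x$family, x$scheme, x$subset))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report to CSV
#'
#' @param report A `metrics_report`.
#' @param path Output CSV path.
#' @export
write_metrics_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE)
  invisible(path)
}
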