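#' Train the classifier on a labeled Ct cohort
#'
#' Runs the full training pipeline: triplicate QC, score computation,
#' Gaussian class-conditional fitting, threshold solving at `odds_level`,
#' classification of the training samples, and the training confusion
#' table with its metrics.
#'
#' @param table A raw Ct table with `class` labels (see
#'   [simulate_cohort()] / [read_ct_table()]).
#' @param params A [qc_params()].
#' @param score A [score_spec()]; default the miR375 score.
#' @param class_a,class_b The binary class labels (low- and high-score).
#' @param priors Prior mode passed to [fit_gaussian_classifier()].
#' @param odds_level Odds defining the strong-call thresholds.
#' @param score_outliers Score and classify QC-flagged samples (marked
#'   `qc_outlier = TRUE`) instead of excluding them.
#'
#' @return An object of class `ct_run` with elements `mode`, `qc`,
#'   `scores`, `model`, `thresholds`, `calls`, `confusion`, `metrics`,
#'   `config`.
#' @examples
#' run <- run_train(simulate_cohort(cohort_spec(seed = 4)))
#' run$metrics$accuracy_all
#' @export
run_train <- function(table, params = qc_params(), score = score_dct375(),
                      class_a = "nonNE", class_b = "NE", priors = "equal",
                      odds_level = 9, score_outliers = FALSE) {
  validate_ct_table(table)
  if (!("class" %in% names(table)) || any(is.na(table$class))) {
    stop_config("Training requires a fully labeled `class` column.")
  }
  qc <- qc_cohort(table, params)
  scores <- score_table(qc, score, score_outliers = score_outliers)
  model <- fit_gaussian_classifier(scores, class_a = class_a,
                                   class_b = class_b, priors = priors)
  thresholds <- solve_thresholds(model, odds_level = odds_level)
  calls <- classify_samples(scores, thresholds, model = model)
  confusion <- confusion_table(calls)
  metrics <- classification_metrics(confusion)
  structure(
    list(mode = "train", qc = qc, scores = scores, model = model,
         thresholds = thresholds, calls = calls, confusion = confusion,
         metrics = metrics,
         config = list(score = score$name, priors = priors,
                       odds_level = odds_level,
                       score_outliers = score_outliers)),
    class = "ct_run"
  )
}

#' Validate fixed thresholds on an independent labeled cohort
#'
#' No refitting: the supplied thresholds (and optionally the training
#' model, for posterior odds) are applied to a new labeled cohort, and the
#' confusion table, metrics, separation t-test, and empirical ROC/AUC are
#' computed.
#'
#' @inheritParams run_train
#' @param thresholds A [threshold_set()] — from [run_train()]'s result,
#'   [read_thresholds_json()], or [reference_thresholds()].
#' @param model Optional `gaussian_class_model` for posterior odds.
#' @return A `ct_run` with additional elements `roc` and `t_test`.
#' @export
run_validate <- function(table, thresholds, model = NULL,
                         params = qc_params(), score = score_dct375(),
                         class_b = "NE", score_outliers = TRUE) {
  validate_ct_table(table)
  if (!inherits(thresholds, "threshold_set")) {
    stop_config("`thresholds` (a threshold_set) are required for validation.")
  }
  qc <- qc_cohort(table, params)
  scores <- score_table(qc, score, score_outliers = score_outliers)
  calls <- classify_samples(scores, thresholds, model = model)
  confusion <- confusion_table(calls)
  metrics <- classification_metrics(confusion)
  roc <- empirical_roc(scores, positive = class_b)
  ttest <- separation_t_test(scores)
  structure(
    list(mode = "validate", qc = qc, scores = scores, model = model,
         thresholds = thresholds, calls = calls, confusion = confusion,
         metrics = metrics, roc = roc, t_test = ttest,
         config = list(score = score$name,
                       odds_level = thresholds$odds_level,
                       score_outliers = score_outliers)),
    class = "ct_run"
  )
}

#' Classify an unlabeled (or out-of-scope) cohort
#'
#' Classify-only mode for samples without usable binary labels — e.g.
#' high-grade neuroendocrine tumors (LCNEC, SCLC) that the two-class
#' thresholds were never trained on. No metrics are computed; instead the
#' per-box fraction of samples summarizes how the cohort disperses over
#' the decision boxes.
#'
#' @inheritParams run_validate
#' @return A `ct_run` with `calls` and `box_fractions` (tibble `box`,
#'   `n`, `fraction`; fractions sum to 1) and no metrics.
#' @export
run_classify <- function(table, thresholds, model = NULL,
                         params = qc_params(), score = score_dct375(),
                         score_outliers = TRUE) {
  validate_ct_table(table)
  if (!inherits(thresholds, "threshold_set")) {
    stop_config("`thresholds` (a threshold_set) are required to classify.")
  }
  qc <- qc_cohort(table, params)
  scores <- score_table(qc, score, score_outliers = score_outliers)
  calls <- classify_samples(scores, thresholds, model = model)
  fractions <- calls |>
    dplyr::count(.data$box, .drop = FALSE) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  structure(
    list(mode = "classify", qc = qc, scores = scores, model = model,
         thresholds = thresholds, calls = calls, box_fractions = fractions,
         config = list(score = score$name,
                       odds_level = thresholds$odds_level,
                       score_outliers = score_outliers)),
    class = "ct_run"
  )
}

#' @export
print.ct_run <- function(x, ...) {
  cat(sprintf("<ct_run:%s> %d samples scored (%s)\n", x$mode,
              nrow(x$calls), x$config$score))
  if (!is.null(x$thresholds)) print(x$thresholds)
  if (!is.null(x$metrics)) {
    cat(sprintf("  accuracy %.1f%% | rate(%s) %.1f%% | rate(%s) %.1f%%\n",
                x$metrics$accuracy_all, x$metrics$class_a,
                x$metrics$rate_class_a, x$metrics$class_b,
                x$metrics$rate_class_b))
  }
  if (!is.null(x$roc)) cat(sprintf("  AUC %.3f\n", x$roc$auc))
  if (!is.null(x$box_fractions)) {
    cat("  box fractions:",
        paste(sprintf("%s %.2f", x$box_fractions$box, x$box_fractions$fraction),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a pipeline run to a report directory
#'
#' Writes the run's artifacts as plain text: per-sample calls
#' (`calls.tsv`), QC report (`qc.tsv`), thresholds and (when present)
#' model JSON, confusion table TSV, and a JSON summary of the metrics.
#' Reports are reproducible: identical input + config yield byte-identical
#' files.
#'
#' @param run A `ct_run`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(run, dir) {
  if (!inherits(run, "ct_run")) stop_config("`run` must be a ct_run.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$calls, file.path(dir, "calls.tsv"))
  write_qc_report(run$qc, file.path(dir, "qc.tsv"))
  write_thresholds_json(run$thresholds, file.path(dir, "thresholds.json"))
  if (!is.null(run$model)) {
    write_model_json(run$model, file.path(dir, "model.json"))
  }
  if (!is.null(run$confusion)) {
    write_confusion(run$confusion, file.path(dir, "confusion.tsv"))
  }
  summary <- list(mode = run$mode, config = run$config)
  if (!is.null(run$metrics)) summary$metrics <- as.list(run$metrics)
  if (!is.null(run$roc)) summary$auc <- run$roc$auc
  if (!is.null(run$box_fractions)) {
    summary$box_fractions <- setNames(as.list(run$box_fractions$fraction),
                                      as.character(run$box_fractions$box))
  }
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
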