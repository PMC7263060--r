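#' Published reference results for the miR375 lung-tumor classifier
#'
#' Two small fixtures from the published training analysis of 58 lung
#' tumors (27 non-neuroendocrine: 14 adenocarcinoma, 13 squamous; 31
#' low-grade neuroendocrine: 8 atypical, 23 typical carcinoid), shipped so
#' that new cohorts can be classified and benchmarked without refitting:
#'
#' * `reference_confusion()` — the training-set subtype-by-box confusion
#'   table (55 of 58 calls on the correct side of the even-odds cut; the
#'   two-class collapse gives 53/58 = 91.4% accuracy).
#' * `reference_thresholds()` — the training-set decision thresholds on
#'   the `dct375` scale: 1.4 (odds 10:90), 3.0 (even odds), 4.9
#'   (odds 90:10) cycles.
#'
#' These are carried as packaged constants, not re-derived: the underlying
#' per-sample training measurements are not public.
#'
#' @return `reference_confusion()` a [confusion_table()];
#'   `reference_thresholds()` a [threshold_set()].
#' @examples
#' classification_metrics(reference_confusion())
#' @export
reference_confusion <- function() {
  path <- system.file("extdata", "training_confusion.tsv", package = "ctbayes",
                      mustWork = TRUE)
  read_confusion(path)
}

#' @rdname reference_confusion
#' @export
reference_thresholds <- function() threshold_set(1.4, 3, 4.9, odds_level = 9)
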