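#' Subtype-by-box confusion table
#'
#' Cross-tabulates classifier calls by histological subtype (rows) and
#' decision box (columns), the layout used to report training-set
#' performance.
#'
#' @param calls A call tibble from [classify_samples()] with a `subtype`
#'   column.
#' @param class_map Named character vector subtype -> binary class; taken
#'   from the calls' `class` column when present.
#' @return An object of class `confusion_table`: a tibble with a `subtype`
#'   column and integer columns `strong_a`, `weak_a`, `weak_b`,
#'   `strong_b`; the subtype -> class map is kept as an attribute.
#' @export
confusion_table <- function(calls, class_map = NULL) {
  boxes <- c("strong_a", "weak_a", "weak_b", "strong_b")
  if (nrow(calls) == 0L) {
    out <- tibble::tibble(subtype = character(),
                          !!!setNames(rep(list(integer()), 4L), boxes))
    return(structure(out, class_map = character(),
                     class = c("confusion_table", class(out))))
  }
  if (!("subtype" %in% names(calls)) || any(is.na(calls$subtype))) {
    stop_data("Every call needs a known subtype to build a confusion table.")
  }
  if (is.null(class_map)) {
    if (!("class" %in% names(calls))) {
      stop_config("Supply `class_map` when the calls carry no class column.")
    }
    pairs <- dplyr::distinct(calls, .data$subtype, .data$class)
    class_map <- setNames(pairs$class, pairs$subtype)
  }
  unknown <- setdiff(unique(calls$subtype), names(class_map))
  if (length(unknown) > 0L) {
    stop_data(sprintf("Subtype(s) without class mapping: %s.",
                      paste(unknown, collapse = ", ")))
  }
  out <- calls |>
    dplyr::count(.data$subtype, box = factor(.data$box, levels = boxes)) |>
    tidyr::pivot_wider(names_from = "box", values_from = "n",
                       values_fill = 0L, names_expand = TRUE) |>
    dplyr::arrange(.data$subtype)
  structure(out, class_map = class_map[out$subtype],
            class = c("confusion_table", class(out)))
}

box_cols <- function() c("strong_a", "weak_a", "weak_b", "strong_b")

#' @export
print.confusion_table <- function(x, ...) {
  cat("<confusion_table> rows = subtypes, columns = odds boxes\n")
  NextMethod()
}

#' Accuracy, class rates, and high-reliability accuracy
#'
#' Collapses the four odds boxes to two predicted classes
#' (a = `strong_a` + `weak_a`, b = `strong_b` + `weak_b`) and computes the
#' headline rates on the percent scale. For the miR375 lung-tumor score,
#' class a is non-NE and class b low-grade NE, so `rate_class_a` is what
#' the source study reports as sensitivity and `rate_class_b` as
#' specificity; both aliases are included. High-reliability accuracy
#' restricts to the `strong_*` calls (posterior odds beyond the
#' `odds_level`) and is the fraction of those that are correct.
#'
#' @param table A [confusion_table()].
#' @return A one-row tibble: `accuracy_all`, `rate_class_a`,
#'   `rate_class_b`, `sensitivity`, `specificity`,
#'   `accuracy_high_reliability`, `n_high_reliability`, `n_total`, and the
#'   supporting counts. Percentages are carried at full precision; round
#'   only for display.
#' @examples
#' classification_metrics(reference_confusion())
#' @export
classification_metrics <- function(table) {
  if (!inherits(table, "confusion_table") || nrow(table) == 0L) {
    stop_data("`table` must be a non-empty confusion_table.")
  }
  cmap <- attr(table, "class_map")
  classes <- sort(unique(cmap))
  if (length(classes) != 2L) {
    stop_data("The class map must define exactly two classes.")
  }
  # class "a" is the one predicted by the *_a boxes: identified as the class
  # whose subtypes concentrate in the a columns
  a_mass <- vapply(classes, function(cl) {
    rows <- table$subtype %in% names(cmap)[cmap == cl]
    sum(table$strong_a[rows] + table$weak_a[rows])
  }, numeric(1))
  class_a <- classes[which.max(a_mass)]
  class_b <- setdiff(classes, class_a)

  truth <- cmap[table$subtype]
  pred_a <- table$strong_a + table$weak_a
  pred_b <- table$strong_b + table$weak_b
  n_a <- sum(pred_a[truth == class_a] + pred_b[truth == class_a])
  n_b <- sum(pred_a[truth == class_b] + pred_b[truth == class_b])
  correct_a <- sum(pred_a[truth == class_a])
  correct_b <- sum(pred_b[truth == class_b])
  strong_total <- sum(table$strong_a + table$strong_b)
  strong_correct <- sum(table$strong_a[truth == class_a]) +
    sum(table$strong_b[truth == class_b])

  tibble::tibble(
    class_a = class_a, class_b = class_b,
    n_total = n_a + n_b, n_class_a = n_a, n_class_b = n_b,
    correct_class_a = correct_a, correct_class_b = correct_b,
    accuracy_all = 100 * (correct_a + correct_b) / (n_a + n_b),
    rate_class_a = 100 * correct_a / n_a,
    rate_class_b = 100 * correct_b / n_b,
    sensitivity = 100 * correct_a / n_a,
    specificity = 100 * correct_b / n_b,
    n_high_reliability = strong_total,
    accuracy_high_reliability = if (strong_total > 0)
      100 * strong_correct / strong_total else NA_real_
  )
}

#' Empirical ROC curve and AUC
#'
#' The AUC is the Mann-Whitney U statistic scaled by `n_pos * n_neg`, with
#' ties counted 1/2 — the probability that a random positive-class score
#' exceeds a random negative-class one. ROC points are produced at every
#' distinct threshold and include (0,0) and (1,1).
#'
#' @param scores Numeric scores (higher = more positive-class-like), or a
#'   score tibble from [score_table()].
#' @param labels Class label per score (from `scores$class` for tibbles).
#' @param positive Label of the positive (high-score) class; default
#'   `"NE"`, matching the miR375 score orientation.
#' @return A list of class `roc_result`: `points` (tibble `threshold`,
#'   `tpr`, `fpr`), `auc`, `n_pos`, `n_neg`.
#' @export
empirical_roc <- function(scores, labels = NULL, positive = "NE") {
  if (is.data.frame(scores)) {
    labels <- labels %||% scores$class
    scores <- scores$value
  }
  pos <- labels == positive
  if (!any(pos) || all(pos)) {
    stop_data("Both classes must be present to compute a ROC curve.")
  }
  n1 <- as.numeric(sum(pos)); n0 <- as.numeric(sum(!pos))
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # one ROC point per distinct threshold via cumulative counts over the
  # score-sorted samples
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  pos_sorted <- pos[ord]
  last_of_run <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  points <- tibble::tibble(
    threshold = c(Inf, s_sorted[last_of_run]),
    tpr = c(0, cumsum(pos_sorted)[last_of_run] / n1),
    fpr = c(0, cumsum(!pos_sorted)[last_of_run] / n0)
  )
  structure(list(points = points, auc = auc, n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positive vs %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Between-class separation t-test
#'
#' Two-sample Student's t-test (pooled variance by default, matching the
#' classical reporting convention; Welch via `var_equal = FALSE`) of the
#' score between the two classes.
#'
#' @param scores Numeric scores or a score tibble.
#' @param labels Class labels.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return One-row tibble: `t_statistic`, `t_pvalue`, `df`, per-class means.
#' @export
separation_t_test <- function(scores, labels = NULL, var_equal = TRUE) {
  if (is.data.frame(scores)) {
    labels <- labels %||% scores$class
    scores <- scores$value
  }
  groups <- split(scores, labels)
  if (length(groups) != 2L || any(lengths(groups) < 2L)) {
    stop_data("Need two classes with >= 2 samples each for the t-test.")
  }
  if (all(vapply(groups, function(g) var(g) == 0, logical(1)))) {
    stop_data("Both groups have zero variance; the t-test is undefined.")
  }
  ht <- t.test(groups[[1]], groups[[2]], var.equal = var_equal)
  tibble::tibble(
    class_1 = names(groups)[1], class_2 = names(groups)[2],
    mean_1 = mean(groups[[1]]), mean_2 = mean(groups[[2]]),
    t_statistic = unname(ht$statistic), df = unname(ht$parameter),
    t_pvalue = ht$p.value
  )
}

#' One-way ANOVA of the score against clinical stage
#'
#' Tests, within each binary class separately, whether the score differs
#' across clinical-stage groups — the check that the marker is a subtype
#' signal rather than a stage signal.
#'
#' @param scores Numeric scores or a score tibble with `stage` and `class`
#'   columns.
#' @param stages Stage label per score (for numeric input).
#' @param classes Binary class per score (for numeric input); omit to run
#'   a single pooled ANOVA.
#' @return Tibble with one row per class: `class`, `f_statistic`, `df1`,
#'   `df2`, `p_value`, `n`.
#' @export
stage_anova <- function(scores, stages = NULL, classes = NULL) {
  if (is.data.frame(scores)) {
    stages <- stages %||% scores$stage
    classes <- classes %||% scores$class
    scores <- scores$value
  }
  if (is.null(classes)) classes <- rep("all", length(scores))
  keep <- !is.na(stages) & !is.na(scores)
  scores <- scores[keep]; stages <- stages[keep]; classes <- classes[keep]

  purrr::map_dfr(unique(classes), function(cl) {
    x <- scores[classes == cl]
    g <- droplevels(factor(stages[classes == cl]))
    usable <- table(g)
    if (length(usable) < 2L) {
      stop_data(sprintf(
        "Class '%s' has fewer than 2 stage groups; ANOVA needs at least 2.", cl
      ))
    }
    fit <- aov(x ~ g)
    s <- summary(fit)[[1]]
    tibble::tibble(
      class = cl,
      f_statistic = s[["F value"]][1],
      df1 = s[["Df"]][1], df2 = s[["Df"]][2],
      p_value = s[["Pr(>F)"]][1],
      n = length(x)
    )
  })
}

#' Normalizer stability between classes
#'
#' A usable endogenous normalizer must not itself separate the classes:
#' this summarizes the per-class U6 mean Cts and flags the normalizer as
#' unstable only when the between-class difference is both statistically
#' significant (t-test p < `alpha`) and larger than `min_effect` cycles.
#'
#' @param qc A `ct_qc` object, its `means` tibble, or a data frame with
#'   `assay`, `mean_ct`, `class`.
#' @param assay Normalizer assay name (default `"U6"`).
#' @param alpha Significance level of the t-test.
#' @param min_effect Minimal between-class mean difference (cycles) to
#'   call instability.
#' @return One-row tibble: per-class means and SDs, `delta_mean`,
#'   `t_pvalue`, `stable`.
#' @export
normalizer_stability <- function(qc, assay = "U6", alpha = 0.05,
                                 min_effect = 1) {
  means <- if (inherits(qc, "ct_qc")) qc$means else qc
  u6 <- dplyr::filter(means, .data$assay == !!assay,
                      is.finite(.data$mean_ct))
  classes <- sort(unique(u6$class))
  if (length(classes) != 2L) stop_data("Need exactly two classes present.")
  g1 <- u6$mean_ct[u6$class == classes[1]]
  g2 <- u6$mean_ct[u6$class == classes[2]]
  if (length(g1) < 2L || length(g2) < 2L) {
    stop_data("Need >= 2 samples per class for the stability test.")
  }
  ht <- t.test(g1, g2, var.equal = TRUE)
  delta <- mean(g2) - mean(g1)
  tibble::tibble(
    assay = assay, class_1 = classes[1], class_2 = classes[2],
    mean_1 = mean(g1), sd_1 = sd(g1), mean_2 = mean(g2), sd_2 = sd(g2),
    delta_mean = delta, t_pvalue = ht$p.value,
    stable = !(ht$p.value < alpha && abs(delta) > min_effect)
  )
}

#' Read and write confusion tables as TSV
#'
#' The layout mirrors the published table: subtype rows, four box
#' columns, plus a `class` column recording the subtype -> class map.
#'
#' @param table A `confusion_table`.
#' @param path TSV file path.
#' @return Readers return the `confusion_table`; writers their input,
#'   invisibly.
#' @export
write_confusion <- function(table, path) {
  out <- tibble::as_tibble(table)
  out$class <- attr(table, "class_map")[out$subtype]
  readr::write_tsv(out, path)
  invisible(table)
}

#' @rdname write_confusion
#' @export
read_confusion <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    subtype = readr::col_character(), class = readr::col_character(),
    .default = readr::col_integer()
  ))
  missing <- setdiff(c("subtype", "class", box_cols()), names(raw))
  if (length(missing) > 0L) {
    stop_data(sprintf("Confusion TSV lacks column(s): %s.",
                      paste(missing, collapse = ", ")))
  }
  cmap <- setNames(raw$class, raw$subtype)
  out <- dplyr::select(raw, "subtype", dplyr::all_of(box_cols()))
  structure(out, class_map = cmap,
            class = c("confusion_table", class(out)))
}
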