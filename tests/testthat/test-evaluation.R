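test_that("the packaged training confusion table has the published margins", {
  ct <- reference_confusion()
  row_sums <- rowSums(ct[, c("strong_a", "weak_a", "weak_b", "strong_b")])
  expect_equal(setNames(row_sums, ct$subtype),
               c(AD = 14, SQC = 13, AT = 8, TC = 23))
  expect_equal(sum(row_sums), 58)
  expect_equal(attr(ct, "class_map"),
               c(AD = "nonNE", SQC = "nonNE", AT = "NE", TC = "NE"))
})

test_that("confusion tables round-trip through TSV unchanged", {
  ct <- reference_confusion()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_confusion(ct, f)
  back <- read_confusion(f)
  expect_equal(as.data.frame(back), as.data.frame(ct))
  expect_equal(attr(back, "class_map"), attr(ct, "class_map"))
})

test_that("confusion tables are built from calls and handle edge cases", {
  calls <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:6),
    subtype = c("AD", "AD", "TC", "TC", "TC", "SQC"),
    class = c("nonNE", "nonNE", "NE", "NE", "NE", "nonNE"),
    box = factor(c("strong_a", "weak_b", "strong_b", "strong_b", "weak_a",
                   "strong_a"),
                 levels = c("strong_a", "weak_a", "weak_b", "strong_b"))
  )
  ct <- confusion_table(calls)
  expect_equal(ct$strong_b[ct$subtype == "TC"], 2L)
  expect_equal(sum(dplyr::select(tibble::as_tibble(ct), -subtype)), 6)

  empty <- confusion_table(calls[0, ])
  expect_equal(nrow(empty), 0)

  expect_error(confusion_table(dplyr::select(calls, -class)),
               class = "ctbayes_config_error")
  bad_map <- c(AD = "nonNE", SQC = "nonNE", AT = "NE")
  expect_error(confusion_table(calls, class_map = bad_map),
               class = "ctbayes_data_error")
})

test_that("the published training metrics are reproduced from the confusion table", {
  m <- classification_metrics(reference_confusion())
  expect_equal(m$accuracy_all, 100 * 53 / 58, tolerance = 1e-12)
  expect_equal(m$rate_class_a, 100 * 25 / 27, tolerance = 1e-12)
  expect_equal(m$rate_class_b, 100 * 28 / 31, tolerance = 1e-12)
  expect_equal(round(m$accuracy_all, 1), 91.4)
  expect_equal(round(m$sensitivity, 1), 92.6)
  # strong-call (high-reliability) accuracy under the implemented rule
  expect_equal(m$n_high_reliability, 25)
  expect_equal(m$accuracy_high_reliability, 100 * 24 / 25, tolerance = 1e-12)
})

test_that("a perfectly diagonal table yields 100% everywhere", {
  calls <- tibble::tibble(
    sample_id = sprintf("S%02d", 1:8),
    subtype = rep(c("AD", "TC"), each = 4),
    class = rep(c("nonNE", "NE"), each = 4),
    box = factor(rep(c("strong_a", "strong_b"), each = 4),
                 levels = c("strong_a", "weak_a", "weak_b", "strong_b"))
  )
  m <- classification_metrics(confusion_table(calls))
  expect_equal(m$accuracy_all, 100)
  expect_equal(m$rate_class_a, 100)
  expect_equal(m$rate_class_b, 100)
  expect_equal(m$accuracy_high_reliability, 100)
})

test_that("accuracy is the class-size-weighted mean of the class rates", {
  set.seed(12)
  boxes <- c("strong_a", "weak_a", "weak_b", "strong_b")
  for (i in 1:20) {
    calls <- tibble::tibble(
      sample_id = sprintf("S%03d", 1:40),
      subtype = sample(c("AD", "SQC", "AT", "TC"), 40, replace = TRUE),
      box = factor(sample(boxes, 40, replace = TRUE), levels = boxes)
    ) |>
      dplyr::mutate(class = ifelse(subtype %in% c("AD", "SQC"), "nonNE", "NE"))
    ct <- confusion_table(calls)
    m <- classification_metrics(ct)
    weighted <- (m$rate_class_a * m$n_class_a + m$rate_class_b * m$n_class_b) /
      m$n_total
    expect_equal(m$accuracy_all, weighted, tolerance = 1e-12)
    # collapsing the four boxes conserves the counts
    expect_equal(m$n_total, 40)
  }
})

test_that("empirical AUC equals the brute-force all-pairs probability", {
  set.seed(4)
  for (i in 1:10) {
    n1 <- sample(20:100, 1); n0 <- sample(20:100, 1)
    # discretized scores force ties
    x <- c(round(rnorm(n0, 0, 1), 1), round(rnorm(n1, 1, 1), 1))
    lab <- c(rep("nonNE", n0), rep("NE", n1))
    r <- empirical_roc(x, lab)
    pairs <- outer(x[lab == "NE"], x[lab == "nonNE"],
                   function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(pairs), tolerance = 1e-12)
  }
})

test_that("AUC is 1 for separated classes, ~0.5 under the null, and matches pROC", {
  sep <- empirical_roc(c(1, 2, 3, 11, 12, 13),
                       rep(c("nonNE", "NE"), each = 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$points$tpr[1], 0)
  expect_equal(dplyr::last(sep$points$fpr), 1)

  set.seed(19)
  x <- rnorm(4000)
  lab <- rep(c("nonNE", "NE"), 2000)
  null_auc <- empirical_roc(x, lab)$auc
  expect_gt(null_auc, 0.47)
  expect_lt(null_auc, 0.53)

  # independent implementation cross-check
  y <- c(rnorm(300), rnorm(300, 1.2))
  lab2 <- rep(c("nonNE", "NE"), each = 300)
  ours <- empirical_roc(y, lab2)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = lab2, predictor = y, levels = c("nonNE", "NE"),
    direction = "<", quiet = TRUE
  )))
  expect_equal(ours, theirs, tolerance = 1e-12)

  expect_error(empirical_roc(1:5, rep("NE", 5)), class = "ctbayes_data_error")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  x <- rnorm(200, c(0, 2))
  lab <- rep(c("nonNE", "NE"), 100)
  base <- empirical_roc(x, lab)$auc
  expect_equal(empirical_roc(exp(x), lab)$auc, base)
  expect_equal(empirical_roc(x^3 + 5 * x, lab)$auc, base)
})

test_that("the separation t-test matches hand-pooled arithmetic", {
  same <- separation_t_test(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$t_pvalue, 1)

  ht <- separation_t_test(c(0, 2, 4, 6), c("a", "a", "b", "b"))
  # pooled s^2 = 2, se = sqrt(2 * (1/2 + 1/2)) = sqrt(2) -> t = -4/sqrt(2)
  expect_equal(ht$t_statistic, -2 * sqrt(2), tolerance = 1e-12)
  expect_equal(ht$df, 2)

  expect_error(separation_t_test(c(1, 1, 2, 2), c("a", "a", "b", "b")),
               class = "ctbayes_data_error")
})

test_that("well-separated synthetic cohorts give vanishing t-test p-values", {
  tbl <- simulate_cohort(cohort_spec(n_per_class = c(nonNE = 100, NE = 100),
                                     seed = 14))
  scores <- score_table(qc_cohort(tbl), score_dct375())
  ht <- separation_t_test(scores)
  expect_lt(ht$t_pvalue, 1e-10)
})

test_that("stage ANOVA matches a brute-force sum-of-squares oracle", {
  flat <- stage_anova(rep(c(1, 2), 3), rep(c("I", "II", "III"), each = 2))
  expect_equal(flat$f_statistic, 0)

  oracle_f <- function(x, g) {
    g <- factor(g)
    gm <- mean(x)
    ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
    df1 <- nlevels(g) - 1; df2 <- length(x) - nlevels(g)
    (ssb / df1) / (ssw / df2)
  }
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(30)
    g <- sample(c("I", "II", "III"), 30, replace = TRUE)
    res <- stage_anova(x, g)
    expect_equal(res$f_statistic, oracle_f(x, g), tolerance = 1e-10)
  }

  expect_error(stage_anova(rnorm(5), rep("I", 5)), class = "ctbayes_data_error")
})

test_that("stage is unrelated to the score under the null generator", {
  hits <- vapply(1:100, function(s) {
    set.seed(3000 + s)
    x <- rnorm(600)
    g <- rep(c("I", "II", "III"), each = 200)
    stage_anova(x, g)$p_value > 0.05
  }, logical(1))
  expect_gte(sum(hits), 90)
})

test_that("stage ANOVA runs per class on score tables", {
  tbl <- simulate_cohort(cohort_spec(n_per_class = c(nonNE = 60, NE = 60),
                                     seed = 25))
  scores <- score_table(qc_cohort(tbl), score_dct375())
  res <- stage_anova(scores)
  expect_setequal(res$class, c("nonNE", "NE"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
})

test_that("normalizer stability flags only real between-class shifts", {
  means_stable <- tibble::tibble(
    assay = "U6",
    mean_ct = rep(c(24.0, 24.1, 23.9, 24.2), 2),
    class = rep(c("nonNE", "NE"), each = 4)
  )
  expect_true(normalizer_stability(means_stable)$stable)

  set.seed(30)
  means_shifted <- tibble::tibble(
    assay = "U6",
    mean_ct = c(rnorm(30, 24, 0.3), rnorm(30, 27, 0.3)),
    class = rep(c("nonNE", "NE"), each = 30)
  )
  res <- normalizer_stability(means_shifted)
  expect_false(res$stable)
  expect_equal(abs(res$delta_mean), 3, tolerance = 0.3)
})

test_that("the default generator yields a stable normalizer in most seeded runs", {
  stable <- vapply(1:100, function(s) {
    tbl <- simulate_cohort(cohort_spec(seed = 5000 + s))
    means <- tbl |>
      dplyr::summarise(mean_ct = mean(ct), .by = c(sample_id, class, assay))
    normalizer_stability(means)$stable
  }, logical(1))
  expect_gte(sum(stable), 95)
})
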