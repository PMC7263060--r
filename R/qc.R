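#' Quality-control parameters for Ct triplicates
#'
#' Technical outliers among replicate triplicates are identified in two
#' steps: a chi-square test of the within-triplicate variance against the
#' pooled technical variance of the assay, with at most `max_removals`
#' single-replicate removals, followed by a Student's t check of the
#' surviving triplicate mean against the per-assay population of triplicate
#' means.
#'
#' @param alpha_var Significance level of the chi-square variability test.
#' @param alpha_mean Significance level of the mean-deviation t check.
#' @param min_replicates Minimum replicates that must survive removal (>= 2).
#' @param max_removals Maximum replicates removable per triplicate.
#' @param trim_frac Fraction of the most-variable triplicates excluded when
#'   pooling the reference technical variance (0 disables trimming). Keeps
#'   the very outliers under test from inflating the reference.
#' @param pop_scope `"all"` (default) computes the deviation-test population
#'   over all samples regardless of class, as required when class labels are
#'   unknown at QC time; `"class"` uses per-class populations.
#'
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(alpha_var = 0.05, alpha_mean = 0.05,
                      min_replicates = 2L, max_removals = 1L,
                      trim_frac = 0.1, pop_scope = c("all", "class")) {
  for (a in c(alpha_var, alpha_mean)) {
    if (!is.numeric(a) || a <= 0 || a >= 1) {
      stop_config("QC significance levels must lie strictly in (0, 1).")
    }
  }
  if (min_replicates < 2L) stop_config("`min_replicates` must be >= 2.")
  assert_prob(trim_frac, "trim_frac")
  structure(
    list(alpha_var = alpha_var, alpha_mean = alpha_mean,
         min_replicates = as.integer(min_replicates),
         max_removals = as.integer(max_removals),
         trim_frac = trim_frac, pop_scope = match.arg(pop_scope)),
    class = "qc_params"
  )
}

#' Pooled within-triplicate technical SD of an assay
#'
#' Pools the within-triplicate variances of one assay across samples,
#' `sigma0^2 = sum((n_i - 1) s_i^2) / sum(n_i - 1)`, optionally after
#' excluding the `trim_frac` most-variable triplicates so that corrupted
#' triplicates do not inflate the reference variance they are tested
#' against.
#'
#' @param table A raw Ct table.
#' @param assay Assay name to pool over.
#' @param trim_frac Fraction of the largest triplicate variances excluded
#'   before pooling.
#' @return A one-row tibble with `assay`, `sigma0` (cycles), `dof` (pooled
#'   degrees of freedom), and `n_triplicates` used.
#' @export
estimate_pooled_sd <- function(table, assay, trim_frac = 0.1) {
  validate_ct_table(table)
  per <- table |>
    dplyr::filter(.data$assay == !!assay) |>
    dplyr::summarise(s2 = var(.data$ct), n = dplyr::n(),
                     .by = "sample_id") |>
    dplyr::filter(.data$n >= 2L)
  if (nrow(per) < 2L) {
    stop_data(sprintf("Fewer than 2 usable triplicates for assay '%s'.", assay))
  }
  if (trim_frac > 0) {
    keep <- per$s2 <= stats::quantile(per$s2, 1 - trim_frac, type = 1)
    if (sum(keep) >= 2L) per <- per[keep, , drop = FALSE]
  }
  dof <- sum(per$n - 1L)
  tibble::tibble(
    assay = assay,
    sigma0 = sqrt(sum((per$n - 1L) * per$s2) / dof),
    dof = dof,
    n_triplicates = nrow(per)
  )
}

# box-score of one variability test: statistic, p-value, pass/fail
var_test <- function(cts, sigma0, alpha) {
  n <- length(cts)
  s2 <- var(cts)
  stat <- (n - 1) * s2 / sigma0^2
  p <- pchisq(stat, df = n - 1, lower.tail = FALSE)
  list(stat = stat, p = p, fail = p < alpha)
}

#' Assess one Ct triplicate for technical outliers
#'
#' Applies the two-step check to a single (sample, assay) triplicate:
#' (a) variability — the statistic `(n-1) s^2 / sigma0^2` is referred to the
#' upper chi-square(n-1) quantile at `alpha_var`; on failure the replicate
#' farthest from the triplicate median is removed (at most
#' `params$max_removals` times) and the survivors re-tested; (b) deviation —
#' the surviving triplicate mean is referred, via a Student's t statistic
#' `(m - pop_mean) / pop_sd`, to the population of triplicate means of the
#' same assay. Both tests are recorded; a pass requires both.
#'
#' @param cts Numeric vector of 2-3 replicate Ct values.
#' @param sigma0 Pooled technical SD (cycles), as from
#'   [estimate_pooled_sd()] (a number or its one-row tibble). If 0, the
#'   variability test is skipped with a warning.
#' @param pop_mean,pop_sd Mean and SD of the per-sample triplicate means of
#'   this assay across the cohort.
#' @param params A [qc_params()].
#' @param pop_n Number of samples behind `pop_mean`/`pop_sd`; the t check
#'   uses `pop_n - 1` degrees of freedom (`Inf` = normal reference).
#' @param sample_id,assay Optional identifiers carried into the verdict.
#'
#' @return A one-row tibble (`sample_id`, `assay`, `status`,
#'   `removed_replicates` list-column, `n_used`, `triplicate_mean`,
#'   `triplicate_sd`, `var_statistic`, `var_pvalue`, `mean_statistic`,
#'   `mean_pvalue`, `reason`). `status` is `"pass"`,
#'   `"pass_after_removal"`, or `"outlier"`.
#' @export
assess_triplicate <- function(cts, sigma0, pop_mean, pop_sd, params = qc_params(),
                              pop_n = Inf, sample_id = NA_character_,
                              assay = NA_character_) {
  v <- assess_one(cts, sigma0, pop_mean, pop_sd, params, pop_n)
  tibble::tibble(
    sample_id = sample_id, assay = assay, status = v$status,
    removed_replicates = list(v$removed), n_used = v$n_used,
    triplicate_mean = v$triplicate_mean, triplicate_sd = v$triplicate_sd,
    var_statistic = v$var_statistic, var_pvalue = v$var_pvalue,
    mean_statistic = v$mean_statistic, mean_pvalue = v$mean_pvalue,
    reason = v$reason
  )
}

# workhorse behind assess_triplicate/qc_cohort: plain list, no tibble
# overhead, so whole-cohort QC stays fast
assess_one <- function(cts, sigma0, pop_mean, pop_sd, params, pop_n) {
  if (is.data.frame(sigma0)) sigma0 <- sigma0$sigma0[1]
  if (any(!is.finite(cts))) stop_data("Replicate Ct values must all be finite.")
  verdict <- function(status, removed, kept, vt, mt, reason = NA_character_) {
    list(status = status, removed = removed, n_used = length(kept),
         triplicate_mean = if (length(kept)) mean(kept) else NA_real_,
         triplicate_sd = if (length(kept) > 1) sd(kept) else NA_real_,
         var_statistic = vt$stat, var_pvalue = vt$p,
         mean_statistic = mt$stat, mean_pvalue = mt$p, reason = reason)
  }
  none <- list(stat = NA_real_, p = NA_real_)
  if (length(cts) < 2L) {
    return(verdict("outlier", integer(), cts, none, none,
                   reason = "insufficient replicates"))
  }

  kept_idx <- seq_along(cts)
  removed <- integer()
  if (sigma0 <= 0) {
    warn("Pooled technical SD is 0; the variability test is skipped.")
    vt <- none
  } else {
    vt <- var_test(cts, sigma0, params$alpha_var)
    removals_left <- params$max_removals
    while (vt$fail && removals_left > 0L &&
           length(kept_idx) - 1L >= params$min_replicates) {
      kept <- cts[kept_idx]
      drop_local <- which.max(abs(kept - median(kept)))
      removed <- c(removed, kept_idx[drop_local])
      kept_idx <- kept_idx[-drop_local]
      removals_left <- removals_left - 1L
      vt <- var_test(cts[kept_idx], sigma0, params$alpha_var)
    }
    if (vt$fail) {
      mt <- mean_test(mean(cts[kept_idx]), pop_mean, pop_sd, pop_n)
      return(verdict("outlier", removed, cts[kept_idx], vt, mt,
                     reason = "variability"))
    }
  }

  m <- mean(cts[kept_idx])
  mt <- mean_test(m, pop_mean, pop_sd, pop_n)
  if (is.finite(mt$p) && mt$p < params$alpha_mean) {
    return(verdict("outlier", removed, cts[kept_idx], vt, mt,
                   reason = "mean deviation"))
  }
  status <- if (length(removed) > 0L) "pass_after_removal" else "pass"
  verdict(status, removed, cts[kept_idx], vt, mt)
}

mean_test <- function(m, pop_mean, pop_sd, pop_n) {
  if (!is.finite(pop_sd) || pop_sd <= 0) {
    return(list(stat = NA_real_, p = NA_real_))
  }
  stat <- (m - pop_mean) / pop_sd
  df <- if (is.finite(pop_n)) pop_n - 1 else Inf
  list(stat = stat, p = 2 * pt(-abs(stat), df = df))
}

#' Quality-control a whole cohort of Ct triplicates
#'
#' Estimates the pooled technical SD per assay, assesses every
#' (sample, assay) triplicate with [assess_triplicate()], and returns the
#' per-sample per-assay mean Cts of the surviving measurements together
#' with the exhaustive verdict list.
#'
#' @param table A raw Ct table.
#' @param params A [qc_params()].
#' @return An object of class `ct_qc`: a list with
#'   \describe{
#'     \item{means}{tibble of per-sample per-assay triplicate means
#'       (`sample_id`, `subtype`, `class`, `stage`, `assay`, `mean_ct`,
#'       `n_used`, `status`); outlier triplicates keep their mean but carry
#'       `status = "outlier"` so scoring can exclude or retain them.}
#'     \item{verdicts}{one row per (sample, assay) from
#'       [assess_triplicate()], plus per-assay population statistics.}
#'     \item{pooled}{per-assay pooled-SD table.}
#'     \item{params}{the `qc_params` used.}
#'   }
#' @examples
#' qc <- qc_cohort(simulate_cohort(cohort_spec(seed = 2)))
#' dplyr::count(tidy(qc), status)
#' @export
qc_cohort <- function(table, params = qc_params()) {
  validate_ct_table(table)
  pooled <- purrr::map_dfr(unique(table$assay), function(a) {
    estimate_pooled_sd(table, a, trim_frac = params$trim_frac)
  })

  has_stage <- "stage" %in% names(table)
  meta_cols <- intersect(c("sample_id", "subtype", "class", "stage"), names(table))
  meta <- dplyr::distinct(table, dplyr::across(dplyr::all_of(meta_cols)))

  trip_means <- table |>
    dplyr::summarise(m = mean(.data$ct), .by = c("sample_id", "assay", "class"))
  pop_stats <- if (params$pop_scope == "class") {
    trip_means |>
      dplyr::summarise(pop_mean = mean(.data$m), pop_sd = sd(.data$m),
                       pop_n = dplyr::n(), .by = c("assay", "class"))
  } else {
    trip_means |>
      dplyr::summarise(pop_mean = mean(.data$m), pop_sd = sd(.data$m),
                       pop_n = dplyr::n(), .by = "assay")
  }

  groups <- table |>
    dplyr::summarise(cts = list(.data$ct),
                     .by = c("sample_id", "class", "assay"))
  if (params$pop_scope == "class") {
    groups <- dplyr::left_join(groups, pop_stats, by = c("assay", "class"))
  } else {
    groups <- dplyr::left_join(groups, pop_stats, by = "assay")
  }
  groups <- dplyr::left_join(groups, pooled[, c("assay", "sigma0")], by = "assay")

  ng <- nrow(groups)
  status <- character(ng); reason <- character(ng)
  removed <- vector("list", ng)
  num_cols <- matrix(NA_real_, nrow = ng, ncol = 7L)
  for (g in seq_len(ng)) {
    v <- assess_one(groups$cts[[g]], groups$sigma0[g], groups$pop_mean[g],
                    groups$pop_sd[g], params, groups$pop_n[g])
    status[g] <- v$status; reason[g] <- v$reason %||% NA_character_
    removed[[g]] <- v$removed
    num_cols[g, ] <- c(v$n_used, v$triplicate_mean, v$triplicate_sd,
                       v$var_statistic, v$var_pvalue,
                       v$mean_statistic, v$mean_pvalue)
  }
  verdicts <- tibble::tibble(
    sample_id = groups$sample_id, assay = groups$assay, status = status,
    removed_replicates = removed, n_used = as.integer(num_cols[, 1]),
    triplicate_mean = num_cols[, 2], triplicate_sd = num_cols[, 3],
    var_statistic = num_cols[, 4], var_pvalue = num_cols[, 5],
    mean_statistic = num_cols[, 6], mean_pvalue = num_cols[, 7],
    reason = reason
  )

  # a sample lacking an assay altogether still gets a verdict, so the
  # verdict list is exhaustive over sample x assay
  full_grid <- tidyr::expand_grid(sample_id = unique(table$sample_id),
                                  assay = unique(table$assay))
  absent <- dplyr::anti_join(full_grid, verdicts, by = c("sample_id", "assay"))
  if (nrow(absent) > 0L) {
    verdicts <- dplyr::bind_rows(
      verdicts,
      dplyr::mutate(absent, status = "outlier",
                    removed_replicates = list(integer()), n_used = 0L,
                    triplicate_mean = NA_real_, triplicate_sd = NA_real_,
                    var_statistic = NA_real_, var_pvalue = NA_real_,
                    mean_statistic = NA_real_, mean_pvalue = NA_real_,
                    reason = "missing assay")
    )
  }
  verdicts <- dplyr::arrange(verdicts, .data$sample_id, .data$assay)

  means <- verdicts |>
    dplyr::select("sample_id", "assay", mean_ct = "triplicate_mean",
                  "n_used", "status") |>
    dplyr::left_join(meta, by = "sample_id") |>
    dplyr::select(dplyr::all_of(meta_cols), "assay", "mean_ct", "n_used",
                  "status") |>
    dplyr::arrange(.data$sample_id, .data$assay)

  structure(list(means = means, verdicts = verdicts, pooled = pooled,
                 params = params),
            class = "ct_qc")
}

#' @export
print.ct_qc <- function(x, ...) {
  tab <- table(x$verdicts$status)
  cat("<ct_qc> ", nrow(x$verdicts), " triplicates: ",
      paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ct_qc <- function(x, ...) x$verdicts

#' Write a QC report
#'
#' One TSV row per (sample, assay) verdict; removed replicate indices are
#' comma-joined.
#'
#' @param qc A `ct_qc` object.
#' @param path Output TSV path.
#' @export
write_qc_report <- function(qc, path) {
  out <- qc$verdicts |>
    dplyr::mutate(removed_replicates = purrr::map_chr(
      .data$removed_replicates, ~ paste(.x, collapse = ",")
    ))
  readr::write_tsv(out, path)
  invisible(qc)
}
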