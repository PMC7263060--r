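#' Describe a synthetic Ct-triplicate cohort
#'
#' A cohort specification fixes everything the generator needs to draw a
#' cohort of lung-tumor samples measured by TaqMan RT-qPCR in technical
#' triplicates: per-class sample counts, the class-conditional Gaussian of
#' the latent miR375 score (`dct375 = CtU6 - Ct375`), the normalizer (U6)
#' Ct distribution, within-triplicate technical noise, and an optional rate
#' of injected technical outliers.
#'
#' The defaults emulate a two-class lung cohort of 27 non-neuroendocrine
#' (14 adenocarcinoma, 13 squamous) and 31 low-grade neuroendocrine
#' (8 atypical, 23 typical carcinoid) samples. The default class Gaussians,
#' non-NE ~ N(0.13, 2.39^2) and NE ~ N(5.57, 1.83^2) on the `dct375` scale,
#' were solved so that the equal-prior posterior-odds thresholds land at
#' approximately 1.4 / 3.0 / 4.9 cycles with a Bayes maximum accuracy near
#' 90%; see the package vignette for the derivation.
#'
#' miR205 and miR21 Cts are generated by the same latent-offset mechanism
#' with class-independent offsets, so the weighted miR205 score carries no
#' class separation by default.
#'
#' @param n_per_class Named integer vector of samples per binary class.
#' @param class_labels Named character vector mapping subtype -> class.
#' @param subtype_weights Named numeric vector of within-class subtype
#'   weights; samples are allocated to subtypes deterministically by largest
#'   remainder, so default counts are exactly 14/13/8/23.
#' @param mu_dct,sigma_dct Named numeric vectors (one entry per class): mean
#'   and between-sample SD of the latent `dct375` score, in cycles.
#' @param mu_u6,sigma_u6 Mean and between-sample SD of the U6 Ct (cycles).
#' @param mu_d205,sigma_d205,mu_d21,sigma_d21 Latent offsets (cycles) of the
#'   miR205 and miR21 Cts below U6 (`Ct = CtU6 - offset`), identical for
#'   both classes.
#' @param sigma_tech Within-triplicate technical SD per replicate (cycles).
#' @param outlier_rate Probability that a (sample, assay) triplicate is
#'   corrupted by [inject_outliers()] when [simulate_cohort()] is asked to.
#' @param outlier_modes Subset of `"inflated_variance"`, `"shifted_replicate"`.
#' @param stage_weights Named numeric vector of clinical-stage frequencies;
#'   stages are drawn independently of the latent score. `NULL` omits stages.
#' @param ct_range Plausible Ct range (cycles) used for validation.
#' @param seed Integer seed governing the whole cohort; per-sample
#'   sub-streams are derived from it deterministically.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [simulate_cohort()], [inject_outliers()]
#' @export
cohort_spec <- function(n_per_class = c(nonNE = 27, NE = 31),
                        class_labels = c(AD = "nonNE", SQC = "nonNE",
                                         AT = "NE", TC = "NE"),
                        subtype_weights = c(AD = 14, SQC = 13, AT = 8, TC = 23),
                        mu_dct = c(nonNE = 0.13, NE = 5.57),
                        sigma_dct = c(nonNE = 2.39, NE = 1.83),
                        mu_u6 = 24, sigma_u6 = 1,
                        mu_d205 = -4, sigma_d205 = 1.5,
                        mu_d21 = 2, sigma_d21 = 1,
                        sigma_tech = 0.15,
                        outlier_rate = 0,
                        outlier_modes = c("inflated_variance", "shifted_replicate"),
                        stage_weights = c(IA1 = 7, IA2 = 11, IA3 = 5, IB = 18,
                                          IIA = 3, IIB = 11, IIIA = 11,
                                          IIIB = 5, IVB = 1),
                        ct_range = c(5, 40),
                        seed = 1L) {
  classes <- names(n_per_class)
  if (is.null(classes) || length(classes) != 2L) {
    stop_config("`n_per_class` must be a named vector with exactly two classes.")
  }
  if (any(n_per_class < 1)) stop_config("`n_per_class` entries must be >= 1.")
  if (!setequal(unique(class_labels), classes)) {
    stop_config("`class_labels` must map subtypes onto the classes of `n_per_class`.")
  }
  for (nm in c("sigma_u6", "sigma_d205", "sigma_d21", "sigma_tech")) {
    v <- get(nm)
    assert_scalar_number(v, nm)
    if (v < 0) stop_config(sprintf("`%s` must be >= 0.", nm))
  }
  if (!all(classes %in% names(mu_dct)) || !all(classes %in% names(sigma_dct))) {
    stop_config("`mu_dct` and `sigma_dct` must name both classes.")
  }
  if (any(sigma_dct < 0)) stop_config("`sigma_dct` entries must be >= 0.")
  assert_prob(outlier_rate, "outlier_rate")
  bad <- setdiff(outlier_modes, c("inflated_variance", "shifted_replicate"))
  if (length(bad) > 0L) {
    stop_config(sprintf("Unknown outlier mode(s): %s.", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      n_per_class = n_per_class, class_labels = class_labels,
      subtype_weights = subtype_weights,
      mu_dct = mu_dct, sigma_dct = sigma_dct,
      mu_u6 = mu_u6, sigma_u6 = sigma_u6,
      mu_d205 = mu_d205, sigma_d205 = sigma_d205,
      mu_d21 = mu_d21, sigma_d21 = sigma_d21,
      sigma_tech = sigma_tech,
      outlier_rate = outlier_rate, outlier_modes = outlier_modes,
      stage_weights = stage_weights, ct_range = ct_range,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  samples:", paste(sprintf("%s=%d", names(x$n_per_class), x$n_per_class),
                          collapse = ", "), "\n")
  cat("  dct375 :", paste(sprintf("%s ~ N(%.3g, %.3g^2)", names(x$mu_dct),
                                  x$mu_dct, x$sigma_dct[names(x$mu_dct)]),
                          collapse = ", "), "\n")
  cat(sprintf("  U6     : N(%.3g, %.3g^2); technical SD %.3g cycles\n",
              x$mu_u6, x$sigma_u6, x$sigma_tech))
  cat(sprintf("  outliers: rate %.3g (%s); seed %d\n", x$outlier_rate,
              paste(x$outlier_modes, collapse = "+"), x$seed))
  invisible(x)
}

# deterministic largest-remainder allocation of n samples to weighted bins
allocate_counts <- function(n, weights) {
  p <- weights / sum(weights)
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  setNames(as.integer(base), names(weights))
}

# per-sample RNG sub-stream: reproducible regardless of how many samples
# precede it in the cohort
sample_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(i)) %% 2147483647)
}

#' Simulate a cohort of Ct triplicates
#'
#' Draws, for each sample, a latent `dct375` score from its class Gaussian,
#' a U6 Ct, and latent miR205/miR21 offsets; sets the true target Cts so
#' that `CtU6 - Ct375` equals the drawn score; and adds independent
#' technical noise (SD `sigma_tech`) to each of the three replicates of each
#' assay. When `spec$outlier_rate > 0`, technical outliers are injected via
#' [inject_outliers()].
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer overriding `spec$seed`.
#'
#' @return A tibble with one row per replicate measurement and columns
#'   `sample_id`, `subtype`, `class`, `stage`, `assay`, `replicate`, `ct`.
#'   The tibble carries two attributes: `latent`, a per-sample tibble of the
#'   drawn latent quantities (used by tests as ground truth), and
#'   `corruption`, the injected-outlier record (see
#'   [corrupted_triplicates()]).
#' @examples
#' tbl <- simulate_cohort(cohort_spec(seed = 7))
#' dplyr::count(tbl, class, assay)
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  if (!inherits(spec, "cohort_spec")) stop_config("`spec` must be a cohort_spec.")
  seed <- as.integer(seed %||% spec$seed)

  # sample sheet: deterministic subtype allocation within each class
  sheet <- purrr::map_dfr(names(spec$n_per_class), function(cl) {
    subs <- names(spec$class_labels)[spec$class_labels == cl]
    counts <- allocate_counts(spec$n_per_class[[cl]], spec$subtype_weights[subs])
    tibble::tibble(subtype = rep(names(counts), counts), class = cl)
  })
  n <- nrow(sheet)
  sheet$sample_id <- sprintf("S%03d", seq_len(n))

  if (!is.null(spec$stage_weights)) {
    set.seed(sample_seed(seed, 0L))
    sheet$stage <- sample(names(spec$stage_weights), n, replace = TRUE,
                          prob = spec$stage_weights / sum(spec$stage_weights))
  } else {
    sheet$stage <- NA_character_
  }

  # per-sample draws into preallocated vectors (12 rows per sample:
  # 4 assays x 3 replicates); per-sample RNG sub-streams keep any one
  # sample reproducible independently of cohort size
  ct <- numeric(12L * n)
  dct375 <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(sample_seed(seed, i))
    cl <- sheet$class[i]
    dct375[i] <- rnorm(1, spec$mu_dct[[cl]], spec$sigma_dct[[cl]])
    u6 <- rnorm(1, spec$mu_u6, spec$sigma_u6)
    d205 <- rnorm(1, spec$mu_d205, spec$sigma_d205)
    d21 <- rnorm(1, spec$mu_d21, spec$sigma_d21)
    true_ct <- c(u6 - dct375[i], u6 - d205, u6 - d21, u6)
    ct[(i - 1L) * 12L + 1:12] <-
      rep(true_ct, each = 3L) + rnorm(12L, 0, spec$sigma_tech)
  }
  idx <- rep(seq_len(n), each = 12L)
  out <- tibble::tibble(
    sample_id = sheet$sample_id[idx],
    subtype = sheet$subtype[idx],
    class = sheet$class[idx],
    stage = sheet$stage[idx],
    assay = rep(rep(ct_assays(), each = 3L), times = n),
    replicate = rep(1:3, times = 4L * n),
    ct = ct
  )
  latent <- tibble::tibble(
    sample_id = sheet$sample_id, subtype = sheet$subtype,
    class = sheet$class, stage = sheet$stage, latent_dct375 = dct375
  )

  if (spec$outlier_rate > 0) {
    out <- inject_outliers(out, rate = spec$outlier_rate,
                           modes = spec$outlier_modes,
                           seed = sample_seed(seed, n + 1L))
  } else {
    attr(out, "corruption") <- empty_corruption()
  }
  attr(out, "latent") <- latent
  attr(out, "spec") <- spec
  validate_ct_table(out, spec$ct_range, check_range = TRUE)
  out
}

empty_corruption <- function() {
  tibble::tibble(sample_id = character(), assay = character(), mode = character())
}

#' Inject technical outliers into a Ct table
#'
#' Corrupts a Bernoulli(`rate`) selection of (sample, assay) triplicates.
#' `inflated_variance` multiplies the replicate deviations from the
#' triplicate mean by `inflate_factor`; `shifted_replicate` adds
#' `shift_cycles` to one randomly chosen replicate. The ground-truth record
#' of corrupted triplicates is attached for benchmarking the QC stage.
#'
#' @param table A raw Ct table (as from [simulate_cohort()]).
#' @param rate Corruption probability per triplicate, in \[0, 1\].
#' @param modes Subset of `"inflated_variance"`, `"shifted_replicate"`; the
#'   mode of each corrupted triplicate is drawn uniformly from `modes`.
#' @param seed Integer seed.
#' @param inflate_factor Multiplier on replicate deviations (default 8).
#' @param shift_cycles Offset added to the shifted replicate (default 4).
#'
#' @return The modified table; `attr(, "corruption")` (also via
#'   [corrupted_triplicates()]) lists the corrupted (sample, assay) pairs
#'   and the mode applied.
#' @export
inject_outliers <- function(table, rate, modes = c("inflated_variance",
                                                   "shifted_replicate"),
                            seed = 1L, inflate_factor = 8, shift_cycles = 4) {
  validate_ct_table(table)
  assert_prob(rate, "rate")
  bad <- setdiff(modes, c("inflated_variance", "shifted_replicate"))
  if (length(bad) > 0L) {
    stop_config(sprintf("Unknown outlier mode(s): %s.", paste(bad, collapse = ", ")))
  }
  keys <- dplyr::distinct(table, .data$sample_id, .data$assay)
  if (rate == 0) {
    attr(table, "corruption") <- empty_corruption()
    return(table)
  }
  set.seed(as.integer(seed))
  hit <- rbinom(nrow(keys), 1L, rate) == 1L
  corrupted <- keys[hit, , drop = FALSE]
  corrupted$mode <- sample(modes, nrow(corrupted), replace = TRUE)
  # one uniform draw per corrupted triplicate picks the shifted replicate
  corrupted$which_rep <- sample(1:3, nrow(corrupted), replace = TRUE)

  out <- table
  for (k in seq_len(nrow(corrupted))) {
    idx <- which(out$sample_id == corrupted$sample_id[k] &
                   out$assay == corrupted$assay[k])
    cts <- out$ct[idx]
    if (corrupted$mode[k] == "inflated_variance") {
      out$ct[idx] <- mean(cts) + (cts - mean(cts)) * inflate_factor
    } else {
      j <- corrupted$which_rep[k]
      out$ct[idx[j]] <- cts[j] + shift_cycles
    }
  }
  attr(out, "corruption") <- dplyr::select(corrupted, -"which_rep")
  out
}

#' Ground-truth corruption record of a Ct table
#'
#' @param table A Ct table returned by [simulate_cohort()] or
#'   [inject_outliers()].
#' @return Tibble with columns `sample_id`, `assay`, `mode` (empty when no
#'   outliers were injected).
#' @export
corrupted_triplicates <- function(table) {
  attr(table, "corruption") %||% empty_corruption()
}

#' Per-sample latent ground truth of a simulated cohort
#'
#' @param table A Ct table returned by [simulate_cohort()].
#' @return Tibble with one row per sample including the drawn latent
#'   `dct375` value, or `NULL` for tables not produced by the generator.
#' @export
cohort_latent <- function(table) attr(table, "latent")

#' Read and write raw Ct tables
#'
#' Plain-text round trip of the per-replicate Ct table; the delimiter is
#' auto-detected from the file extension (`.csv` vs anything else = TSV).
#'
#' @param table A raw Ct table.
#' @param path File path ending in `.tsv`, `.txt`, or `.csv`.
#' @return `write_ct_table()` returns `table` invisibly; `read_ct_table()`
#'   returns a tibble validated to have the canonical columns.
#' @export
write_ct_table <- function(table, path) {
  validate_ct_table(table)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(table, path)
  } else {
    readr::write_tsv(table, path)
  }
  invisible(table)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  cols <- readr::cols(
    sample_id = readr::col_character(), subtype = readr::col_character(),
    class = readr::col_character(), stage = readr::col_character(),
    assay = readr::col_character(), replicate = readr::col_integer(),
    ct = readr::col_double()
  )
  tbl <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, col_types = cols)
  } else {
    readr::read_tsv(path, col_types = cols)
  }
  validate_ct_table(tbl)
  tbl
}

#' Read a cohort specification from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose top-level keys
#'   are arguments of [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(cohort_spec))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    stop_config(sprintf("Unknown cohort_spec field(s): %s.", paste(bad, collapse = ", ")))
  }
  # YAML maps arrive as lists; coerce numeric/character vectors back
  raw <- purrr::map(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(cohort_spec, raw)
}
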