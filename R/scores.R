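#' Define a linear Ct-combination score
#'
#' Normalized qPCR expression scores are linear combinations of mean Cts,
#' `score = sum(coefficient * Ct_assay)`. Two presets cover the scores used
#' for lung-tumor classification:
#'
#' * [score_dct375()]: `dct375 = CtU6 - Ct375`, the U6-normalized miR375-3p
#'   score. Because lower Ct means higher abundance, a higher `dct375`
#'   means higher miR375-3p expression relative to U6.
#' * [score_dct205()]: `dct205 = (Ct205 - CtU6) - 0.8 * (Ct21 - CtU6)`, the
#'   weighted miR205-5p score, i.e. coefficients
#'   `{miR205: +1, miR21: -0.8, U6: -0.2}`.
#'
#' @param name Score name used in output tables.
#' @param terms Named numeric vector of per-assay coefficients.
#' @param description Optional free-text description.
#' @return An object of class `score_spec`.
#' @export
score_spec <- function(name, terms, description = NULL) {
  if (!is.numeric(terms) || is.null(names(terms)) || any(names(terms) == "")) {
    stop_config("`terms` must be a fully named numeric vector of coefficients.")
  }
  if (any(!is.finite(terms))) stop_config("Score coefficients must be finite.")
  structure(list(name = name, terms = terms,
                 description = description %||% name),
            class = "score_spec")
}

#' @rdname score_spec
#' @export
score_dct375 <- function() {
  score_spec("dct375", c(U6 = 1, miR375 = -1),
             "U6-normalized miR375-3p score (CtU6 - Ct375)")
}

#' @rdname score_spec
#' @export
score_dct205 <- function() {
  score_spec("dct205", c(miR205 = 1, miR21 = -0.8, U6 = -0.2),
             "weighted miR205-5p score ((Ct205 - CtU6) - 0.8 (Ct21 - CtU6))")
}

#' @export
print.score_spec <- function(x, ...) {
  cat(sprintf("<score_spec> %s = %s\n", x$name,
              paste(sprintf("%+g*Ct[%s]", x$terms, names(x$terms)),
                    collapse = " ")))
  invisible(x)
}

#' Compute one score from a sample's mean Cts
#'
#' @param mean_cts Named numeric vector of per-assay mean Cts (cycles).
#' @param spec A [score_spec()].
#' @param sample_id Optional identifier used in error messages.
#' @return The score value (exact arithmetic on the supplied means).
#' @examples
#' compute_score(c(U6 = 24, miR375 = 19), score_dct375()) # 5
#' @export
compute_score <- function(mean_cts, spec, sample_id = NULL) {
  needed <- names(spec$terms)
  missing <- needed[!(needed %in% names(mean_cts)) |
                      !is.finite(mean_cts[needed])]
  if (length(missing) > 0L) {
    stop_data(sprintf(
      "Missing or non-finite Ct for assay(s) %s%s.",
      paste(missing, collapse = ", "),
      if (is.null(sample_id)) "" else sprintf(" in sample '%s'", sample_id)
    ))
  }
  sum(spec$terms * mean_cts[needed])
}

#' Score every eligible sample of a QC'd cohort
#'
#' Computes each requested score from the post-QC triplicate-mean Cts. A
#' sample is excluded from a score when any assay that score needs was
#' flagged as a technical outlier (or is missing), unless
#' `score_outliers = TRUE`, in which case flagged samples are scored anyway
#' and marked `qc_outlier = TRUE` — mirroring plots where technical
#' outliers are drawn as crossed circles yet still classified.
#'
#' @param qc A `ct_qc` object from [qc_cohort()], or its `means` tibble.
#' @param specs A [score_spec()] or list of them.
#' @param score_outliers Score QC-flagged samples instead of dropping them.
#' @return A tibble (`sample_id`, `subtype`, `class`, `stage`, `score_name`,
#'   `value`, `qc_outlier`), one row per sample per score, ordered by
#'   `sample_id`.
#' @export
score_table <- function(qc, specs = score_dct375(), score_outliers = FALSE) {
  if (inherits(qc, "ct_qc")) qc <- qc$means
  if (inherits(specs, "score_spec")) specs <- list(specs)
  if (length(specs) == 0L) stop_config("`specs` must contain at least one score.")
  if (nrow(qc) == 0L) stop_data("No QC'd measurements to score.")

  meta_cols <- intersect(c("sample_id", "subtype", "class", "stage"), names(qc))
  purrr::map_dfr(specs, function(sp) {
    per_sample <- qc |>
      dplyr::filter(.data$assay %in% names(sp$terms)) |>
      dplyr::summarise(
        value = if (dplyr::n() == length(sp$terms) && all(is.finite(.data$mean_ct)))
          sum(sp$terms[.data$assay] * .data$mean_ct) else NA_real_,
        qc_outlier = any(.data$status == "outlier"),
        .by = dplyr::all_of(meta_cols)
      ) |>
      dplyr::mutate(score_name = sp$name)
    if (!score_outliers) {
      per_sample <- dplyr::filter(per_sample, !.data$qc_outlier)
    }
    dplyr::filter(per_sample, is.finite(.data$value))
  }) |>
    dplyr::select(dplyr::all_of(meta_cols), "score_name", "value", "qc_outlier") |>
    dplyr::arrange(.data$score_name, .data$sample_id)
}

#' Read score specifications from a YAML file
#'
#' The file maps score names either to the string `"dct375"`/`"dct205"`
#' (presets) or to a map of assay -> coefficient.
#'
#' @param path Path to a YAML file.
#' @return A list of [score_spec()] objects.
#' @export
read_score_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::imap(raw, function(val, nm) {
    if (is.character(val) && length(val) == 1L) {
      switch(val,
        dct375 = score_dct375(),
        dct205 = score_dct205(),
        stop_config(sprintf("Unknown score preset '%s'.", val))
      )
    } else {
      score_spec(nm, unlist(val))
    }
  })
}
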