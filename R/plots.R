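#' Rank-ordered score scatter with decision thresholds
#'
#' Samples are ordered by decreasing score along the x axis and colored by
#' their (known) class; horizontal lines mark the three odds thresholds,
#' so the four decision boxes read off as horizontal bands. QC-flagged
#' samples, when scored, are drawn with open crossed symbols.
#'
#' @param scores A score tibble from [score_table()] (or the `calls` of a
#'   `ct_run`).
#' @param thresholds A [threshold_set()].
#' @return A ggplot object.
#' @export
plot_score_scatter <- function(scores, thresholds) {
  value_col <- if ("value" %in% names(scores)) "value" else "score"
  df <- scores |>
    dplyr::arrange(dplyr::desc(.data[[value_col]])) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (!("qc_outlier" %in% names(df))) df$qc_outlier <- FALSE
  has_class <- "class" %in% names(df) && !all(is.na(df$class))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                        y = .data[[value_col]])) +
    ggplot2::geom_hline(
      yintercept = c(thresholds$chi_low, thresholds$chi_mid,
                     thresholds$chi_high),
      linetype = c("dashed", "solid", "dashed"), color = "grey40"
    )
  p <- if (has_class) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$class,
                                         shape = .data$qc_outlier), size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(shape = .data$qc_outlier), size = 2)
  }
  p +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 13),
                                guide = "none") +
    ggplot2::labs(x = "sample rank (decreasing score)", y = "score",
                  color = "class") +
    ggplot2::theme_minimal()
}

#' Class-conditional densities of a fitted model
#'
#' Histogram-free view of the fitted Gaussian class-conditional
#' probability density functions, optionally overlaid on the training
#' scores (rug marks).
#'
#' @param model A `gaussian_class_model`.
#' @param scores Optional score tibble to overlay as rug marks.
#' @return A ggplot object.
#' @export
plot_class_densities <- function(model, scores = NULL) {
  validate_model(model)
  lim <- range(model$mu_a + c(-4, 4) * model$sigma_a,
               model$mu_b + c(-4, 4) * model$sigma_b)
  grid <- seq(lim[1], lim[2], length.out = 400)
  df <- tibble::tibble(
    score = rep(grid, 2L),
    density = c(dnorm(grid, model$mu_a, model$sigma_a),
                dnorm(grid, model$mu_b, model$sigma_b)),
    class = rep(c(model$class_a, model$class_b), each = length(grid))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$density,
                                        color = .data$class)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "score", y = "probability density", color = "class") +
    ggplot2::theme_minimal()
  if (!is.null(scores) && nrow(scores) > 0L) {
    p <- p + ggplot2::geom_rug(
      data = scores,
      ggplot2::aes(x = .data$value, color = .data$class),
      inherit.aes = FALSE, alpha = 0.6
    )
  }
  p
}

#' ROC curve plot
#'
#' @param roc A `roc_result` from [empirical_roc()].
#' @return A ggplot object with the chance diagonal and the AUC in the
#'   subtitle.
#' @export
plot_roc <- function(roc) {
  ggplot2::ggplot(roc$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey50") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.3f", roc$auc)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.roc_result <- function(object, ...) plot_roc(object)

#' @export
autoplot.gaussian_class_model <- function(object, ...) {
  plot_class_densities(object, ...)
}

#' @export
autoplot.ct_run <- function(object, ...) {
  plot_score_scatter(object$calls, object$thresholds)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
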