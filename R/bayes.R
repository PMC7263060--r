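#' Fit a two-class Gaussian Bayes classifier on a scalar score
#'
#' Models the score distribution of each class as a Gaussian (the
#' triplicate-mean scores are well approximated by normal distributions)
#' and stores class priors. Class `a` is the low-score class (non-NE for
#' the miR375 score) and class `b` the high-score class (low-grade NE);
#' orientation is checked against the training means and a warning is
#' raised when `mu_b <= mu_a`.
#'
#' @param scores A score tibble from [score_table()] (or any data frame
#'   with `value` and a class column), or a numeric vector.
#' @param labels Class label per score; taken from `scores$class` when
#'   `scores` is a score tibble.
#' @param class_a,class_b The two class labels; `class_b` is the
#'   high-score, "positive" class.
#' @param priors `"equal"` (default, 0.5/0.5 — the odds boxes are then
#'   symmetric in the likelihood ratio), `"empirical"` (training class
#'   frequencies), or a named numeric vector summing to 1.
#'
#' @return An object of class `gaussian_class_model` with per-class mean,
#'   SD (denominator n-1), prior, and training count.
#' @examples
#' m <- fit_gaussian_classifier(c(0, 2, 4, 6), c("nonNE", "nonNE", "NE", "NE"))
#' tidy(m)
#' @export
fit_gaussian_classifier <- function(scores, labels = NULL, class_a = "nonNE",
                                    class_b = "NE", priors = "equal") {
  if (is.data.frame(scores)) {
    labels <- labels %||% scores$class
    scores <- scores$value
  }
  if (length(scores) != length(labels)) {
    stop_config("`scores` and `labels` must have equal length.")
  }
  xa <- scores[labels == class_a]
  xb <- scores[labels == class_b]
  if (length(xa) < 2L || length(xb) < 2L) {
    stop_data("Each class needs at least 2 samples to fit the model.")
  }
  sa <- sd(xa); sb <- sd(xb)
  if (sa == 0 || sb == 0) {
    stop_data("Degenerate model: a class has zero within-class variance.")
  }
  pr <- if (identical(priors, "equal")) {
    c(0.5, 0.5)
  } else if (identical(priors, "empirical")) {
    c(length(xa), length(xb)) / (length(xa) + length(xb))
  } else {
    p <- unname(priors[c(class_a, class_b)])
    if (any(is.na(p)) || abs(sum(p) - 1) > 1e-8 || any(p <= 0)) {
      stop_config("Numeric `priors` must name both classes and sum to 1.")
    }
    p
  }
  model <- structure(
    list(class_a = class_a, class_b = class_b,
         mu_a = mean(xa), mu_b = mean(xb), sigma_a = sa, sigma_b = sb,
         prior_a = pr[1], prior_b = pr[2],
         n_a = length(xa), n_b = length(xb)),
    class = "gaussian_class_model"
  )
  if (model$mu_b <= model$mu_a) {
    warn(sprintf(
      "Class '%s' does not have the higher training mean (%.3g <= %.3g); check score orientation.",
      class_b, model$mu_b, model$mu_a
    ))
  }
  model
}

validate_model <- function(model) {
  if (!inherits(model, "gaussian_class_model")) {
    stop_config("`model` must be a gaussian_class_model.")
  }
  invisible(model)
}

#' @export
print.gaussian_class_model <- function(x, ...) {
  cat(sprintf(
    "<gaussian_class_model> %s ~ N(%.3f, %.3f^2) [prior %.2f, n=%d] vs %s ~ N(%.3f, %.3f^2) [prior %.2f, n=%d]\n",
    x$class_a, x$mu_a, x$sigma_a, x$prior_a, x$n_a,
    x$class_b, x$mu_b, x$sigma_b, x$prior_b, x$n_b
  ))
  invisible(x)
}

#' @export
tidy.gaussian_class_model <- function(x, ...) {
  tibble::tibble(
    class = c(x$class_a, x$class_b),
    role = c("a (low score)", "b (high score)"),
    mu = c(x$mu_a, x$mu_b), sigma = c(x$sigma_a, x$sigma_b),
    prior = c(x$prior_a, x$prior_b), n = c(x$n_a, x$n_b)
  )
}

#' @export
glance.gaussian_class_model <- function(x, ...) {
  tibble::tibble(
    delta_mu = x$mu_b - x$mu_a,
    pooled_d = (x$mu_b - x$mu_a) /
      sqrt(((x$n_a - 1) * x$sigma_a^2 + (x$n_b - 1) * x$sigma_b^2) /
             (x$n_a + x$n_b - 2)),
    bayes_max_accuracy = bayes_max_accuracy(x),
    n = x$n_a + x$n_b
  )
}

# log posterior odds (b:a) at x; include_priors = FALSE gives the pure
# likelihood ratio
log_odds <- function(model, x, include_priors = TRUE) {
  lo <- dnorm(x, model$mu_b, model$sigma_b, log = TRUE) -
    dnorm(x, model$mu_a, model$sigma_a, log = TRUE)
  if (include_priors) lo <- lo + log(model$prior_b) - log(model$prior_a)
  lo
}

#' Posterior odds of the high-score class
#'
#' `odds(b:a) = prior_b * phi(x; mu_b, sigma_b) / (prior_a * phi(x; mu_a,
#' sigma_a))`, with `phi` the Gaussian density, on the natural scale.
#'
#' @param model A [fit_gaussian_classifier()] model.
#' @param x Score value(s); must be finite.
#' @param include_priors If `FALSE`, returns the pure likelihood ratio.
#' @return Numeric vector of odds, same length as `x`.
#' @export
posterior_odds <- function(model, x, include_priors = TRUE) {
  validate_model(model)
  if (any(!is.finite(x))) stop_data("Scores must be finite to compute odds.")
  exp(log_odds(model, x, include_priors))
}

#' Decision thresholds at given posterior odds
#'
#' Solves the score values where the posterior odds (b:a) equal
#' `1/odds_level`, 1, and `odds_level` — the three cut-points
#' (chi_10:90, chi, chi_90:10 for the default 9, i.e. 90:10 odds) that
#' carve the score axis into the four decision boxes. The log-odds is
#' linear in the score for equal class SDs (closed form) and quadratic
#' otherwise; the root between the class means is taken for the central
#' threshold, and the outer thresholds are taken on the monotone branch of
#' the log-odds containing it. Each solution is verified to satisfy its
#' odds equation to 1e-9.
#'
#' @param model A [fit_gaussian_classifier()] model.
#' @param odds_level Odds defining the high-confidence cut-points (> 1).
#' @param include_priors Include the class priors in the odds.
#' @return A `threshold_set` (see [threshold_set()]).
#' @examples
#' m <- structure(list(class_a = "a", class_b = "b", mu_a = 0, mu_b = 4,
#'                     sigma_a = 1, sigma_b = 1, prior_a = 0.5, prior_b = 0.5,
#'                     n_a = 10, n_b = 10), class = "gaussian_class_model")
#' solve_thresholds(m) # 2 -/+ log(9)/4 and 2
#' @export
solve_thresholds <- function(model, odds_level = 9, include_priors = TRUE) {
  validate_model(model)
  if (!is.numeric(odds_level) || odds_level <= 1) {
    stop_config("`odds_level` must be > 1.")
  }
  ma <- model$mu_a; sa <- model$sigma_a
  mb <- model$mu_b; sb <- model$sigma_b
  k <- if (include_priors) log(model$prior_b) - log(model$prior_a) else 0

  solve_level <- function(target) {
    # log_odds(x) = A x^2 + B x + C0; solve log_odds(x) = target
    A <- 1 / (2 * sa^2) - 1 / (2 * sb^2)
    B <- mb / sb^2 - ma / sa^2
    C0 <- ma^2 / (2 * sa^2) - mb^2 / (2 * sb^2) + log(sa / sb) + k
    if (abs(A) < 1e-14) {
      if (abs(B) < 1e-14) stop_solve("Log-odds is constant; thresholds undefined.")
      return((target - C0) / B)
    }
    disc <- B^2 - 4 * A * (C0 - target)
    if (disc < 0) {
      stop_solve(sprintf(
        "No real threshold at odds level %.3g (discriminant %.3g).",
        exp(target), disc
      ))
    }
    sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  }

  # central cut: prefer the even-odds root between the class means; with
  # skewed priors it may shift outside, in which case take the root where
  # the log-odds is increasing (the single-cut decision geometry)
  mid_roots <- solve_level(0)
  inside <- mid_roots[mid_roots >= min(ma, mb) & mid_roots <= max(ma, mb)]
  chi_mid <- if (length(inside) > 0L) {
    inside[1]
  } else {
    slope <- (mid_roots - ma) / sa^2 - (mid_roots - mb) / sb^2
    rising <- mid_roots[slope > 0]
    if (length(rising) == 0L) {
      stop_solve("No even-odds threshold with increasing log-odds exists.")
    }
    rising[which.min(abs(rising - (ma + mb) / 2))]
  }

  # monotone branch of the log-odds through chi_mid: bounded by the
  # stationary point of the quadratic (if any)
  if (abs(1 / sa^2 - 1 / sb^2) > 1e-14) {
    x_star <- (mb / sb^2 - ma / sa^2) / (1 / sb^2 - 1 / sa^2)
    branch <- if (chi_mid >= x_star) c(x_star, Inf) else c(-Inf, x_star)
  } else {
    branch <- c(-Inf, Inf)
  }
  pick <- function(roots, level_name) {
    ok <- roots[roots >= branch[1] & roots <= branch[2]]
    if (length(ok) == 0L) {
      stop_solve(sprintf(
        "The %s threshold does not exist on the monotone branch of the log-odds.",
        level_name
      ))
    }
    ok[which.min(abs(ok - chi_mid))]
  }
  L <- log(odds_level)
  chi_low <- pick(solve_level(-L), "low-odds")
  chi_high <- pick(solve_level(L), "high-odds")

  resid <- abs(log_odds(model, c(chi_low, chi_mid, chi_high), include_priors) -
                 c(-L, 0, L))
  if (any(resid > 1e-9)) {
    stop_solve("Threshold solutions failed the 1e-9 odds verification.")
  }
  threshold_set(chi_low, chi_mid, chi_high, odds_level)
}

#' Construct a set of decision thresholds
#'
#' Use this to supply externally established cut-points — e.g. the
#' published training-set thresholds available via
#' [reference_thresholds()] — instead of fitting.
#'
#' @param chi_low,chi_mid,chi_high Score cut-points with
#'   `chi_low <= chi_mid <= chi_high`: odds 1/`odds_level`, even odds,
#'   `odds_level`.
#' @param odds_level The odds the outer thresholds represent (default 9,
#'   i.e. 90:10).
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(chi_low, chi_mid, chi_high, odds_level = 9) {
  for (nm in c("chi_low", "chi_mid", "chi_high")) assert_scalar_number(get(nm), nm)
  if (!(chi_low <= chi_mid && chi_mid <= chi_high)) {
    stop_config("Thresholds must satisfy chi_low <= chi_mid <= chi_high.")
  }
  structure(list(chi_low = chi_low, chi_mid = chi_mid, chi_high = chi_high,
                 odds_level = odds_level),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf(
    "<threshold_set> chi_%d:%d = %.4g | chi = %.4g | chi_%d:%d = %.4g\n",
    round(100 / (x$odds_level + 1)), round(100 * x$odds_level / (x$odds_level + 1)),
    x$chi_low, x$chi_mid,
    round(100 * x$odds_level / (x$odds_level + 1)), round(100 / (x$odds_level + 1)),
    x$chi_high
  ))
  invisible(x)
}

#' @export
tidy.threshold_set <- function(x, ...) {
  tibble::tibble(
    threshold = c("chi_low", "chi_mid", "chi_high"),
    value = c(x$chi_low, x$chi_mid, x$chi_high),
    odds_b_over_a = c(1 / x$odds_level, 1, x$odds_level)
  )
}

#' Assign scores to the four odds boxes
#'
#' The thresholds split the score axis into four decision boxes:
#' `strong_a` (x <= chi_low; class a at better than `odds_level`:1),
#' `weak_a` (chi_low < x <= chi_mid), `weak_b` (chi_mid < x <= chi_high),
#' and `strong_b` (x > chi_high). Values exactly at a threshold fall in
#' the lower box.
#'
#' @param scores A score tibble from [score_table()], or a numeric vector.
#' @param thresholds A `threshold_set`.
#' @param model Optional `gaussian_class_model`; when supplied, the
#'   posterior odds and posterior probability of class b are filled in.
#' @return A tibble of calls: the input metadata plus `score`, `box`,
#'   `predicted_class` (`"a"`/`"b"`), and — given a model —
#'   `odds_b_over_a` and `posterior_b`. A numeric input yields one row per
#'   value.
#' @examples
#' classify_samples(c(0.5, 2, 5.5), reference_thresholds())$box
#' @export
classify_samples <- function(scores, thresholds, model = NULL) {
  if (!inherits(thresholds, "threshold_set")) {
    stop_config("`thresholds` must be a threshold_set.")
  }
  if (is.data.frame(scores)) {
    meta <- dplyr::select(scores, -dplyr::any_of(c("value")))
    x <- scores$value
  } else {
    meta <- tibble::tibble(sample_id = sprintf("x%d", seq_along(scores)))
    if ("qc_outlier" %in% names(meta)) meta$qc_outlier <- FALSE
    x <- as.numeric(scores)
  }
  if (any(!is.finite(x))) stop_data("Scores must be finite to classify.")
  box <- dplyr::case_when(
    x > thresholds$chi_high ~ "strong_b",
    x > thresholds$chi_mid ~ "weak_b",
    x > thresholds$chi_low ~ "weak_a",
    .default = "strong_a"
  )
  out <- dplyr::bind_cols(
    meta,
    tibble::tibble(
      score = x,
      box = factor(box, levels = c("strong_a", "weak_a", "weak_b", "strong_b")),
      predicted_class = ifelse(box %in% c("strong_b", "weak_b"), "b", "a")
    )
  )
  if (!is.null(model)) {
    validate_model(model)
    out$odds_b_over_a <- posterior_odds(model, x)
    out$posterior_b <- out$odds_b_over_a / (1 + out$odds_b_over_a)
  }
  out
}

#' Bayes maximum accuracy of a two-class Gaussian model
#'
#' The best accuracy any classifier can achieve under the model,
#' `integral of max(prior_a * phi_a, prior_b * phi_b)`, computed
#' piecewise-analytically: the density-ratio crossing points (roots of the
#' log-odds) partition the axis into intervals on which one weighted
#' density dominates, and each piece integrates to a difference of
#' Gaussian CDFs.
#'
#' @param model A `gaussian_class_model`.
#' @return Accuracy in \[max(prior_a, prior_b), 1\]; 0.5 for
#'   indistinguishable equal-prior classes.
#' @examples
#' m <- fit_gaussian_classifier(c(-1, 1, 1.5, 2.5), c("a", "a", "b", "b"),
#'                              class_a = "a", class_b = "b")
#' bayes_max_accuracy(m)
#' @export
bayes_max_accuracy <- function(model) {
  validate_model(model)
  ma <- model$mu_a; sa <- model$sigma_a
  mb <- model$mu_b; sb <- model$sigma_b
  A <- 1 / (2 * sa^2) - 1 / (2 * sb^2)
  B <- mb / sb^2 - ma / sa^2
  C0 <- ma^2 / (2 * sa^2) - mb^2 / (2 * sb^2) + log(sa / sb) +
    log(model$prior_b) - log(model$prior_a)
  cross <- if (abs(A) < 1e-14) {
    if (abs(B) < 1e-14) numeric() else -C0 / B
  } else {
    disc <- B^2 - 4 * A * C0
    if (disc <= 0) numeric() else sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  }
  bounds <- c(-Inf, cross, Inf)
  mass <- function(lo, hi, mu, sigma, prior) {
    prior * (pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma))
  }
  total <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    mid <- if (is.infinite(lo) && is.infinite(hi)) (ma + mb) / 2
      else if (is.infinite(lo)) hi - 1 else if (is.infinite(hi)) lo + 1
      else (lo + hi) / 2
    b_wins <- log_odds(model, mid) > 0
    total <- total + if (b_wins) mass(lo, hi, mb, sb, model$prior_b)
      else mass(lo, hi, ma, sa, model$prior_a)
  }
  total
}

#' Read and write classifier models and thresholds as JSON
#'
#' Field-for-field serialization so that train and classify runs can
#' exchange fitted models and cut-points as plain text.
#'
#' @param model A `gaussian_class_model`.
#' @param thresholds A `threshold_set`.
#' @param path JSON file path.
#' @return Readers return the reconstructed object; writers their input,
#'   invisibly.
#' @export
write_model_json <- function(model, path) {
  validate_model(model)
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(raw, class = "gaussian_class_model")
}

#' @rdname write_model_json
#' @export
write_thresholds_json <- function(thresholds, path) {
  if (!inherits(thresholds, "threshold_set")) {
    stop_config("`thresholds` must be a threshold_set.")
  }
  jsonlite::write_json(unclass(thresholds), path, auto_unbox = TRUE, digits = NA)
  invisible(thresholds)
}

#' @rdname write_model_json
#' @export
read_thresholds_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(raw$chi_low, raw$chi_mid, raw$chi_high, raw$odds_level)
}
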