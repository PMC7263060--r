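test_that("fitting recovers hand-computed class means and SDs", {
  m <- fit_gaussian_classifier(c(0, 2, 4, 6), c("nonNE", "nonNE", "NE", "NE"))
  expect_equal(m$mu_a, 1)
  expect_equal(m$mu_b, 5)
  expect_equal(m$sigma_a, sqrt(2))
  expect_equal(m$sigma_b, sqrt(2))
  expect_equal(c(m$prior_a, m$prior_b), c(0.5, 0.5))

  emp <- fit_gaussian_classifier(c(0, 2, 4, 6, 8, 10),
                                 c("nonNE", "nonNE", "NE", "NE", "NE", "NE"),
                                 priors = "empirical")
  expect_equal(c(emp$prior_a, emp$prior_b), c(2, 4) / 6)
})

test_that("degenerate and undersized training sets are rejected", {
  expect_error(fit_gaussian_classifier(c(1, 1, 5, 5), c("nonNE", "nonNE", "NE", "NE")),
               class = "ctbayes_data_error")
  expect_error(fit_gaussian_classifier(c(1, 5, 6), c("nonNE", "NE", "NE")),
               class = "ctbayes_data_error")
})

test_that("a reversed score orientation triggers a warning, not an error", {
  expect_warning(
    fit_gaussian_classifier(c(5, 6, 1, 2), c("nonNE", "nonNE", "NE", "NE")),
    "orientation"
  )
})

test_that("fitting recovers the generating parameters from large samples", {
  set.seed(2024)
  x <- c(rnorm(10000, 0.9, 1.3), rnorm(10000, 5.8, 1.3))
  lab <- rep(c("nonNE", "NE"), each = 10000)
  m <- fit_gaussian_classifier(x, lab)
  expect_lt(abs(m$mu_a - 0.9), 0.05)
  expect_lt(abs(m$mu_b - 5.8), 0.05)
  expect_lt(abs(m$sigma_a - 1.3), 0.05)
  expect_lt(abs(m$sigma_b - 1.3), 0.05)
})

test_that("posterior odds match Gaussian closed forms", {
  m <- make_model(0, 1, 4, 1)
  expect_equal(posterior_odds(m, 2), 1)
  # log-odds = 4x - 8: odds 9 at x = (8 + ln 9) / 4
  expect_equal(posterior_odds(m, (8 + log(9)) / 4), 9, tolerance = 1e-12)
  expect_equal(posterior_odds(m, 4), exp(8), tolerance = 1e-12)
  expect_error(posterior_odds(m, Inf), class = "ctbayes_data_error")

  skew <- make_model(0, 1, 4, 1, prior_a = 0.9)
  expect_equal(posterior_odds(skew, 2), 1 / 9, tolerance = 1e-12)
  expect_equal(posterior_odds(skew, 2, include_priors = FALSE), 1,
               tolerance = 1e-12)
})

test_that("posterior odds increase monotonically between the class means", {
  m <- make_model(0.9, 1.3, 5.8, 1.3)
  x <- seq(0.9, 5.8, length.out = 200)
  expect_true(all(diff(posterior_odds(m, x)) > 0))
})

test_that("equal-variance thresholds match the closed form to solver precision", {
  m <- make_model(0, 1, 4, 1)
  th <- solve_thresholds(m, odds_level = 9)
  expect_equal(th$chi_mid, 2, tolerance = 1e-12)
  expect_equal(th$chi_high, (8 + log(9)) / 4, tolerance = 1e-12)
  expect_equal(th$chi_low, (8 - log(9)) / 4, tolerance = 1e-12)

  # general closed form: chi = (mu_a + mu_b)/2 + sigma^2 * target / delta_mu
  set.seed(11)
  for (i in 1:25) {
    mu_a <- runif(1, -3, 3); d <- runif(1, 0.5, 6); s <- runif(1, 0.2, 3)
    L <- runif(1, 2, 50)
    m <- make_model(mu_a, s, mu_a + d, s)
    th <- solve_thresholds(m, odds_level = L)
    mid <- mu_a + d / 2
    expect_equal(th$chi_mid, mid, tolerance = 1e-12)
    expect_equal(th$chi_high, mid + s^2 * log(L) / d, tolerance = 1e-12)
    expect_equal(th$chi_low, mid - s^2 * log(L) / d, tolerance = 1e-12)
  }
})

test_that("unequal-variance thresholds agree with an independent bisection oracle", {
  bisect_root <- function(f, lo, hi, tol = 1e-12) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  set.seed(3)
  for (i in 1:20) {
    m <- make_model(runif(1, -1, 1), runif(1, 0.8, 1.6),
                    runif(1, 3, 6), runif(1, 0.8, 1.6))
    th <- solve_thresholds(m, odds_level = 9)
    f <- function(t) function(x) log(posterior_odds(m, x)) - t
    # bracket each root around the solver's answer
    for (pair in list(c(th$chi_low, -log(9)), c(th$chi_mid, 0),
                      c(th$chi_high, log(9)))) {
      oracle <- bisect_root(f(pair[2]), pair[1] - 0.5, pair[1] + 0.5)
      expect_equal(pair[1], oracle, tolerance = 1e-8)
    }
  }
})

test_that("solved thresholds satisfy their odds equations and ordering", {
  set.seed(8)
  for (i in 1:50) {
    m <- make_model(runif(1, -2, 2), runif(1, 0.3, 2.5),
                    runif(1, 2.5, 7), runif(1, 0.3, 2.5),
                    prior_a = runif(1, 0.2, 0.8))
    th <- tryCatch(solve_thresholds(m, odds_level = 9),
                   ctbayes_solve_error = function(e) NULL)
    if (is.null(th)) {
      # a refusal is only legitimate when the rising branch of the
      # log-odds quadratic genuinely cannot span [-log 9, log 9]
      A <- 1 / (2 * m$sigma_a^2) - 1 / (2 * m$sigma_b^2)
      B <- m$mu_b / m$sigma_b^2 - m$mu_a / m$sigma_a^2
      l_star <- log(posterior_odds(m, -B / (2 * A)))
      expect_true((A < 0 && l_star < log(9)) ||
                    (A > 0 && l_star > -log(9)))
      next
    }
    expect_true(th$chi_low <= th$chi_mid && th$chi_mid <= th$chi_high)
    lo <- log(posterior_odds(m, c(th$chi_low, th$chi_mid, th$chi_high)))
    expect_lt(max(abs(lo - c(-log(9), 0, log(9)))), 1e-9)
  }
})

test_that("an unreachable odds level raises a threshold-solve error", {
  # wider low class: the log-odds is a downward parabola whose maximum
  # never reaches log(9)
  m <- make_model(0, 2, 0.5, 1)
  expect_error(solve_thresholds(m, odds_level = 9),
               class = "ctbayes_solve_error")
})

test_that("box assignment follows the published cut-points and tie convention", {
  th <- reference_thresholds()
  expect_equal(as.character(classify_samples(5.5, th)$box), "strong_b")
  expect_equal(as.character(classify_samples(2.0, th)$box), "weak_a")
  expect_equal(as.character(classify_samples(0.5, th)$box), "strong_a")
  expect_equal(as.character(classify_samples(3.5, th)$box), "weak_b")
  # values exactly at a threshold fall into the lower box
  expect_equal(as.character(classify_samples(c(1.4, 3, 4.9), th)$box),
               c("strong_a", "weak_a", "weak_b"))
  expect_error(classify_samples(NaN, th), class = "ctbayes_data_error")
})

test_that("classification fills posterior odds consistent with the model", {
  m <- make_model(0, 1, 4, 1)
  th <- solve_thresholds(m)
  calls <- classify_samples(c(1, 2, 3), th, model = m)
  expect_equal(calls$odds_b_over_a, posterior_odds(m, c(1, 2, 3)))
  expect_equal(calls$posterior_b, calls$odds_b_over_a / (1 + calls$odds_b_over_a))
})

test_that("Bayes maximum accuracy matches closed forms and a quadrature oracle", {
  expect_equal(bayes_max_accuracy(make_model(1, 1, 1, 1)), 0.5, tolerance = 1e-12)
  # equal variances at separation d: accuracy = 1 - pnorm(-d/2)
  for (d in c(0.5, 1, 2, 4)) {
    expect_equal(bayes_max_accuracy(make_model(0, 1, d, 1)),
                 1 - pnorm(-d / 2), tolerance = 1e-9)
  }
  # unequal variances against direct numerical integration
  grid_oracle <- function(m) {
    f <- function(x) pmax(m$prior_a * dnorm(x, m$mu_a, m$sigma_a),
                          m$prior_b * dnorm(x, m$mu_b, m$sigma_b))
    integrate(f, -50, 50, rel.tol = 1e-10)$value
  }
  for (m in list(make_model(0, 1, 4, 2), make_model(0, 2.39, 5.57, 1.83),
                 make_model(-1, 0.5, 1, 1.7, prior_a = 0.3))) {
    expect_equal(bayes_max_accuracy(m), grid_oracle(m), tolerance = 1e-6)
  }
})

test_that("Bayes maximum accuracy is bounded below by the larger prior", {
  set.seed(5)
  for (i in 1:30) {
    m <- make_model(runif(1, -2, 2), runif(1, 0.3, 3),
                    runif(1, -2, 2), runif(1, 0.3, 3),
                    prior_a = runif(1, 0.1, 0.9))
    expect_gte(bayes_max_accuracy(m) + 1e-12, max(m$prior_a, m$prior_b))
  }
})

test_that("Monte-Carlo accuracy at the even-odds cut matches the Bayes bound", {
  m <- make_model(0.13, 2.39, 5.57, 1.83)
  th <- solve_thresholds(m)
  set.seed(77)
  n <- 1e5
  x <- c(rnorm(n / 2, m$mu_a, m$sigma_a), rnorm(n / 2, m$mu_b, m$sigma_b))
  truth <- rep(c("a", "b"), each = n / 2)
  pred <- ifelse(x > th$chi_mid, "b", "a")
  expect_equal(mean(pred == truth), bayes_max_accuracy(m), tolerance = 0.005)
})

test_that("models and thresholds round-trip through JSON losslessly", {
  m <- make_model(0.127, 2.388, 5.574, 1.828, n_a = 27L, n_b = 31L)
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  back <- read_model_json(f)
  expect_equal(unclass(back)[names(unclass(m))], unclass(m))

  th <- solve_thresholds(m)
  g <- withr::local_tempfile(fileext = ".json")
  write_thresholds_json(th, g)
  th2 <- read_thresholds_json(g)
  expect_equal(unclass(th2), unclass(th))
})
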