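test_that("the stratified split is disjoint, exhaustive and reproducible", {
  sim <- simulate_cohort(simulation_config(n_patients = 27, seed = 4))
  co <- sim$cohort
  sp <- split_cohort(co, 0.8, seed = 9)
  expect_equal(length(sp$train), 22)
  expect_equal(length(sp$test), 5)
  expect_setequal(c(sp$train, sp$test), co$clinical$id)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_cohort(co, 0.8, seed = 9))
  expect_false(identical(sp, split_cohort(co, 0.8, seed = 10)))
  # stratification keeps deaths in both halves when possible
  died <- outcome_gos(co) == 1
  expect_gt(sum(died[sp$train]), 0)
  expect_gt(sum(died[sp$test]), 0)

  two <- new_cohort(tiny_cohort()$clinical[1:2, ])
  sp2 <- split_cohort(two, 0.5, seed = 1)
  expect_equal(lengths(sp2[c("train", "test")]), c(train = 1L, test = 1L))
  expect_error(split_cohort(new_cohort(tiny_cohort()$clinical[1, ]), 0.8, 1),
               "at least 2")
  expect_error(split_cohort(two, 1.2, 1), "between 0 and 1")
})

test_that("reported t values equal coefficient / SE", {
  tab <- coef_table(c(a = -9.29, b = 2), c(4.77, 0.5))
  expect_equal(tab$t_value, c(-9.29 / 4.77, 4))
  set.seed(21)
  x <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  y <- rbinom(80, 1, plogis(0.5 + x$x1))
  fit <- fit_outcome(x, y)
  expect_equal(fit$table$t_value, fit$table$value / fit$table$std_error,
               tolerance = 1e-9)
})

test_that("the logistic fit recovers strong generating coefficients", {
  set.seed(31)
  n <- 500
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  beta <- c(-0.5, 1.5, -1.0, 0)
  eta <- beta[1] + as.matrix(X) %*% beta[2:4]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_outcome(X, y)
  expect_true(fit$converged)
  expect_false(fit$separation)
  expect_true(all(abs(fit$coefficients - beta) < 3 * fit$se))
  expect_true(all(fit$fitted >= 0 & fit$fitted <= 1))
})

test_that("logit and probit fitted probabilities agree in rank", {
  # both links are monotone in the single linear predictor, so the fitted
  # probabilities must be perfectly rank-correlated
  set.seed(32)
  X <- data.frame(x1 = rnorm(120))
  y <- rbinom(120, 1, plogis(0.3 + 0.8 * X$x1))
  f1 <- fit_outcome(X, y, link = "logit")
  f2 <- fit_outcome(X, y, link = "probit")
  expect_equal(cor(f1$fitted, f2$fitted, method = "spearman"), 1)
})

test_that("separation is flagged and the ridge refit stays finite", {
  X <- data.frame(x = c(-2, -1.5, -1, 1, 1.5, 2, -1.2, 1.2))
  y <- c(0, 0, 0, 1, 1, 1, 0, 1)  # perfectly separated
  fit <- fit_outcome(X, y)
  expect_true(fit$separation)
  expect_true(fit$ridge_used)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(fit$se)))
  # with the fallback disabled the raw fit is returned but stays flagged
  raw <- fit_outcome(X, y, ridge = 0)
  expect_true(raw$separation)
  expect_false(raw$ridge_used)
})

test_that("fit_outcome validates its inputs", {
  X <- data.frame(a = rnorm(20), b = rep(1, 20))
  y <- rbinom(20, 1, 0.5)
  expect_error(fit_outcome(X, y), "zero-variance")
  expect_error(fit_outcome(data.frame(a = rnorm(3)), c(0, 1, 1, 0)),
               "differ in length")
  expect_error(fit_outcome(data.frame(a = rnorm(3), b = rnorm(3),
                                      c = rnorm(3)), c(0, 1, 1)),
               "more terms")
  expect_error(fit_outcome(X, y, terms = "zz"), "not present")
})

test_that("backward elimination drops a pure-noise predictor", {
  set.seed(33)
  n <- 400
  X <- data.frame(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * X$signal))
  sel <- select_terms(X, y, t_cut = 1.5)
  expect_equal(sel$terms, "signal")
  expect_warning(
    out <- select_terms(data.frame(noise = rnorm(40)),
                        rbinom(40, 1, 0.5), t_cut = 50),
    "intercept-only")
  expect_length(out$terms, 0)
})

test_that("marginal pre-screening keeps informative blocks", {
  set.seed(34)
  n <- 300
  X <- data.frame(a1 = rnorm(n), a2 = rnorm(n), b1 = rnorm(n), b2 = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * X$a1))
  kept <- prescreen_terms(X, y, blocks = list(a = c("a1", "a2"),
                                              b = c("b1", "b2")))
  expect_true("a1" %in% kept)
  expect_false(any(c("b1", "b2") %in% kept))
})

test_that("predict_prob applies the inverse link", {
  fit <- structure(list(coefficients = c("(Intercept)" = 0, x = 1),
                        terms = "x", link = "logit"),
                   class = "outcome_fit")
  expect_equal(predict_prob(fit, c(x = 0)), 0.5)
  expect_equal(predict_prob(fit, c(x = 50)), 1, tolerance = 1e-9)
  expect_equal(predict_prob(fit, c(x = log(0.87 / 0.13))), 0.87)
  expect_error(predict_prob(fit, c(z = 1)), "missing model term")
})

test_that("evaluation counts the confusion table with a strict threshold", {
  ev <- evaluate_predictions(c(1, 1, 1), c(1, 1, 1))
  expect_equal(ev$accuracy, 1)
  # exactly 0.5 is classified as non-survival
  ev <- evaluate_predictions(c(0.5, 0.5), c(0, 1))
  expect_equal(ev$tn, 1)
  expect_equal(ev$fn, 1)
  ev <- evaluate_predictions(c(0.9, 0.2, 0.6, 0.4), c(1, 1, 0, 0))
  expect_equal(ev[c("tp", "fp", "tn", "fn")],
               list(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  expect_equal(ev$misclassified, c(2L, 3L))
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "empty")
})

test_that("the ordinal GOS variant fits proportional odds on all 5 levels", {
  skip_if_not_installed("MASS")
  set.seed(35)
  n <- 300
  x <- rnorm(n)
  latent <- 1.2 * x + rlogis(n)
  gos <- as.integer(cut(latent, c(-Inf, -1.5, -0.5, 0.5, 1.5, Inf)))
  ord <- fit_gos_ordinal(data.frame(x = x), gos)
  expect_equal(ord$table$term, "x")
  # slope recovered with the right sign and within 3 SEs
  expect_lt(abs(ord$table$value - 1.2), 3 * ord$table$std_error)
  expect_length(ord$zeta, 4)
  expect_error(fit_gos_ordinal(data.frame(x = x), rep(6, n)), "within")
})

test_that("the cohort-level model chain runs end to end", {
  sim <- simulate_cohort(simulation_config(n_patients = 30, seed = 6,
                                           missing_rate = 0))
  m <- fit_cohort_outcome(sim$cohort, degree = 2, seed = 6)
  expect_s3_class(m, "outcome_model")
  expect_true(all(m$fitted_all$probability >= 0 & m$fitted_all$probability <= 1))
  expect_setequal(c(m$train, m$test), m$fitted_all$patient_id)
  expect_equal(m$fit$table$t_value,
               m$fit$table$value / m$fit$table$std_error, tolerance = 1e-9)
})
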