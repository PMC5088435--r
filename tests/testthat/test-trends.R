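test_that("the discrete orthonormal basis matches hand constructions", {
  B <- trend_basis(3, 1)
  expect_equal(B[, "T0"], rep(1 / sqrt(3), 3))
  expect_equal(B[, "L"], c(-1, 0, 1) / sqrt(2))
  expect_equal(trend_basis(7, 0)[, 1], rep(1 / sqrt(7), 7))
  B <- trend_basis(5, 3)
  expect_equal(crossprod(B), diag(4), ignore_attr = TRUE, tolerance = 1e-10)
  expect_error(trend_basis(3, 3), "too short")
  expect_error(trend_basis(4, 5), "degree")
})

test_that("basis columns are orthogonal to all lower-degree monomials", {
  for (n in c(4, 9, 15)) {
    B <- trend_basis(n, 3)
    t <- seq_len(n)
    for (j in 1:3) {
      for (p in 0:(j - 1)) {
        expect_lt(abs(sum(B[, j + 1] * t^p)), 1e-8)
      }
    }
  }
})

test_that("trend extraction reproduces hand projections", {
  # constant series: only the level term survives
  tr <- extract_trends(rep(3, 4), 2)
  expect_equal(unname(tr$coefficients), c(3 * sqrt(4), 0, 0))
  # a series equal to a basis column projects to a unit coefficient
  B <- trend_basis(6, 2)
  tr <- extract_trends(B[, "Q"], 2)
  expect_equal(unname(tr$coefficients), c(0, 0, 1))
  # hand projection with the n = 3 basis
  tr <- extract_trends(c(1, 2, 4), 1)
  expect_equal(unname(tr$coefficients["L"]), 3 / sqrt(2))
  # short series flagged, not raised
  tr <- extract_trends(c(1, 2), 3)
  expect_false(tr$usable)
  expect_null(tr$coefficients)
})

test_that("trend extraction is linear in the series", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(7); y <- rnorm(7); a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    lhs <- extract_trends(a * x + b * y, 3)$coefficients
    rhs <- a * extract_trends(x, 3)$coefficients +
      b * extract_trends(y, 3)$coefficients
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("reconstruction error is non-increasing in degree", {
  set.seed(12)
  y <- rnorm(9)
  errs <- sapply(0:4, function(d) {
    sum(residual_summary(y, extract_trends(y, d))$residuals^2)
  })
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("residuals are orthogonal to the basis and vanish when saturated", {
  B <- trend_basis(3, 1)
  res <- residual_summary(c(1, 2, 4), extract_trends(c(1, 2, 4), 1))
  expect_lt(max(abs(crossprod(B, res$residuals))), 1e-10)
  # exactly quadratic series, d = 2: perfect fit
  y <- 2 + 0.5 * (1:6) - 0.3 * (1:6)^2
  res <- residual_summary(y, extract_trends(y, 2))
  expect_lt(max(abs(res$residuals)), 1e-9)
  expect_equal(res$variance, 0, tolerance = 1e-16)
  # saturated basis (d = n - 1)
  y <- c(4, -1, 7)
  res <- residual_summary(y, extract_trends(y, 2))
  expect_lt(max(abs(res$residuals)), 1e-9)
  expect_error(residual_summary(c(1, 2), extract_trends(c(1, 2), 3)),
               "unusable")
})

test_that("trend residuals agree with an independent lm/poly fit", {
  set.seed(13)
  for (n in c(5, 8, 12)) {
    y <- rnorm(n)
    ours <- residual_summary(y, extract_trends(y, 2))$residuals
    theirs <- stats::residuals(stats::lm(y ~ stats::poly(seq_len(n), 2)))
    expect_equal(ours, unname(theirs), tolerance = 1e-9)
  }
})

test_that("coefficients of equal degree are comparable across lengths", {
  # same underlying linear shape sampled at 5 vs 8 points: unit-norm basis
  # puts both linear coefficients on the same scale convention (positive,
  # growing with the slope), despite the differing lengths
  y5 <- 2 * (1:5); y8 <- 2 * (1:8)
  c5 <- extract_trends(y5, 1)$coefficients["L"]
  c8 <- extract_trends(y8, 1)$coefficients["L"]
  expect_gt(c5, 0)
  expect_gt(c8, 0)
  # projections onto unit vectors: slope * ||centered index||
  expect_equal(unname(c5), 2 * sqrt(sum((1:5 - 3)^2)))
  expect_equal(unname(c8), 2 * sqrt(sum((1:8 - 4.5)^2)))
})

test_that("the smoother averages over shrinking end windows", {
  expect_equal(smooth_series(c(0, 3, 6, 9)),
               c(1.5, 3, 6, 7.5))
  expect_equal(smooth_series(c(5, 7)), c(5, 7))
})

test_that("trend_matrix builds the 13(d+1) pool and reports exclusions", {
  co <- assign_rounds(tiny_cohort())
  tm <- trend_matrix(co, 2)
  expect_equal(ncol(tm$features), 13 * 3)
  # only P11 and P14 have 3-round TNFa series, but their other mediators
  # are empty, so everyone is excluded at d = 2
  expect_equal(nrow(tm$features), 0)
  expect_setequal(tm$excluded, co$clinical$id)

  sim <- simulate_cohort(simulation_config(n_patients = 8, rounds_min = 4,
                                           rounds_max = 6, missing_rate = 0,
                                           seed = 2))
  tm <- trend_matrix(sim$cohort, 3)
  expect_equal(ncol(tm$features), 13 * 4)
  expect_equal(nrow(tm$features), 8)
  expect_true(all(grepl("\\.(T0|L|Q|C)$", names(tm$features))))
  # truncating the history shortens series; degree-3 trends then need 4 rounds
  tm2 <- trend_matrix(sim$cohort, 3, up_to_round = 3)
  expect_equal(nrow(tm2$features), 0)
  # empty cohort
  empty <- new_cohort(tiny_cohort()$clinical[0, ])
  expect_equal(nrow(trend_matrix(empty, 2)$features), 0)
})
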