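test_that("cluster weights summarize GOS as (red flags, mean, sd)", {
  w <- cluster_weight(c(1, 1, 4, 5))
  expect_equal(w$red_flags, 2L)
  expect_equal(w$gos_mean, 2.75)
  expect_equal(w$gos_sd, sd(c(1, 1, 4, 5)))
  expect_equal(round(w$gos_sd, 4), 2.0616)
  expect_equal(w$prob_death, 0.5)
  # the 4-deaths-of-11 worst cluster
  w <- cluster_weight(c(rep(1, 4), rep(4, 7)))
  expect_equal(w$prob_death, 4 / 11)
  # best cluster: no deaths, no spread
  w <- cluster_weight(rep(5, 6))
  expect_equal(w$red_flags, 0L)
  expect_equal(w$prob_death, 0)
  expect_equal(w$gos_sd, 0)
  # singleton sd convention
  expect_equal(cluster_weight(3)$gos_sd, 0)
  expect_error(cluster_weight(numeric(0)), "empty")
  expect_error(cluster_weight(c(1, 6)), "within")
})

test_that("Beta-Binomial updating follows the conjugacy formula", {
  post <- bayes_update(beta_prior(1, 1), cluster_weight(c(rep(1, 4), rep(4, 7))))
  expect_equal(post$alpha, 5)
  expect_equal(post$beta, 8)
  expect_equal(post$mean, 5 / 13)
  expect_error(beta_prior(0, 1), "positive")
  # posterior mean lies strictly between prior mean and empirical rate
  set.seed(41)
  for (i in 1:50) {
    a <- runif(1, 0.1, 8); b <- runif(1, 0.1, 8)
    n <- sample(1:20, 1); rf <- rbinom(1, n, runif(1))
    gos <- c(rep(1, rf), rep(sample(2:5, 1), n - rf))
    w <- cluster_weight(gos)
    post <- bayes_update(beta_prior(a, b), w)
    pm <- a / (a + b); emp <- rf / n
    if (abs(pm - emp) > 1e-12) {
      expect_gt(post$mean, min(pm, emp))
      expect_lt(post$mean, max(pm, emp))
    }
  }
  # vague prior converges to the empirical rate, strong prior to the prior mean
  w <- cluster_weight(c(1, 1, 4, 5))
  expect_equal(bayes_update(beta_prior(1e-9, 1e-9), w)$mean, 0.5,
               tolerance = 1e-8)
  expect_equal(bayes_update(beta_prior(3e8, 1e8), w)$mean, 0.75,
               tolerance = 1e-7)
})

test_that("k-means recovers well-separated triplets at the brute-force optimum", {
  set.seed(51)
  centers <- matrix(c(0, 0, 10, 0, 0, 10), ncol = 2, byrow = TRUE)
  x <- centers[rep(1:3, each = 3), ] + matrix(rnorm(18, sd = 0.1), ncol = 2)
  rownames(x) <- paste0("p", 1:9)
  part <- cluster_stage(x, k = 3, seed = 1, n_restarts = 25)
  labels <- part$assignment
  expect_equal(length(unique(labels[1:3])), 1)
  expect_equal(length(unique(labels[4:6])), 1)
  expect_equal(length(unique(labels[7:9])), 1)
  expect_equal(part$wcss, brute_force_wcss(x, 3), tolerance = 1e-9)
})

test_that("clustering is deterministic under a seed and validates input", {
  set.seed(52)
  x <- matrix(rnorm(40), ncol = 2, dimnames = list(paste0("p", 1:20), NULL))
  a <- cluster_stage(x, k = 3, seed = 7)
  b <- cluster_stage(x, k = 3, seed = 7)
  expect_identical(a$assignment, b$assignment)
  expect_error(cluster_stage(x[1:2, ], k = 3), "fewer rows")
  expect_error(cluster_stage(x[c(1, 1, 1, 1), ], k = 3), "degenerate")
  # k = 1: everything in one cluster, WCSS = total sum of squares
  one <- cluster_stage(x, k = 1, seed = 1)
  expect_equal(unname(table(one$assignment)), 20, ignore_attr = TRUE)
  expect_equal(one$wcss, sum(scale(x, scale = FALSE)^2))
})

test_that("spectral clustering recovers separated groups deterministically", {
  set.seed(53)
  x <- rbind(matrix(rnorm(40, mean = 0, sd = 0.3), ncol = 2),
             matrix(rnorm(40, mean = 4, sd = 0.3), ncol = 2))
  rownames(x) <- paste0("p", 1:40)
  part <- cluster_stage(x, k = 2, method = "spectral", seed = 2)
  expect_equal(length(unique(part$assignment[1:20])), 1)
  expect_equal(length(unique(part$assignment[21:40])), 1)
  expect_false(part$assignment[[1]] == part$assignment[[21]])
  part2 <- cluster_stage(x, k = 2, method = "spectral", seed = 2)
  expect_identical(part$assignment, part2$assignment)
})

test_that("stage features follow the staged variable sets and stay bounded", {
  sim <- simulate_cohort(simulation_config(n_patients = 20, rounds_min = 8,
                                           rounds_max = 12, missing_rate = 0,
                                           seed = 8))
  co <- sim$cohort
  sf <- stage_features(co, -1)
  expect_equal(colnames(sf$features), "gcs")
  expect_equal(abs(mean(sf$features)) < 1e-12, TRUE)
  sf0 <- stage_features(co, 0)
  expect_setequal(colnames(sf0$features),
                  c("gcs", "age", "sex_male", "infection", "bleeding",
                    "surgical_decompression", "subarachnoid_hemorrhage"))
  # stage 1: no history yet, so GCS + clinical + 13 current readings
  sf1 <- stage_features(co, 1, degree = 2)
  expect_equal(ncol(sf1$features), 7 + 13)
  # from stage degree + 2 on the dimension is constant at the bound
  dims <- sapply(4:8, function(s) ncol(stage_features(co, s, degree = 2)$features))
  expect_true(all(dims == 7 + 13 * 3 + 13))
  expect_true(all(dims <= 1 + 6 + 13 * 3 + 13))
  expect_error(stage_features(co, 40, degree = 2), "exceeds the maximum")
})

test_that("patients missing a round's readings are excluded at that stage", {
  sim <- simulate_cohort(simulation_config(n_patients = 12, rounds_min = 4,
                                           rounds_max = 8, missing_rate = 0,
                                           seed = 9))
  co <- sim$cohort
  nr <- n_rounds(co)
  short <- names(nr)[nr < 8]
  expect_gt(length(short), 0)
  sf <- stage_features(co, 8, degree = 2)
  expect_true(all(short %in% sf$excluded))
  expect_false(any(short %in% sf$included))
})

test_that("stage partitions are exhaustive and conserve red flags", {
  sim <- simulate_cohort(simulation_config(n_patients = 24, seed = 10))
  co <- sim$cohort
  prof <- profile_cohort(co, seed = 10)
  gos <- outcome_gos(co)
  for (part in prof$partitions) {
    ids <- names(part$assignment)
    sizes <- vapply(part$weights, `[[`, numeric(1), "size")
    expect_equal(sum(sizes), length(ids))
    pd <- vapply(part$weights, `[[`, numeric(1), "prob_death")
    expect_true(all(pd >= 0 & pd <= 1))
    rf <- vapply(part$weights, `[[`, numeric(1), "red_flags")
    expect_equal(sum(rf), sum(gos[ids] == 1))
  }
  # canonical labels: death probability non-decreasing in the label (stages >= 0)
  for (part in prof$partitions[-1]) {
    pd <- vapply(part$weights, `[[`, numeric(1), "prob_death")
    expect_true(all(diff(pd) >= -1e-12))
  }
})

test_that("new patients are assigned to the nearest centroid with low-label ties", {
  set.seed(54)
  x <- matrix(c(rnorm(10, -5), rnorm(10, 5)), ncol = 1,
              dimnames = list(paste0("p", 1:20), "f"))
  part <- cluster_stage(x, k = 2, seed = 3)
  part$center <- 0; part$scale <- 1; part$features_used <- "f"
  # a row equal to a centroid lands in that cluster
  for (j in 1:2) {
    hit <- assign_new_patient(part, c(f = unname(part$centroids[j, 1])))
    expect_equal(hit$cluster, j)
  }
  # identical to an existing member: same cluster as that member
  hit <- assign_new_patient(part, c(f = unname(x["p3", 1])))
  expect_equal(hit$cluster, unname(part$assignment["p3"]))
  # exactly equidistant: lower canonical label
  mid <- mean(unname(part$centroids[, 1]))
  expect_equal(assign_new_patient(part, c(f = mid))$cluster, 1)
  expect_error(assign_new_patient(part, c(g = 1)), "missing value")
})

test_that("risk curves read cluster probabilities and omit absent stages", {
  parts <- list(
    inject_partition(-1, c("A", "B"), c(0.1, 0.4)),
    inject_partition(0, c("A", "B"), c(0.0, 0.5)),
    inject_partition(1, c("B"), c(0.7))
  )
  cv <- risk_curve(parts, "A")
  expect_equal(cv$stages, c(-1, 0))
  expect_equal(cv$probs, c(0.1, 0.0))
  cv <- risk_curve(parts, "B")
  expect_equal(cv$stages, c(-1, 0, 1))
  expect_equal(cv$probs, c(0.4, 0.5, 0.7))
  expect_error(risk_curve(parts, "Z"), "unknown patient")
  # a patient alone in a death-free cluster at every stage: flat zero curve
  lone <- list(inject_partition(-1, "A", 0), inject_partition(0, "A", 0))
  expect_equal(risk_curve(lone, "A")$probs, c(0, 0))
})

test_that("non-survivors sit on higher risk curves at late stages", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_cohort(simulation_config(n_patients = 30, seed = 100 + s))
    co <- sim$cohort
    prof <- profile_cohort(co, seed = 100 + s)
    gos <- outcome_gos(co)
    late <- vapply(names(gos), function(id) {
      cv <- risk_curve(prof, id)
      mean(utils::tail(cv$probs, 3))
    }, numeric(1))
    if (mean(late[gos == 1]) > mean(late[gos > 1])) hits <- hits + 1
  }
  expect_gte(hits, 3)
})
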