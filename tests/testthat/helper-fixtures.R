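# Hand-built 4-patient cohort with short TNFa/IL10 series; everything else
# empty. Used by the I/O and round-assignment tests.
tiny_cohort <- function() {
  clinical <- data.frame(
    id = c("P11", "P14", "A1", "A2"),
    age = c(29, 60, 40, 55),
    sex = c("male", "male", "female", "male"),
    infection = c(0, 1, 0, 1),
    bleeding = c(1, 1, 0, 0),
    surgical_decompression = c(0, 1, 0, 1),
    subarachnoid_hemorrhage = c(1, 0, 0, 1),
    gcs = c(6, 7, 5, 8),
    gos6 = c(4L, 1L, 3L, 5L),
    gos12 = c(4L, 1L, 3L, 5L),
    stringsAsFactors = FALSE
  )
  readings <- data.frame(
    patient_id = c(rep("P11", 3), rep("P14", 3), rep("A1", 2)),
    mediator = c(rep("TNFa", 3), rep("TNFa", 3), rep("IL10", 2)),
    time_hours = c(6, 12, 24, 8, 20, 30, 10, 40),
    concentration_pg_ml = c(5, 8, 12, 20, 30, 45, 3, 6),
    stringsAsFactors = FALSE
  )
  new_cohort(clinical, readings)
}

# Exhaustive minimum within-cluster sum of squares over all assignments of
# n points to exactly k non-empty clusters (independent oracle for k-means).
brute_force_wcss <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 9)
  best <- Inf
  assign <- rep(1L, n)
  total <- k^n
  for (code in 0:(total - 1)) {
    c0 <- code
    for (i in seq_len(n)) { assign[i] <- c0 %% k + 1L; c0 <- c0 %/% k }
    if (length(unique(assign)) < k) next
    w <- 0
    for (j in seq_len(k)) {
      xs <- x[assign == j, , drop = FALSE]
      w <- w + sum(sweep(xs, 2, colMeans(xs))^2)
    }
    if (w < best) best <- w
  }
  best
}

# Risk curve literal constructor (for injecting printed cluster weights).
make_curve <- function(id, stages, probs) {
  structure(list(id = id, stages = stages, probs = probs),
            class = "risk_curve")
}

# Stage partition with injected death probabilities: patient i is alone in
# cluster i, whose prob_death is given.
inject_partition <- function(stage, ids, probs) {
  weights <- lapply(probs, function(p) {
    structure(list(size = 1L, red_flags = NA_integer_, gos_mean = NA_real_,
                   gos_sd = NA_real_, prob_death = p),
              class = "cluster_weight")
  })
  structure(list(stage = stage,
                 assignment = stats::setNames(seq_along(ids), ids),
                 weights = weights, k = length(ids), method = "injected",
                 seed = 0L),
            class = "stage_partition")
}
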