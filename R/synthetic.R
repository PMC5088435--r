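#' Default per-mediator simulation parameters
#'
#' Log-normal baselines (natural-log median pg/mL and between-patient
#' spread) with outcome-dependent linear/quadratic log-scale trends over
#' normalized time in hospital. Non-survivors carry sustained elevations of
#' 0.8-1.5 log units by the end of stay on the canonical pro-inflammatory
#' axis (TNF-a, IL-6, IL-8, IL-1b, MIP-1a) and the anti-inflammatory IL-10;
#' survivors show mild resolution (small negative trends). Magnitudes are
#' order-of-magnitude realistic for severe-TBI CSF panels.
#'
#' @return Data frame with one row per panel mediator: `log_baseline`,
#'   `baseline_sd` (between-patient), `surv_linear`, `surv_quad`,
#'   `death_linear`, `death_quad`, `noise_sd` (within-series).
#' @export
default_mediator_params <- function() {
  m <- default_mediator_panel()
  p <- data.frame(
    mediator = m,
    log_baseline = c(1.6, 2.3, 1.4, 1.1, 0.7, 6.2, 5.7, 3.0, 1.1, 3.4,
                     3.9, 2.3, 3.9),
    baseline_sd = 0.3,
    surv_linear = 0, surv_quad = 0,
    death_linear = 0, death_quad = 0,
    noise_sd = 0.5,
    stringsAsFactors = FALSE
  )
  rownames(p) <- m
  p[c("IL6", "IL8", "TNFa"), "surv_linear"] <- c(-0.3, -0.3, -0.2)
  p["TNFa", c("death_linear", "death_quad")] <- c(1.5, 0.5)
  p["IL6", "death_linear"] <- 1.2
  p["IL8", "death_linear"] <- 1.0
  p["IL10", c("death_linear", "death_quad")] <- c(1.0, 0.5)
  p["IL1b", "death_linear"] <- 0.8
  p["MIP1a", "death_linear"] <- 0.8
  p
}

#' Configuration for the synthetic severe-TBI cohort generator
#'
#' Defaults mirror the reference cohort structure: 27 patients with a 7/27
#' death fraction, admission GCS of 6.0 (survivors) vs 5.6 (non-survivors)
#' on a truncated 3-8 severe-injury scale, 4-13 mediator reading rounds of
#' the 13-cytokine CSF panel, and 5% missing readings.
#'
#' @param n_patients Cohort size.
#' @param death_fraction Probability of the death outcome class.
#' @param gcs_mean_surv,gcs_mean_death,gcs_sd,gcs_range Truncated-normal
#'   GCS parameters per class.
#' @param age_mean_surv,age_mean_death,age_sd,age_min Age parameters.
#' @param male_fraction Probability of male sex.
#' @param flag_rates_surv,flag_rates_death Bernoulli rates for the four
#'   clinical flags (infection, bleeding, surgical decompression,
#'   subarachnoid hemorrhage), mildly outcome-informative by default.
#' @param rounds_min,rounds_max Uniform range of reading rounds.
#' @param missing_rate Probability each individual reading is lost.
#' @param effect_scale Multiplier on the outcome-dependent trends (0 erases
#'   all outcome signal from the mediator series).
#' @param mediator_params See [default_mediator_params()].
#' @param gos_given_survival Probabilities of GOS 2-5 among survivors
#'   (uniform by default).
#' @param seed Integer seed; the same seed yields a bit-identical cohort.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_patients = 27,
                              death_fraction = 7 / 27,
                              gcs_mean_surv = 6.0, gcs_mean_death = 5.6,
                              gcs_sd = 1.0, gcs_range = c(3, 8),
                              age_mean_surv = 34.0, age_mean_death = 37.9,
                              age_sd = 14, age_min = 16,
                              male_fraction = 0.88,
                              flag_rates_surv = c(infection = 0.3,
                                                  bleeding = 0.5,
                                                  surgical_decompression = 0.4,
                                                  subarachnoid_hemorrhage = 0.5),
                              flag_rates_death = c(infection = 0.5,
                                                   bleeding = 0.7,
                                                   surgical_decompression = 0.5,
                                                   subarachnoid_hemorrhage = 0.7),
                              rounds_min = 4, rounds_max = 13,
                              missing_rate = 0.05,
                              effect_scale = 1.0,
                              mediator_params = default_mediator_params(),
                              gos_given_survival = c(`2` = 0.25, `3` = 0.25,
                                                     `4` = 0.25, `5` = 0.25),
                              seed = 1) {
  if (death_fraction <= 0 || death_fraction >= 1) {
    stop("death_fraction must be strictly between 0 and 1")
  }
  if (rounds_min < 2) stop("rounds_min must be at least 2")
  if (rounds_max < rounds_min) stop("rounds_max must be >= rounds_min")
  if (effect_scale < 0) stop("effect_scale must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_patients < 1) stop("n_patients must be positive")
  structure(as.list(environment()), class = "sim_config")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n,
                    stats::pnorm(lo, mean, sd),
                    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate a synthetic severe-TBI cohort
#'
#' Draws outcome classes, clinical profiles and 13-mediator CSF time series
#' with outcome-dependent log-scale trends (see [simulation_config()]).
#' Log-concentration of mediator m for a patient at normalized time s in
#' `[0, 1]` (round 1 to last round) is
#' `baseline + patient_intercept + effect_scale * (linear * s + quad * s^2)
#' + noise`, with class-specific linear/quadratic coefficients. Readings
#' are dropped independently at `missing_rate`. GOS is 1 for deaths and
#' drawn from `gos_given_survival` otherwise.
#'
#' @param config A [simulation_config()].
#' @return List with `cohort` (a `dyn_cohort` with rounds assigned) and
#'   `truth` (data frame: id, class, per-patient trend coefficients used).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("P%02d", seq_len(n))
  died <- stats::rbinom(n, 1, config$death_fraction) == 1

  gcs_mean <- ifelse(died, config$gcs_mean_death, config$gcs_mean_surv)
  gcs <- round(rtrunc_norm(n, gcs_mean, config$gcs_sd,
                           config$gcs_range[1] - 0.49,
                           config$gcs_range[2] + 0.49))
  gcs <- pmin(pmax(gcs, config$gcs_range[1]), config$gcs_range[2])
  age_mean <- ifelse(died, config$age_mean_death, config$age_mean_surv)
  age <- round(pmax(stats::rnorm(n, age_mean, config$age_sd), config$age_min))
  sex <- ifelse(stats::runif(n) < config$male_fraction, "male", "female")
  flags <- sapply(names(config$flag_rates_surv), function(f) {
    rate <- ifelse(died, config$flag_rates_death[[f]],
                   config$flag_rates_surv[[f]])
    stats::rbinom(n, 1, rate)
  })
  gos_levels <- as.integer(names(config$gos_given_survival))
  gos <- ifelse(died, 1L,
                sample(gos_levels, n, replace = TRUE,
                       prob = config$gos_given_survival))
  clinical <- data.frame(id = ids, age = age, sex = sex, flags,
                         gcs = gcs, gos6 = as.integer(gos),
                         gos12 = as.integer(gos),
                         stringsAsFactors = FALSE)

  mp <- config$mediator_params
  panel <- mp$mediator
  round_choices <- seq(config$rounds_min, config$rounds_max)
  n_rounds <- round_choices[sample.int(length(round_choices), n,
                                       replace = TRUE)]
  rows <- vector("list", n)
  truth_tr <- vector("list", n)
  for (i in seq_len(n)) {
    R <- n_rounds[i]
    s <- (seq_len(R) - 1) / (R - 1)
    times <- 12 + 24 * (seq_len(R) - 1) + stats::runif(R, -6, 6)
    lin <- if (died[i]) mp$death_linear else mp$surv_linear
    qd <- if (died[i]) mp$death_quad else mp$surv_quad
    intercepts <- mp$log_baseline + stats::rnorm(length(panel), 0, mp$baseline_sd)
    logc <- outer(config$effect_scale * lin, s) +
      outer(config$effect_scale * qd, s^2) +
      intercepts +
      stats::rnorm(length(panel) * R, 0, mp$noise_sd)
    keep <- matrix(stats::runif(length(panel) * R) >= config$missing_rate,
                   nrow = length(panel))
    rows[[i]] <- data.frame(
      patient_id = ids[i],
      mediator = rep(panel, times = R)[as.vector(keep)],
      time_hours = rep(times, each = length(panel))[as.vector(keep)],
      concentration_pg_ml = exp(as.vector(logc))[as.vector(keep)],
      stringsAsFactors = FALSE
    )
    truth_tr[[i]] <- data.frame(
      id = ids[i], mediator = panel,
      linear = config$effect_scale * lin,
      quadratic = config$effect_scale * qd,
      stringsAsFactors = FALSE
    )
  }
  readings <- do.call(rbind, rows)
  readings <- readings[order(readings$patient_id, readings$mediator,
                             readings$time_hours), ]
  rownames(readings) <- NULL
  cohort <- assign_rounds(new_cohort(clinical, readings))
  truth <- list(
    classes = data.frame(id = ids, died = died, gos = gos,
                         n_rounds = n_rounds, stringsAsFactors = FALSE),
    trends = do.call(rbind, truth_tr)
  )
  list(cohort = cohort, truth = truth)
}

#' Deterministic worked-example cohort
#'
#' A fixed 12-patient fixture for documentation and integration tests,
#' containing two focal patients with 12 reading rounds each: a 29-year-old
#' survivor with GCS 6 who recovers to GOS 4 (id `P11`) and a 60-year-old
#' non-survivor with GCS 7 (id `P14`).
#'
#' @return A `dyn_cohort` with rounds assigned.
#' @export
worked_example_cohort <- function() {
  cfg <- simulation_config(n_patients = 12, rounds_min = 12, rounds_max = 12,
                           missing_rate = 0, seed = 20161101)
  sim <- simulate_cohort(cfg)
  cohort <- sim$cohort
  died <- sim$truth$classes$died
  surv_i <- which(!died)[1]
  death_i <- which(died)[1]
  old <- cohort$clinical$id
  new_ids <- sprintf("S%02d", seq_along(old))
  new_ids[surv_i] <- "P11"
  new_ids[death_i] <- "P14"
  cohort$clinical$id <- new_ids
  cohort$readings$patient_id <- new_ids[match(cohort$readings$patient_id, old)]
  fix <- function(id, age, gcs, gos) {
    j <- match(id, cohort$clinical$id)
    cohort$clinical$age[j] <<- age
    cohort$clinical$gcs[j] <<- gcs
    cohort$clinical$gos6[j] <<- as.integer(gos)
    cohort$clinical$gos12[j] <<- as.integer(gos)
  }
  fix("P11", 29, 6, 4)
  fix("P14", 60, 7, 1)
  validate_cohort(cohort)
  cohort
}
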