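#' Assemble the outcome-model feature table for a cohort
#'
#' The candidate predictor pool: GCS, the clinical/demographic variables
#' and the 13 x (degree + 1) orthogonal polynomial trend columns (patients
#' with any series shorter than degree + 1 rounds are excluded).
#'
#' @param cohort A `dyn_cohort` with rounds assigned.
#' @param degree Trend degree (0-4).
#' @param smooth Smooth series before trend extraction.
#' @return List with `features` (data frame, rownames = ids), `included`,
#'   `excluded`, `trend_columns`, `clinical_columns`.
#' @export
outcome_features <- function(cohort, degree = 2, smooth = FALSE) {
  tm <- trend_matrix(cohort, degree, smooth = smooth)
  clin <- clinical_features(cohort)
  gcs <- data.frame(gcs = as.numeric(cohort$clinical$gcs),
                    row.names = cohort$clinical$id)
  ids <- tm$included
  feats <- cbind(gcs[ids, , drop = FALSE], clin[ids, , drop = FALSE],
                 tm$features[ids, , drop = FALSE])
  list(features = feats, included = ids, excluded = tm$excluded,
       trend_columns = names(tm$features),
       clinical_columns = c("gcs", names(clin)))
}

#' Fit the selected outcome model for a cohort
#'
#' The full modeling chain: 80/20 stratified split, marginal pre-screening
#' of per-mediator trend blocks plus the clinical block, backward
#' elimination by `|t| >= t_cut` on the pooled survivors, final fit on the
#' training set and evaluation on the held-out test set.
#'
#' @param cohort A `dyn_cohort` with rounds assigned and known outcomes.
#' @param degree Trend degree.
#' @param link `"logit"` or `"probit"`.
#' @param rule Outcome binarization (see [binarize_gos()]); `low_high` is
#'   the headline poor/favorable split.
#' @param t_cut Retention threshold on `|t|`.
#' @param train_fraction,seed Split parameters.
#' @param smooth Smooth series before trend extraction.
#' @return List of class `outcome_model`: `fit`, `terms`, `train`, `test`,
#'   `fitted_all` (data frame patient/outcome/probability over all included
#'   patients), `test_eval`, `excluded`.
#' @export
fit_cohort_outcome <- function(cohort, degree = 2,
                               link = c("logit", "probit"),
                               rule = c("low_high", "survival"),
                               t_cut = 1.5, train_fraction = 0.8, seed = 1,
                               smooth = FALSE) {
  link <- match.arg(link)
  rule <- match.arg(rule)
  of <- outcome_features(cohort, degree, smooth = smooth)
  gos <- outcome_gos(cohort)[of$included]
  keep <- !is.na(gos)
  ids <- of$included[keep]
  feats <- of$features[keep, , drop = FALSE]
  y <- as.integer(binarize_gos(gos[keep], rule) == "High")
  if (length(unique(y)) < 2) stop("both outcome classes must be present")

  subcoh <- new_cohort(cohort$clinical[cohort$clinical$id %in% ids, , drop = FALSE],
                       mediator_panel = cohort$mediator_panel)
  split <- split_cohort(subcoh, train_fraction, seed,
                        rule = if (rule == "low_high") "low_high" else "survival")
  tr <- split$train
  blocks <- split(of$trend_columns,
                  sub("\\..*$", "", of$trend_columns))
  blocks <- c(list(clinical = of$clinical_columns), blocks)
  # drop zero-variance columns within the training rows before screening
  usable <- names(feats)[vapply(feats[tr, , drop = FALSE], stats::sd,
                                numeric(1)) > 0]
  blocks <- lapply(blocks, intersect, y = usable)
  blocks <- blocks[lengths(blocks) > 0]
  ytr <- y[match(tr, ids)]
  pool <- prescreen_terms(feats[tr, , drop = FALSE], ytr, blocks,
                          link = link, t_cut = t_cut)
  sel <- select_terms(feats[tr, , drop = FALSE], ytr, terms = pool,
                      t_cut = t_cut, link = link)
  if (is.null(sel$fit)) {
    fit <- fit_outcome(feats[tr, 0, drop = FALSE], ytr, link = link)
  } else {
    fit <- sel$fit
  }
  p_all <- predict_prob(fit, feats)
  te <- split$test
  test_eval <- if (length(te) > 0) {
    evaluate_predictions(p_all[match(te, ids)], y[match(te, ids)])
  } else NULL
  structure(list(fit = fit, terms = sel$terms, train = tr, test = te,
                 fitted_all = data.frame(patient_id = ids, outcome = y,
                                         probability = as.numeric(p_all),
                                         in_test = ids %in% te,
                                         stringsAsFactors = FALSE),
                 test_eval = test_eval, excluded = of$excluded,
                 link = link, rule = rule, degree = degree, t_cut = t_cut,
                 seed = seed),
            class = "outcome_model")
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("<outcome_model> %s link, %s rule, degree %d: %d term(s) retained\n",
              x$link, x$rule, x$degree, length(x$terms)))
  print(x$fit)
  if (!is.null(x$test_eval)) {
    cat(sprintf("  held-out accuracy: %d/%d\n", x$test_eval$correct,
                x$test_eval$n))
  }
  invisible(x)
}

#' Run the full dynamic-profiling pipeline
#'
#' simulate (or read) -> assign rounds -> trend extraction -> outcome model
#' -> staged profiling -> leave-one-out curve-matching prediction, writing
#' every report to `out_dir`: the fit table (term/value/SE/t), fitted
#' probabilities, per-stage partitions with cluster weights, risk curves,
#' the leave-one-out prediction report and a run log recording every seed
#' and knob.
#'
#' @param out_dir Output directory (created if needed).
#' @param clinical_csv,mediators_csv Input CSVs; when `NULL` a synthetic
#'   cohort is simulated from `sim_config`.
#' @param sim_config A [simulation_config()] used when no CSVs are given.
#' @param degree,k,method,link,gos_rule,t_cut,n_restarts,seed Pipeline
#'   knobs (see the module functions).
#' @return List of class `dyn_run` with elements `cohort`, `model`,
#'   `profile`, `curves`, `loo`, `paths`.
#' @export
run_pipeline <- function(out_dir,
                         clinical_csv = NULL, mediators_csv = NULL,
                         sim_config = simulation_config(seed = seed),
                         degree = 2, k = 3, method = "kmeans",
                         link = "logit", gos_rule = "survival",
                         t_cut = 1.5, n_restarts = 25, seed = 1) {
  if (degree < 0 || degree > 4) stop("degree must be between 0 and 4")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()

  if (!is.null(clinical_csv)) {
    cohort <- read_clinical(clinical_csv)
    if (!is.null(mediators_csv)) cohort <- read_mediators(mediators_csv, cohort)
    cohort <- assign_rounds(cohort)
  } else {
    sim <- simulate_cohort(sim_config)
    cohort <- sim$cohort
    paths$ground_truth <- file.path(out_dir, "ground_truth.csv")
    utils::write.csv(sim$truth$classes, paths$ground_truth, row.names = FALSE)
  }
  paths$clinical <- file.path(out_dir, "clinical.csv")
  paths$mediators <- file.path(out_dir, "mediators.csv")
  write_cohort(cohort, paths$clinical, paths$mediators)

  model <- tryCatch(
    fit_cohort_outcome(cohort, degree = degree, link = link, t_cut = t_cut,
                       seed = seed),
    error = function(e) { warning("outcome model skipped: ",
                                  conditionMessage(e)); NULL }
  )
  if (!is.null(model)) {
    paths$fit_table <- file.path(out_dir, "outcome_fit.csv")
    utils::write.csv(model$fit$table, paths$fit_table, row.names = FALSE)
    paths$fitted <- file.path(out_dir, "fitted_probabilities.csv")
    utils::write.csv(model$fitted_all, paths$fitted, row.names = FALSE)
  }

  # the statistically significant clinical variables and trends retained by
  # the outcome model feed the stage features; with no model (or nothing
  # retained in a family) all variables of that family are used
  sig_clin <- NULL; sig_trend <- NULL
  if (!is.null(model) && length(model$terms) > 0) {
    clin_names <- names(clinical_features(cohort))
    hits <- intersect(model$terms, clin_names)
    if (length(hits) > 0) sig_clin <- hits
    hits <- grep("\\.(T0|L|Q|C|T4)$", model$terms, value = TRUE)
    if (length(hits) > 0) sig_trend <- hits
  }

  profile <- profile_cohort(cohort, degree = degree, k = k, method = method,
                            seed = seed, n_restarts = n_restarts,
                            significant_clinical = sig_clin,
                            significant_trends = sig_trend)
  part_rows <- do.call(rbind, lapply(profile$partitions, function(p) {
    data.frame(stage = p$stage, patient_id = names(p$assignment),
               cluster = as.integer(p$assignment),
               prob_death = vapply(p$weights, `[[`, numeric(1),
                                   "prob_death")[p$assignment],
               stringsAsFactors = FALSE)
  }))
  rownames(part_rows) <- NULL
  paths$partitions <- file.path(out_dir, "partitions.csv")
  utils::write.csv(part_rows, paths$partitions, row.names = FALSE)
  paths$weights <- file.path(out_dir, "partitions.json")
  jsonlite::write_json(
    lapply(profile$partitions, function(p) list(
      stage = p$stage, seed = p$seed, k = p$k, method = p$method,
      features_used = p$features_used,
      centroids = unname(as.data.frame(p$centroids)),
      weights = lapply(p$weights, unclass)
    )),
    paths$weights, auto_unbox = TRUE, digits = NA)

  db_ids <- names(profile$partitions[["-1"]]$assignment)
  curves <- lapply(db_ids, function(id) risk_curve(profile, id))
  names(curves) <- db_ids
  curve_rows <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(patient_id = cv$id, stage = cv$stages, prob_death = cv$probs,
               stringsAsFactors = FALSE)
  }))
  rownames(curve_rows) <- NULL
  paths$curves <- file.path(out_dir, "risk_curves.csv")
  utils::write.csv(curve_rows, paths$curves, row.names = FALSE)

  loo <- tryCatch(
    loo_success_rate(cohort, degree = degree, k = k, method = method,
                     seed = seed, n_restarts = n_restarts,
                     significant_clinical = sig_clin,
                     significant_trends = sig_trend,
                     gos_rule = gos_rule),
    error = function(e) { warning("LOO prediction skipped: ",
                                  conditionMessage(e)); NULL }
  )
  if (!is.null(loo)) {
    paths$loo_records <- file.path(out_dir, "loo_predictions.csv")
    utils::write.csv(loo$records, paths$loo_records, row.names = FALSE)
    paths$loo_summary <- file.path(out_dir, "loo_summary.json")
    jsonlite::write_json(
      list(success_rate = loo$success_rate, n = loo$n,
           baseline = loo$baseline, ci95 = loo$ci, gos_rule = loo$gos_rule),
      paths$loo_summary, auto_unbox = TRUE, digits = NA)
  }

  log <- list(seed = seed, degree = degree, k = k, method = method,
              link = link, gos_rule = gos_rule, t_cut = t_cut,
              n_restarts = n_restarts,
              simulated = is.null(clinical_csv),
              sim_seed = if (is.null(clinical_csv)) sim_config$seed else NULL,
              n_patients = nrow(cohort$clinical),
              timestamp = format(Sys.time(), tz = "UTC"))
  paths$run_log <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, digits = NA)

  structure(list(cohort = cohort, model = model, profile = profile,
                 curves = curves, loo = loo, paths = paths),
            class = "dyn_run")
}

#' @export
print.dyn_run <- function(x, ...) {
  cat("<dyn_run>\n")
  print(x$cohort)
  if (!is.null(x$model)) print(x$model)
  print(x$profile)
  if (!is.null(x$loo)) print(x$loo)
  invisible(x)
}
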