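#' Area under a risk curve
#'
#' Trapezoidal area of the death probability against the stage index, over
#' the curve's stages up to and including `up_to_stage`. Stage spacing is
#' the stage index itself (unit spacing between consecutive rounds); a
#' curve with a single retained point has area 0.
#'
#' @param curve A `risk_curve`.
#' @param up_to_stage Horizon (default: the curve's last stage).
#' @return Non-negative area.
#' @export
curve_area <- function(curve, up_to_stage = max(curve$stages)) {
  if (length(curve$stages) == 0) stop("empty curve")
  if (up_to_stage < min(curve$stages)) {
    stop("horizon precedes the curve's first stage")
  }
  keep <- curve$stages <= up_to_stage
  trapezoid(curve$stages[keep], curve$probs[keep])
}

trapezoid <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Area distance between two risk curves
#'
#' Closeness of two patients' risk curves is the absolute difference of the
#' areas under them, computed over their common stages up to the horizon
#' (curves of unequal length are compared on common support only).
#'
#' @param a,b `risk_curve` objects.
#' @param up_to_stage Horizon (default: last common stage).
#' @return Non-negative, symmetric distance.
#' @export
curve_distance <- function(a, b, up_to_stage = Inf) {
  common <- intersect(a$stages, b$stages)
  common <- common[common <= up_to_stage]
  if (length(common) == 0) stop("curves share no stages up to the horizon")
  ya <- a$probs[match(common, a$stages)]
  yb <- b$probs[match(common, b$stages)]
  ord <- order(common)
  abs(trapezoid(common[ord], ya[ord]) - trapezoid(common[ord], yb[ord]))
}

#' Predict an incoming patient's outcome class by curve matching
#'
#' Finds the database patient(s) whose risk curve is closest to the
#' incoming patient's (area distance at the given horizon) and predicts the
#' match's binarized GOS. Exact ties are resolved by majority class among
#' the tied matches; a residual tie predicts `Low` (conservative).
#'
#' @param incoming A `risk_curve` for the incoming patient.
#' @param database Named list of `risk_curve`s (existing patients).
#' @param classes Binarized outcome per database patient (`"Low"`/`"High"`,
#'   named by id or in database order).
#' @param stage Horizon: the incoming patient's latest reading round by
#'   default.
#' @return List of class `curve_match`: `incoming`, `matched` (ids),
#'   `distance`, `stage_horizon`, `predicted_class`.
#' @export
predict_incoming <- function(incoming, database, classes,
                             stage = max(incoming$stages)) {
  if (length(database) == 0) stop("empty curve database")
  ids <- names(database)
  if (is.null(ids)) ids <- vapply(database, `[[`, character(1), "id")
  if (!is.null(names(classes))) classes <- classes[ids]
  classes <- as.character(classes)
  dist <- vapply(database, function(b) {
    tryCatch(curve_distance(incoming, b, up_to_stage = stage),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(dist))) stop("no database curve shares stages with the incoming patient")
  dmin <- min(dist, na.rm = TRUE)
  tied <- which(!is.na(dist) & dist <= dmin + 1e-12)
  cls <- classes[tied]
  n_high <- sum(cls == "High"); n_low <- sum(cls == "Low")
  predicted <- if (n_high > n_low) "High" else "Low"
  structure(list(incoming = incoming$id, matched = ids[tied],
                 distance = dmin, stage_horizon = stage,
                 predicted_class = predicted),
            class = "curve_match")
}

#' @export
print.curve_match <- function(x, ...) {
  cat(sprintf("<curve_match> %s -> %s (d = %.4f at stage %s): predicted %s\n",
              x$incoming, paste(x$matched, collapse = "/"), x$distance,
              x$stage_horizon, x$predicted_class))
  invisible(x)
}

#' Leave-one-out outcome prediction by dynamic profiling
#'
#' For each patient: rebuild every stage partition without them (same seed,
#' so differences come only from their removal), place them stage by stage
#' as an incoming patient to obtain their risk curve, and at their last
#' reading round predict their binarized GOS from the database patient with
#' the closest risk curve. The random baseline for comparison is 0.5 (the
#' success rate of assigning Low/High by a fair coin).
#'
#' @param cohort A `dyn_cohort` with rounds assigned and outcomes known.
#' @param degree,k,method,seed,n_restarts,significant_clinical,significant_trends
#'   Profiling configuration; see [profile_cohort()].
#' @param gos_rule Binarization used both for database classes and success
#'   scoring: `"survival"` (death vs not, default -- the mediator dynamics
#'   carry mortality signal) or `"low_high"` (GOS <= 3 vs >= 4).
#' @return List of class `loo_result`: `success_rate`, `n`, `baseline`
#'   (0.5), `ci` (exact binomial 95% CI), `records` (per-patient data
#'   frame), `skipped` (ids with no usable rounds).
#' @export
loo_success_rate <- function(cohort, degree = 2, k = 3, method = "kmeans",
                             seed = 1, n_restarts = 25,
                             significant_clinical = NULL,
                             significant_trends = NULL,
                             gos_rule = c("survival", "low_high")) {
  gos_rule <- match.arg(gos_rule)
  gos <- outcome_gos(cohort)
  eligible <- names(gos)[!is.na(gos)]
  if (length(eligible) < 3) stop("need at least 3 patients with known GOS")
  cls <- as.character(binarize_gos(gos[eligible], gos_rule))
  names(cls) <- eligible
  r <- cohort$readings$round
  max_stage <- if (length(r) == 0 || all(is.na(r))) 0 else max(r, na.rm = TRUE)
  tables <- profile_feature_tables(cohort, degree, max_stage,
                                   significant_clinical, significant_trends)
  records <- list(); skipped <- character(0)
  for (p in eligible) {
    fold <- setdiff(eligible, p)
    prof <- profile_cohort(cohort, degree = degree, k = k, method = method,
                           seed = seed, n_restarts = n_restarts,
                           include = fold, max_stage = max_stage,
                           raw_features = tables)
    stages <- integer(0); probs <- numeric(0)
    for (s in prof$stages) {
      raw <- tables[[as.character(s)]]
      if (!p %in% rownames(raw)) next
      hit <- assign_new_patient(prof$partitions[[as.character(s)]],
                                unlist(raw[p, , drop = FALSE]))
      stages <- c(stages, s); probs <- c(probs, hit$prob_death)
    }
    if (length(stages[stages >= 1]) == 0) { skipped <- c(skipped, p); next }
    incoming <- structure(list(id = p, stages = stages, probs = probs),
                          class = "risk_curve")
    db <- lapply(fold, function(q) risk_curve(prof, q))
    names(db) <- fold
    match_res <- predict_incoming(incoming, db, cls[fold],
                                  stage = max(stages))
    records[[p]] <- data.frame(
      patient_id = p, true_class = cls[[p]],
      predicted_class = match_res$predicted_class,
      matched_id = paste(match_res$matched, collapse = "/"),
      distance = match_res$distance,
      horizon_stage = match_res$stage_horizon,
      correct = match_res$predicted_class == cls[[p]],
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, records)
  rownames(rec) <- NULL
  n <- nrow(rec)
  successes <- sum(rec$correct)
  ci <- as.numeric(stats::binom.test(successes, n)$conf.int)
  structure(list(success_rate = successes / n, n = n, baseline = 0.5,
                 ci = ci, records = rec, skipped = skipped,
                 gos_rule = gos_rule),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf(
    "<loo_result> %d/%d correct (%.1f%%; 95%% CI %.1f-%.1f%%) vs 50%% random baseline [%s rule]\n",
    sum(x$records$correct), x$n, 100 * x$success_rate,
    100 * x$ci[1], 100 * x$ci[2], x$gos_rule))
  invisible(x)
}
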