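#' Cluster weight from GOS scores
#'
#' The outcome summary attached to every cluster: the number of red flags
#' (GOS = 1, i.e. deaths), the mean and sample standard deviation of the
#' GOS scores, and the empirical death probability red_flags / size.
#'
#' @param gos_values Non-empty vector of GOS scores in `[1, 5]`.
#' @return List of class `cluster_weight`: `size`, `red_flags`, `gos_mean`,
#'   `gos_sd` (0 for a singleton), `prob_death`.
#' @export
cluster_weight <- function(gos_values) {
  if (length(gos_values) == 0) stop("cluster is empty")
  if (any(is.na(gos_values)) || any(gos_values < 1 | gos_values > 5)) {
    stop("GOS scores must be within [1, 5]")
  }
  n <- length(gos_values)
  rf <- sum(gos_values == 1)
  structure(list(size = n, red_flags = rf,
                 gos_mean = mean(gos_values),
                 gos_sd = if (n > 1) stats::sd(gos_values) else 0,
                 prob_death = rf / n),
            class = "cluster_weight")
}

#' @export
print.cluster_weight <- function(x, ...) {
  cat(sprintf(
    "<cluster_weight> size %d, red flags %d (P(death) = %.3f), GOS %.2f +/- %.2f\n",
    x$size, x$red_flags, x$prob_death, x$gos_mean, x$gos_sd))
  invisible(x)
}

#' Beta prior over a cluster's death probability
#'
#' @param alpha,beta Positive shape parameters.
#' @return List of class `beta_prior` with `alpha`, `beta`, `mean`.
#' @export
beta_prior <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0) {
    stop("alpha and beta must be positive")
  }
  structure(list(alpha = alpha, beta = beta, mean = alpha / (alpha + beta)),
            class = "beta_prior")
}

#' Conjugate Beta-Binomial update of a cluster death probability
#'
#' Treats the cluster's red flags as Binomial(size, p) and updates the Beta
#' prior, so the posterior blends medical prior expertise with the observed
#' death fraction: posterior = Beta(alpha + red_flags, beta + size -
#' red_flags), posterior mean = (alpha + red_flags) / (alpha + beta + size).
#'
#' @param prior A [beta_prior()].
#' @param weight A [cluster_weight()].
#' @return A `beta_prior` for the posterior (its `mean` is the posterior
#'   mean death probability).
#' @export
bayes_update <- function(prior, weight) {
  stopifnot(inherits(prior, "beta_prior"), inherits(weight, "cluster_weight"))
  beta_prior(prior$alpha + weight$red_flags,
             prior$beta + weight$size - weight$red_flags)
}

# ---- stage feature construction ------------------------------------------

#' Clinical feature columns
#'
#' Numeric encoding of the clinical/demographic variables used from Stage 0
#' on: age, sex (male = 1) and the four binary flags.
#'
#' @param cohort A `dyn_cohort`.
#' @return Data frame with rownames = patient ids.
#' @export
clinical_features <- function(cohort) {
  cl <- cohort$clinical
  out <- data.frame(
    age = as.numeric(cl$age),
    sex_male = as.numeric(cl$sex %in% c("male", "M", "m", 1)),
    infection = as.numeric(cl$infection),
    bleeding = as.numeric(cl$bleeding),
    surgical_decompression = as.numeric(cl$surgical_decompression),
    subarachnoid_hemorrhage = as.numeric(cl$subarachnoid_hemorrhage)
  )
  rownames(out) <- cl$id
  out
}

# Raw (unstandardized) feature rows for one profiling stage.
#
# Stage -1: GCS only. Stage 0: GCS + clinical/demographic. Stage i >= 1:
# GCS + significant clinical + polynomial trends of the history (rounds
# 1..i-1, degree capped at min(degree, i-2) -- a quadratic needs 3 history
# points) + the 13 raw readings of round i. Patients missing any round-i
# reading are excluded at stage i (no imputation); a patient whose history
# for some mediator is too short for a coefficient gets 0 there (no
# detectable trend) so columns stay aligned.
raw_stage_features <- function(cohort, stage, degree = 2,
                               significant_clinical = NULL,
                               significant_trends = NULL) {
  cl <- cohort$clinical
  ids <- cl$id
  gcs <- data.frame(gcs = as.numeric(cl$gcs), row.names = ids)
  if (stage == -1) return(gcs)
  clin <- clinical_features(cohort)
  if (!is.null(significant_clinical)) {
    clin <- clin[, intersect(names(clin), significant_clinical), drop = FALSE]
  }
  if (stage == 0) return(cbind(gcs, clin))
  if (stage < -1 || stage != round(stage)) stop("stage must be an integer >= -1")

  rd <- cohort$readings
  if (nrow(rd) == 0 || all(is.na(rd$round))) {
    stop("rounds must be assigned before stage >= 1 features")
  }
  max_round <- max(rd$round, na.rm = TRUE)
  if (stage > max_round) {
    stop("stage ", stage, " exceeds the maximum observed round ", max_round)
  }
  panel <- cohort$mediator_panel
  # current-interval readings: one column per mediator at round `stage`
  cur <- rd[!is.na(rd$round) & rd$round == stage, , drop = FALSE]
  cur_mat <- matrix(NA_real_, length(ids), length(panel),
                    dimnames = list(ids, paste0(panel, ".r")))
  if (nrow(cur) > 0) {
    agg <- tapply(cur$concentration_pg_ml,
                  list(factor(cur$patient_id, levels = ids),
                       factor(cur$mediator, levels = panel)),
                  mean)
    cur_mat[] <- agg
  }
  keep <- rowSums(is.na(cur_mat)) == 0
  out <- cbind(gcs, clin)[keep, , drop = FALSE]

  d_eff <- min(degree, stage - 2)
  if (d_eff >= 0) {
    labs <- degree_labels(d_eff)
    tcols <- as.vector(t(outer(panel, labs, paste, sep = ".")))
    tr <- matrix(0, sum(keep), length(tcols),
                 dimnames = list(ids[keep], tcols))
    for (id in ids[keep]) {
      for (m in panel) {
        y <- round_values(cohort, id, m, up_to_round = stage - 1)
        if (length(y) == 0) next
        dd <- min(d_eff, length(y) - 1)
        co <- extract_trends(y, dd)$coefficients
        tr[id, paste(m, degree_labels(dd), sep = ".")] <- co
      }
    }
    if (!is.null(significant_trends)) {
      tr <- tr[, intersect(colnames(tr), significant_trends), drop = FALSE]
    }
    out <- cbind(out, as.data.frame(tr))
  }
  cbind(out, as.data.frame(cur_mat[keep, , drop = FALSE]))
}

#' Standardized feature table for one profiling stage
#'
#' Builds the stage's feature rows (see Details) and z-scores every column
#' (zero-variance columns are centered only), storing the moments so an
#' incoming patient can be placed on the same scale. Stage -1 uses the GCS
#' alone; Stage 0 adds the clinical/demographic variables; Stage i >= 1
#' adds the polynomial trends of rounds 1..i-1 plus the raw readings of
#' round i, so the feature dimension is bounded and constant across stages
#' i >= max(2, degree + 2).
#'
#' @param cohort A `dyn_cohort` with rounds assigned (for stages >= 1).
#' @param stage Integer >= -1.
#' @param degree Highest trend degree (0-4).
#' @param significant_clinical Optional subset of clinical column names
#'   (from [clinical_features()]) to use from Stage 0 on; default all.
#' @param significant_trends Optional subset of trend column names to use;
#'   default all.
#' @return List with `features` (standardized matrix), `raw`, `center`,
#'   `scale`, `included`, `excluded`.
#' @export
stage_features <- function(cohort, stage, degree = 2,
                           significant_clinical = NULL,
                           significant_trends = NULL) {
  raw <- raw_stage_features(cohort, stage, degree, significant_clinical,
                            significant_trends)
  std <- standardize_features(as.matrix(raw))
  list(features = std$x, raw = raw, center = std$center, scale = std$scale,
       included = rownames(raw),
       excluded = setdiff(cohort$clinical$id, rownames(raw)))
}

standardize_features <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, `/`),
       center = center, scale = scale)
}

# ---- clustering ----------------------------------------------------------

#' Partition one stage's patients into k clusters
#'
#' k-means (Hartigan-Wong updates, best within-cluster sum of squares over
#' `n_restarts` random starts) or spectral clustering (Gaussian affinity
#' with bandwidth = median pairwise distance, symmetric-normalized
#' Laplacian, top-k eigenvector embedding with row normalization, then
#' k-means in the embedding). Labels are canonicalized by ascending cluster
#' mean of the first feature column (the GCS column at every stage).
#'
#' @param features Standardized numeric matrix, rownames = patient ids.
#' @param k Number of clusters (default 3).
#' @param method `"kmeans"` or `"spectral"`.
#' @param seed Integer seed (drives the restarts).
#' @param n_restarts Random starts (default 25).
#' @return List of class `stage_partition` (without outcome weights):
#'   `assignment` (named integer), `centroids` (k x p, canonical order),
#'   `wcss`, `k`, `method`, `seed`.
#' @export
cluster_stage <- function(features, k = 3, method = c("kmeans", "spectral"),
                          seed = 1, n_restarts = 25) {
  method <- match.arg(method)
  x <- as.matrix(features)
  if (!all(is.finite(x))) stop("features must be finite")
  if (nrow(x) < k) stop("fewer rows (", nrow(x), ") than clusters (", k, ")")
  if (nrow(unique(x)) < k) stop("degenerate features: fewer than k distinct rows")

  set.seed(seed)
  if (method == "kmeans") {
    km <- stats::kmeans(x, centers = k, nstart = n_restarts, iter.max = 50,
                        algorithm = "Hartigan-Wong")
    labels <- km$cluster
  } else {
    emb <- spectral_embedding(x, k)
    km <- stats::kmeans(emb, centers = k, nstart = n_restarts, iter.max = 50,
                        algorithm = "Hartigan-Wong")
    labels <- km$cluster
  }
  # canonical labels: ascending cluster mean of the first feature column
  m1 <- tapply(x[, 1], labels, mean)
  remap <- match(names(sort(m1)), names(m1))
  new_lab <- match(labels, remap)
  names(new_lab) <- rownames(x)
  centroids <- matrix(NA_real_, k, ncol(x),
                      dimnames = list(NULL, colnames(x)))
  for (j in seq_len(k)) {
    centroids[j, ] <- colMeans(x[new_lab == j, , drop = FALSE])
  }
  wcss <- sum(vapply(seq_len(k), function(j) {
    xs <- x[new_lab == j, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
  structure(list(assignment = new_lab, centroids = centroids, wcss = wcss,
                 k = k, method = method, seed = seed),
            class = "stage_partition")
}

# Ng-Jordan-Weiss spectral embedding: Gaussian affinity (bandwidth =
# median pairwise distance), L_sym = D^-1/2 W D^-1/2, top-k eigenvectors,
# rows normalized to unit length.
spectral_embedding <- function(x, k) {
  dmat <- as.matrix(stats::dist(x))
  sigma <- stats::median(dmat[upper.tri(dmat)])
  if (!is.finite(sigma) || sigma <= 0) stop("degenerate features for spectral embedding")
  W <- exp(-dmat^2 / (2 * sigma^2))
  diag(W) <- 0
  dinv <- 1 / sqrt(pmax(rowSums(W), 1e-12))
  L <- dinv * W * rep(dinv, each = nrow(W))
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  U / pmax(nrm, 1e-12)
}

#' Cluster a cohort at one profiling stage, with outcome weights
#'
#' Runs [stage_features()] and [cluster_stage()], attaches a
#' [cluster_weight()] to every cluster from the members' outcome GOS
#' scores, and canonicalizes labels by the outcome profile: stage -1 by
#' ascending cluster mean GCS, later stages by ascending death probability
#' (ties by descending mean GOS, then by first centroid coordinate).
#'
#' @param cohort A `dyn_cohort`; only patients with a known outcome GOS
#'   enter the partition.
#' @param stage Integer >= -1.
#' @param include Optional subset of patient ids (e.g. a leave-one-out
#'   fold); default all.
#' @inheritParams stage_features
#' @inheritParams cluster_stage
#' @param raw_features Optional precomputed [raw_stage_features()] table
#'   for the full cohort (an optimization for leave-one-out loops).
#' @return A `stage_partition` with `stage`, `weights` (list indexed by
#'   cluster label), `center`, `scale`, `features_used`, `included`,
#'   `excluded`.
#' @export
stage_partition <- function(cohort, stage, degree = 2, k = 3,
                            method = "kmeans", seed = 1, n_restarts = 25,
                            significant_clinical = NULL,
                            significant_trends = NULL,
                            include = NULL, raw_features = NULL) {
  if (is.null(raw_features)) {
    raw_features <- raw_stage_features(cohort, stage, degree,
                                       significant_clinical,
                                       significant_trends)
  }
  gos <- outcome_gos(cohort)
  ids <- rownames(raw_features)
  ids <- ids[!is.na(gos[ids])]
  if (!is.null(include)) ids <- intersect(ids, include)
  raw <- as.matrix(raw_features[ids, , drop = FALSE])
  std <- standardize_features(raw)
  part <- cluster_stage(std$x, k = k, method = method, seed = seed,
                        n_restarts = n_restarts)
  part$stage <- stage
  part$center <- std$center
  part$scale <- std$scale
  part$features_used <- colnames(raw)
  part$included <- ids
  part$excluded <- setdiff(cohort$clinical$id, ids)

  lab <- part$assignment
  weights <- lapply(seq_len(k), function(j) cluster_weight(gos[ids[lab == j]]))
  # outcome-profile canonical order
  if (stage == -1) {
    key_order <- order(vapply(seq_len(k),
                              function(j) mean(raw[lab == j, "gcs"]),
                              numeric(1)))
  } else {
    pd <- vapply(weights, `[[`, numeric(1), "prob_death")
    gm <- vapply(weights, `[[`, numeric(1), "gos_mean")
    key_order <- order(pd, -gm, part$centroids[, 1])
  }
  relabel <- match(seq_len(k), key_order)
  part$assignment[] <- relabel[lab]
  part$centroids <- part$centroids[key_order, , drop = FALSE]
  part$weights <- weights[key_order]
  part
}

#' @export
print.stage_partition <- function(x, ...) {
  cat(sprintf("<stage_partition> stage %s, %s, k = %d, %d patients\n",
              if (is.null(x$stage)) "?" else x$stage, x$method, x$k,
              length(x$assignment)))
  if (!is.null(x$weights)) {
    for (j in seq_len(x$k)) {
      w <- x$weights[[j]]
      cat(sprintf("  cluster %d: n = %d, red flags = %d, P(death) = %.3f\n",
                  j, w$size, w$red_flags, w$prob_death))
    }
  }
  invisible(x)
}

#' Place a new patient into an existing stage partition
#'
#' Standardizes the raw feature row with the partition's stored moments and
#' assigns the nearest centroid (Euclidean distance; ties go to the lower
#' canonical label). The assigned cluster's red-flag fraction estimates the
#' patient's current death probability.
#'
#' @param partition A `stage_partition` with stored moments.
#' @param features Named numeric vector or one-row data frame on the raw
#'   feature scale, covering `features_used`.
#' @return List with `cluster` and `prob_death` (NA when the partition
#'   carries no weights).
#' @export
assign_new_patient <- function(partition, features) {
  if (is.data.frame(features) || is.matrix(features)) {
    features <- unlist(as.data.frame(features)[1, , drop = FALSE])
  }
  need <- partition$features_used
  if (is.null(need)) need <- colnames(partition$centroids)
  if (!all(need %in% names(features)) || anyNA(features[need])) {
    stop("feature row is missing value(s) for: ",
         paste(setdiff(need, names(features)[!is.na(features)]),
               collapse = ", "))
  }
  z <- (as.numeric(features[need]) - partition$center) / partition$scale
  d2 <- rowSums(sweep(partition$centroids, 2, z)^2)
  cl <- which(d2 <= min(d2) + 1e-12)[1]
  pd <- if (!is.null(partition$weights)) partition$weights[[cl]]$prob_death else NA_real_
  list(cluster = cl, prob_death = pd)
}

# ---- full profile and risk curves ----------------------------------------

#' Profile a cohort across all stages
#'
#' Builds the full sequence of stage partitions: stage -1 (GCS), stage 0
#' (GCS + clinical/demographic), then one stage per reading round while at
#' least `k` patients still have complete readings for the round.
#'
#' @inheritParams stage_partition
#' @param max_stage Last reading round to attempt (default: highest
#'   observed round).
#' @param raw_features Optional precomputed list of raw feature tables
#'   indexed as produced by [profile_feature_tables()].
#' @return List of class `dyn_profile`: `partitions` (list keyed by stage
#'   as character), `stages`, plus the configuration used.
#' @export
profile_cohort <- function(cohort, degree = 2, k = 3, method = "kmeans",
                           seed = 1, n_restarts = 25,
                           significant_clinical = NULL,
                           significant_trends = NULL,
                           include = NULL, max_stage = NULL,
                           raw_features = NULL) {
  if (is.null(max_stage)) {
    r <- cohort$readings$round
    max_stage <- if (length(r) == 0 || all(is.na(r))) 0 else max(r, na.rm = TRUE)
  }
  if (is.null(raw_features)) {
    raw_features <- profile_feature_tables(cohort, degree, max_stage,
                                           significant_clinical,
                                           significant_trends)
  }
  partitions <- list()
  stages <- integer(0)
  for (stage in seq(-1, max_stage)) {
    raw <- raw_features[[as.character(stage)]]
    if (is.null(raw)) break
    part <- tryCatch(
      stage_partition(cohort, stage, degree = degree, k = k, method = method,
                      seed = seed, n_restarts = n_restarts,
                      include = include, raw_features = raw),
      error = function(e) NULL
    )
    if (is.null(part)) {
      if (stage <= 0) stop("could not cluster stage ", stage,
                           ": too few patients or degenerate features")
      next
    }
    partitions[[as.character(stage)]] <- part
    stages <- c(stages, stage)
  }
  structure(list(partitions = partitions, stages = stages, degree = degree,
                 k = k, method = method, seed = seed,
                 n_restarts = n_restarts,
                 significant_clinical = significant_clinical,
                 significant_trends = significant_trends),
            class = "dyn_profile")
}

#' Precompute raw stage feature tables for a cohort
#'
#' The per-patient feature rows at each stage do not depend on which other
#' patients are in the partition, so leave-one-out loops compute them once
#' and re-standardize per fold.
#'
#' @inheritParams stage_partition
#' @param max_stage Highest reading round to build.
#' @return Named list of raw feature tables, keys `"-1"`, `"0"`, `"1"`, ...
#' @export
profile_feature_tables <- function(cohort, degree = 2, max_stage = NULL,
                                   significant_clinical = NULL,
                                   significant_trends = NULL) {
  if (is.null(max_stage)) {
    r <- cohort$readings$round
    max_stage <- if (length(r) == 0 || all(is.na(r))) 0 else max(r, na.rm = TRUE)
  }
  out <- list()
  for (stage in seq(-1, max_stage)) {
    out[[as.character(stage)]] <-
      raw_stage_features(cohort, stage, degree, significant_clinical,
                         significant_trends)
  }
  out
}

#' @export
print.dyn_profile <- function(x, ...) {
  cat(sprintf("<dyn_profile> %d stage(s) (%s), k = %d, %s, degree %d\n",
              length(x$stages),
              paste(range(x$stages), collapse = ".."),
              x$k, x$method, x$degree))
  invisible(x)
}

#' Risk curve of a profiled patient
#'
#' The patient's sequence of cluster death probabilities across the stages
#' in which they were included; stages where they lack data are omitted.
#'
#' @param profile A `dyn_profile` (or plain list of `stage_partition`s).
#' @param id Patient id.
#' @return List of class `risk_curve` with `id`, `stages`, `probs`.
#' @export
risk_curve <- function(profile, id) {
  parts <- if (inherits(profile, "dyn_profile")) profile$partitions else profile
  stages <- integer(0); probs <- numeric(0)
  found <- FALSE
  for (part in parts) {
    if (id %in% names(part$assignment)) {
      found <- TRUE
      cl <- part$assignment[[id]]
      stages <- c(stages, part$stage)
      probs <- c(probs, part$weights[[cl]]$prob_death)
    }
  }
  if (!found) stop("unknown patient id: ", id)
  ord <- order(stages)
  structure(list(id = id, stages = stages[ord], probs = probs[ord]),
            class = "risk_curve")
}

#' @export
print.risk_curve <- function(x, ...) {
  cat(sprintf("<risk_curve> %s: stages %s\n", x$id,
              paste(range(x$stages), collapse = "..")))
  print(stats::setNames(round(x$probs, 3), x$stages))
  invisible(x)
}
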