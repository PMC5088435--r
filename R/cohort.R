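#' @keywords internal
"_PACKAGE"

# The 13-mediator CSF panel used throughout; ASCII names match the
# TNFa.L / IL10.Q column convention of the fit reports.
.default_panel <- c(
  "IL1a", "IL1b", "IL2", "IL4", "IL5", "IL6", "IL8",
  "IL10", "IL13", "MIP1a", "MIP1b", "TNFa", "VEGF"
)

.clinical_flags <- c("infection", "bleeding", "surgical_decompression",
                     "subarachnoid_hemorrhage")
.clinical_required <- c("id", "age", "sex", .clinical_flags, "gcs")

#' Default inflammatory mediator panel
#'
#' The 13 CSF cytokines/chemokines measured in severe TBI cohorts:
#' IL-1a, IL-1b, IL-2, IL-4, IL-5, IL-6, IL-8, IL-10, IL-13, MIP-1a,
#' MIP-1b, TNF-a and VEGF, in ASCII spelling.
#'
#' @return Character vector of 13 mediator names.
#' @export
default_mediator_panel <- function() .default_panel

#' Construct a longitudinal cohort
#'
#' Bundles a per-patient clinical table and a long-format table of mediator
#' readings into a validated cohort object, the central container of the
#' package.
#'
#' @param clinical Data frame, one row per patient, with columns `id`,
#'   `age` (years), `sex` (`"male"`/`"female"`), the four binary flags
#'   `infection`, `bleeding`, `surgical_decompression`,
#'   `subarachnoid_hemorrhage` (0/1 or logical), `gcs` (integer 3-15) and
#'   optionally `gos6`, `gos12` (integer 1-5, `NA` when unknown) plus any
#'   extra covariate columns.
#' @param readings Data frame with columns `patient_id`, `mediator`,
#'   `time_hours`, `concentration_pg_ml` and optionally `round`. May be
#'   empty.
#' @param mediator_panel Character vector of allowed mediator names.
#'
#' @return An object of class `dyn_cohort`: a list with elements
#'   `clinical`, `readings` and `mediator_panel`.
#' @export
new_cohort <- function(clinical,
                       readings = empty_readings(),
                       mediator_panel = default_mediator_panel()) {
  clinical <- as.data.frame(clinical, stringsAsFactors = FALSE)
  readings <- as.data.frame(readings, stringsAsFactors = FALSE)
  for (col in c("gos6", "gos12")) {
    if (!col %in% names(clinical)) clinical[[col]] <- rep(NA_integer_, nrow(clinical))
  }
  if (!"round" %in% names(readings)) readings$round <- rep(NA_integer_, nrow(readings))
  obj <- structure(
    list(clinical = clinical, readings = readings,
         mediator_panel = mediator_panel),
    class = "dyn_cohort"
  )
  validate_cohort(obj)
  obj
}

#' @rdname new_cohort
#' @export
empty_readings <- function() {
  data.frame(patient_id = character(), mediator = character(),
             time_hours = numeric(), concentration_pg_ml = numeric(),
             round = integer(), stringsAsFactors = FALSE)
}

#' Validate a cohort object
#'
#' Checks the invariants of the container: unique ids, GCS within 3-15,
#' positive ages, GOS scores within 1-5 when present, readings that refer
#' to known patients and panel mediators, non-negative concentrations, and
#' strictly increasing times within each (patient, mediator) series.
#'
#' @param cohort A `dyn_cohort`.
#' @return The cohort, invisibly; stops with an informative error otherwise.
#' @export
validate_cohort <- function(cohort) {
  cl <- cohort$clinical
  missing_cols <- setdiff(.clinical_required, names(cl))
  if (length(missing_cols) > 0) {
    stop("clinical table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(cl$id)) {
    stop("duplicate patient id(s): ",
         paste(unique(cl$id[duplicated(cl$id)]), collapse = ", "))
  }
  if (nrow(cl) > 0) {
    if (any(!is.finite(cl$gcs)) || any(cl$gcs < 3 | cl$gcs > 15)) {
      stop("gcs must be within [3, 15] for every patient")
    }
    if (any(!is.finite(cl$age)) || any(cl$age <= 0)) {
      stop("age must be positive for every patient")
    }
    for (col in c("gos6", "gos12")) {
      v <- cl[[col]]
      bad <- !is.na(v) & (v < 1 | v > 5 | v != round(v))
      if (any(bad)) stop(col, " must be an integer in [1, 5] when present")
    }
  }
  rd <- cohort$readings
  if (nrow(rd) > 0) {
    unknown <- setdiff(unique(rd$patient_id), cl$id)
    if (length(unknown) > 0) {
      stop("readings refer to unknown patient id(s): ",
           paste(unknown, collapse = ", "))
    }
    off_panel <- setdiff(unique(rd$mediator), cohort$mediator_panel)
    if (length(off_panel) > 0) {
      stop("readings refer to mediator(s) outside the panel: ",
           paste(off_panel, collapse = ", "))
    }
    if (any(rd$concentration_pg_ml < 0)) {
      stop("concentrations must be non-negative")
    }
    key <- paste(rd$patient_id, rd$mediator, sep = "\r")
    ord <- order(key, rd$time_hours)
    k <- key[ord]; tt <- rd$time_hours[ord]
    same <- k[-1] == k[-length(k)]
    if (any(same & diff(tt) <= 0)) {
      stop("duplicate or non-increasing timestamps within a (patient, mediator) series")
    }
  }
  invisible(cohort)
}

#' @export
print.dyn_cohort <- function(x, ...) {
  cl <- x$clinical
  gos <- outcome_gos(x)
  cat(sprintf("<dyn_cohort> %d patients, %d mediator readings\n",
              nrow(cl), nrow(x$readings)))
  if (nrow(cl) > 0) {
    cat(sprintf("  deaths (GOS = 1): %d / %d with known outcome\n",
                sum(gos == 1, na.rm = TRUE), sum(!is.na(gos))))
    nr <- n_rounds(x)
    if (length(nr) > 0 && any(nr > 0)) {
      cat(sprintf("  reading rounds per patient: %d-%d\n", min(nr), max(nr)))
    }
  }
  invisible(x)
}

#' Outcome GOS score per patient
#'
#' The 12-month score when recorded, otherwise the 6-month score; `NA` when
#' neither exists. GOS 1 denotes death.
#'
#' @param cohort A `dyn_cohort`.
#' @return Named integer vector, one entry per patient.
#' @export
outcome_gos <- function(cohort) {
  cl <- cohort$clinical
  gos <- ifelse(!is.na(cl$gos12), cl$gos12, cl$gos6)
  names(gos) <- cl$id
  gos
}

#' Binarize GOS scores
#'
#' @param gos Integer GOS scores (1-5).
#' @param rule `"low_high"`: Low = GOS <= 3 (poor outcome), High = GOS >= 4
#'   (favorable); `"survival"`: Low = GOS 1 (death), High = GOS > 1.
#' @return Factor with levels `Low`, `High` (`NA` preserved).
#' @export
binarize_gos <- function(gos, rule = c("low_high", "survival")) {
  rule <- match.arg(rule)
  cut <- if (rule == "low_high") 3 else 1
  factor(ifelse(is.na(gos), NA, ifelse(gos <= cut, "Low", "High")),
         levels = c("Low", "High"))
}

#' Number of reading rounds per patient
#'
#' After round assignment this is the highest round index a patient has; for
#' unassigned readings it falls back to the longest per-mediator series.
#'
#' @param cohort A `dyn_cohort`.
#' @return Named integer vector, one entry per patient (0 when no readings).
#' @export
n_rounds <- function(cohort) {
  cl <- cohort$clinical
  out <- stats::setNames(integer(nrow(cl)), cl$id)
  rd <- cohort$readings
  if (nrow(rd) == 0) return(out)
  if (all(!is.na(rd$round))) {
    mx <- tapply(rd$round, rd$patient_id, max)
  } else {
    len <- tapply(rd$time_hours, paste(rd$patient_id, rd$mediator, sep = "\r"),
                  length)
    ids <- sub("\r.*$", "", names(len))
    mx <- tapply(as.integer(len), ids, max)
  }
  out[names(mx)] <- as.integer(mx)
  out
}

#' Read the clinical CSV
#'
#' One row per patient; boolean flag columns accept 0/1 or TRUE/FALSE.
#' Extra columns are carried along as free covariates.
#'
#' @param path Path to a UTF-8 CSV with header.
#' @param mediator_panel Panel for the resulting cohort skeleton.
#' @return A `dyn_cohort` with empty mediator series.
#' @export
read_clinical <- function(path, mediator_panel = default_mediator_panel()) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.clinical_required, names(cl))
  if (length(missing_cols) > 0) {
    stop("clinical CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cl$id <- as.character(cl$id)
  for (col in c("gcs", "gos6", "gos12")) {
    if (col %in% names(cl)) {
      v <- suppressWarnings(as.integer(cl[[col]]))
      if (any(is.na(v) & !is.na(cl[[col]]) & cl[[col]] != "" &
              !(is.character(cl[[col]]) && toupper(cl[[col]]) == "NA"))) {
        stop("unparsable values in column ", col)
      }
      cl[[col]] <- v
    }
  }
  for (col in .clinical_flags) cl[[col]] <- as.integer(as.logical(as.numeric(cl[[col]])))
  new_cohort(cl, mediator_panel = mediator_panel)
}

#' Read the long-format mediator CSV into a cohort
#'
#' Appends readings (columns `patient_id`, `mediator`, `time_hours`,
#' `concentration_pg_ml`) to an existing cohort skeleton, sorted by time
#' within each (patient, mediator) series. Unknown ids, off-panel mediators,
#' negative concentrations and duplicate timestamps are errors.
#'
#' @param path Path to a UTF-8 CSV with header.
#' @param cohort A `dyn_cohort` already holding the patient ids.
#' @return The cohort with populated series (rounds not yet assigned; see
#'   [assign_rounds()]).
#' @export
read_mediators <- function(path, cohort) {
  rd <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "mediator", "time_hours", "concentration_pg_ml")
  missing_cols <- setdiff(req, names(rd))
  if (length(missing_cols) > 0) {
    stop("mediator CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  rd$patient_id <- as.character(rd$patient_id)
  rd <- rd[order(rd$patient_id, rd$mediator, rd$time_hours), req]
  rd$round <- NA_integer_
  rownames(rd) <- NULL
  new_cohort(cohort$clinical, rd, cohort$mediator_panel)
}

#' Write a cohort to the clinical / mediator CSV pair
#'
#' @param cohort A `dyn_cohort`.
#' @param clinical_path,mediators_path Output CSV paths.
#' @return The two paths, invisibly.
#' @export
write_cohort <- function(cohort, clinical_path, mediators_path) {
  utils::write.csv(cohort$clinical, clinical_path, row.names = FALSE)
  cols <- c("patient_id", "mediator", "time_hours", "concentration_pg_ml")
  utils::write.csv(cohort$readings[, cols, drop = FALSE], mediators_path,
                   row.names = FALSE)
  invisible(c(clinical_path, mediators_path))
}

#' Assign reading rounds
#'
#' A round is the i-th interval after injury during which mediator readings
#' were collected; it is the discrete time axis of the profiling stages.
#' Under the `ordinal` scheme a patient's j-th reading of each mediator is
#' round j; under `time_binned`, round = floor(time / bin_width) + 1.
#'
#' @param cohort A `dyn_cohort` with populated series.
#' @param scheme `"ordinal"` (default) or `"time_binned"`.
#' @param bin_width Bin width in hours (time-binned scheme only).
#' @return The cohort with a `round` column on every reading.
#' @export
assign_rounds <- function(cohort, scheme = c("ordinal", "time_binned"),
                          bin_width = 24) {
  scheme <- match.arg(scheme)
  rd <- cohort$readings
  if (nrow(rd) > 0) {
    ord <- order(rd$patient_id, rd$mediator, rd$time_hours)
    rd <- rd[ord, , drop = FALSE]
    if (scheme == "ordinal") {
      rd$round <- stats::ave(rd$time_hours,
                             paste(rd$patient_id, rd$mediator, sep = "\r"),
                             FUN = seq_along)
    } else {
      if (!is.finite(bin_width) || bin_width <= 0) {
        stop("bin_width must be positive under the time_binned scheme")
      }
      rd$round <- floor(rd$time_hours / bin_width) + 1
    }
    rd$round <- as.integer(rd$round)
    rownames(rd) <- NULL
  }
  new_cohort(cohort$clinical, rd, cohort$mediator_panel)
}

#' Extract one mediator series for one patient
#'
#' @param cohort A `dyn_cohort`.
#' @param id Patient id.
#' @param mediator Mediator name.
#' @param up_to_round Keep readings with round <= this (default all).
#' @return List with `times`, `values` and `rounds` (sorted by time).
#' @export
mediator_series <- function(cohort, id, mediator, up_to_round = Inf) {
  rd <- cohort$readings
  sel <- rd$patient_id == id & rd$mediator == mediator &
    (is.na(rd$round) | rd$round <= up_to_round)
  if (is.finite(up_to_round)) sel <- sel & !is.na(rd$round)
  rd <- rd[sel, , drop = FALSE]
  ord <- order(rd$time_hours)
  list(times = rd$time_hours[ord], values = rd$concentration_pg_ml[ord],
       rounds = rd$round[ord])
}
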