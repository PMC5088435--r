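# Discrete orthonormal polynomial bases over the index grid 1..n.
# Bases depend only on (n, degree); memoized since profiling recomputes
# them thousands of times across stages and leave-one-out folds.
.basis_cache <- new.env(parent = emptyenv())

#' Discrete orthonormal polynomial basis
#'
#' Builds the n x (degree + 1) matrix whose j-th column is the orthonormal
#' polynomial of degree j - 1 over the equally spaced index grid 1..n
#' (Gram-Schmidt orthonormalization of the monomials 1, t, t^2, ...). The
#' degree-0 column is the constant 1/sqrt(n); signs are fixed so each
#' column is positive at the last index. Because every column has unit
#' Euclidean norm, projections of series of different lengths onto the same
#' degree are directly comparable.
#'
#' @param n_points Series length (must exceed `degree`).
#' @param degree Highest polynomial degree, 0-4.
#' @return Matrix with orthonormal columns named `T0`, `L`, `Q`, `C`, `T4`
#'   (level, linear, quadratic, cubic, quartic).
#' @export
trend_basis <- function(n_points, degree) {
  if (degree < 0 || degree > 4) stop("degree must be between 0 and 4")
  if (n_points <= degree) {
    stop("series too short: need at least degree + 1 = ", degree + 1, " points")
  }
  key <- paste(n_points, degree)
  hit <- .basis_cache[[key]]
  if (!is.null(hit)) return(hit)
  t <- seq_len(n_points)
  V <- outer(t, 0:degree, `^`)
  B <- qr.Q(qr(V))[, seq_len(degree + 1), drop = FALSE]
  flip <- B[n_points, ] < 0
  B[, flip] <- -B[, flip]
  colnames(B) <- degree_labels(degree)
  .basis_cache[[key]] <- B
  B
}

#' Column labels for trend degrees
#'
#' @param degree Highest degree.
#' @return Character vector `T0`, `L`, `Q`, `C`, `T4` up to `degree`.
#' @export
degree_labels <- function(degree) {
  c("T0", "L", "Q", "C", "T4")[seq_len(degree + 1)]
}

#' Centered moving-average smoother
#'
#' Window of 3 with shrinking windows at the two ends (the first and last
#' points average over the two observations available to them).
#'
#' @param values Numeric series.
#' @return Smoothed series of equal length.
#' @export
smooth_series <- function(values) {
  n <- length(values)
  if (n <= 2) return(values)
  out <- values
  out[1] <- mean(values[1:2])
  out[n] <- mean(values[(n - 1):n])
  out[2:(n - 1)] <- (values[1:(n - 2)] + values[2:(n - 1)] + values[3:n]) / 3
  out
}

#' Extract orthogonal polynomial trend coefficients from a series
#'
#' Projects the (optionally smoothed) series onto the discrete orthonormal
#' polynomial basis over its own index grid: `coefficients = t(B) %*% y`.
#' Series shorter than degree + 1 points cannot support the basis and are
#' flagged unusable rather than raising an error.
#'
#' @param values Numeric concentrations, one per round, in round order.
#' @param degree Highest polynomial degree (0-4).
#' @param smooth Smooth with [smooth_series()] before projecting
#'   (default FALSE: abrupt mediator changes are part of the signal and the
#'   higher-degree terms are meant to capture them).
#' @return List of class `trend_coefficients`: `coefficients` (named numeric,
#'   `NULL` when unusable), `usable`, `n_points`, `degree`.
#' @export
extract_trends <- function(values, degree, smooth = FALSE) {
  n <- length(values)
  if (n < degree + 1) {
    return(structure(list(coefficients = NULL, usable = FALSE,
                          n_points = n, degree = degree),
                     class = "trend_coefficients"))
  }
  y <- if (smooth) smooth_series(values) else values
  B <- trend_basis(n, degree)
  co <- drop(crossprod(B, y))
  names(co) <- colnames(B)
  structure(list(coefficients = co, usable = TRUE, n_points = n,
                 degree = degree),
            class = "trend_coefficients")
}

#' @export
print.trend_coefficients <- function(x, ...) {
  if (!x$usable) {
    cat(sprintf("<trend_coefficients> unusable: %d point(s) < degree %d + 1\n",
                x$n_points, x$degree))
  } else {
    cat(sprintf("<trend_coefficients> degree %d over %d points\n",
                x$degree, x$n_points))
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' Residuals of a polynomial trend fit
#'
#' @param values The series the coefficients were extracted from.
#' @param trends A usable `trend_coefficients` for that series.
#' @return List with `residuals` (series minus basis reconstruction) and
#'   `variance` (their sample variance; 0 for a saturated basis).
#' @export
residual_summary <- function(values, trends) {
  if (!inherits(trends, "trend_coefficients") || !trends$usable) {
    stop("trend coefficients are unusable (series shorter than degree + 1)")
  }
  if (length(values) != trends$n_points) {
    stop("series length does not match the fitted coefficients")
  }
  B <- trend_basis(trends$n_points, trends$degree)
  res <- values - drop(B %*% trends$coefficients)
  v <- if (length(res) > 1) stats::var(res) else 0
  list(residuals = res, variance = v)
}

#' Per-patient trend feature table for a cohort
#'
#' One row per included patient and `13 * (degree + 1)` columns named
#' `<mediator>.T0`, `<mediator>.L`, ... Each mediator series (optionally
#' truncated at a round horizon) is collapsed to one value per round and
#' projected onto its own orthonormal basis, so coefficients of equal degree
#' are comparable across series of different lengths. Patients with any
#' mediator series shorter than degree + 1 rounds cannot support the basis
#' and are excluded; the exclusion mask reports them.
#'
#' @param cohort A `dyn_cohort` with rounds assigned.
#' @param degree Highest polynomial degree (0-4).
#' @param up_to_round Use readings with round <= this (default all).
#' @param smooth Passed to [extract_trends()].
#' @return List with `features` (data frame, rownames = patient ids),
#'   `included` and `excluded` (id vectors).
#' @export
trend_matrix <- function(cohort, degree, up_to_round = Inf, smooth = FALSE) {
  if (degree < 0 || degree > 4) stop("degree must be between 0 and 4")
  ids <- cohort$clinical$id
  panel <- cohort$mediator_panel
  labs <- degree_labels(degree)
  cols <- as.vector(t(outer(panel, labs, paste, sep = ".")))
  feat <- matrix(NA_real_, nrow = length(ids), ncol = length(cols),
                 dimnames = list(ids, cols))
  ok <- rep(TRUE, length(ids))
  for (i in seq_along(ids)) {
    for (m in panel) {
      y <- round_values(cohort, ids[i], m, up_to_round)
      tr <- extract_trends(y, degree, smooth = smooth)
      if (!tr$usable) { ok[i] <- FALSE; break }
      feat[i, paste(m, labs, sep = ".")] <- tr$coefficients
    }
  }
  list(features = as.data.frame(feat[ok, , drop = FALSE]),
       included = ids[ok], excluded = ids[!ok])
}

# One value per round for a (patient, mediator): readings sharing a round
# (possible under time-binned schemes) are averaged; rounds with no reading
# are simply absent (the series is the ordered sequence of observed rounds).
round_values <- function(cohort, id, mediator, up_to_round = Inf) {
  s <- mediator_series(cohort, id, mediator, up_to_round = up_to_round)
  if (length(s$values) == 0) return(numeric(0))
  if (anyNA(s$rounds)) return(s$values)
  as.numeric(tapply(s$values, s$rounds, mean))
}
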