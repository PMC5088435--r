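#' Stratified train/test split of a cohort
#'
#' Splits patient ids into disjoint, exhaustive train and test sets,
#' stratified by the binarized outcome so small test sets are not left
#' without any deaths. Reproducible under `seed`.
#'
#' @param cohort A `dyn_cohort` (at least 2 patients).
#' @param train_fraction Proportion in (0, 1); the train size is rounded to
#'   nearest within each stratum with at least one test patient overall.
#' @param seed Integer seed.
#' @param rule Binarization rule passed to [binarize_gos()].
#' @return List with `train` and `test` id vectors.
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1,
                         rule = c("survival", "low_high")) {
  rule <- match.arg(rule)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be strictly between 0 and 1")
  }
  ids <- cohort$clinical$id
  if (length(ids) < 2) stop("cohort must contain at least 2 patients")
  cls <- as.character(binarize_gos(outcome_gos(cohort), rule))
  cls[is.na(cls)] <- "unknown"
  # largest-remainder allocation: per-stratum counts proportional to the
  # stratum size, summing exactly to round(fraction * n), with at least one
  # patient on each side overall
  n_total <- round(train_fraction * length(ids))
  n_total <- min(max(n_total, 1), length(ids) - 1)
  groups <- split(ids, cls)
  quota <- train_fraction * lengths(groups)
  n_tr <- floor(quota)
  short <- n_total - sum(n_tr)
  if (short > 0) {
    extra <- order(quota - n_tr, decreasing = TRUE)
    n_tr[extra[seq_len(short)]] <- n_tr[extra[seq_len(short)]] + 1
  } else if (short < 0) {
    cut <- order(quota - n_tr)
    take <- utils::head(cut[n_tr[cut] > 0], -short)
    n_tr[take] <- n_tr[take] - 1
  }
  n_tr <- pmin(n_tr, lengths(groups))
  set.seed(seed)
  train <- unlist(lapply(seq_along(groups), function(g) {
    sample(groups[[g]], n_tr[g])
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

#' Coefficient table with t statistics
#'
#' The fit-report layout: term, estimate, standard error and t value
#' (estimate / SE). Used internally by [fit_outcome()] and exported so
#' reports can be rebuilt from printed estimate/SE pairs.
#'
#' @param estimate,se Numeric vectors of equal length.
#' @param term Term names (defaults to names of `estimate`).
#' @return Data frame with columns `term`, `value`, `std_error`, `t_value`.
#' @export
coef_table <- function(estimate, se, term = names(estimate)) {
  if (is.null(term)) term <- paste0("b", seq_along(estimate) - 1)
  data.frame(term = term, value = as.numeric(estimate),
             std_error = as.numeric(se),
             t_value = as.numeric(estimate) / as.numeric(se),
             stringsAsFactors = FALSE)
}

#' Fit a binary outcome model
#'
#' Maximum-likelihood logistic or probit regression of a binarized GOS
#' outcome on clinical and trend features, fitted by iteratively reweighted
#' least squares with standard errors from the observed information. With
#' n of a few dozen and strong predictors the likelihood can separate
#' (fitted probabilities of exactly 0/1); separation is flagged and, by
#' default, the model is refitted with a small ridge penalty
#' (`ridge * sum(beta^2)`, intercept unpenalized) to stabilize the
#' estimates.
#'
#' @param features Data frame / matrix of predictors (rows = patients).
#' @param outcomes Binary vector (1 = survival / High, 0 = death / Low).
#' @param link `"logit"` or `"probit"`.
#' @param terms Columns of `features` to use (default all).
#' @param ridge Ridge penalty used on separation (0 disables the fallback,
#'   in which case a non-converged fit is an error).
#' @return Object of class `outcome_fit`: `table` (the [coef_table()]),
#'   `coefficients`, `fitted` (survival probabilities), `link`, `terms`,
#'   `separation`, `converged`, `ridge_used`.
#' @export
fit_outcome <- function(features, outcomes, link = c("logit", "probit"),
                        terms = NULL, ridge = 1e-4) {
  link <- match.arg(link)
  X <- as.data.frame(features)
  if (!is.null(terms)) {
    missing_terms <- setdiff(terms, names(X))
    if (length(missing_terms) > 0) {
      stop("terms not present in the feature table: ",
           paste(missing_terms, collapse = ", "))
    }
    X <- X[, terms, drop = FALSE]
  }
  y <- as.numeric(outcomes)
  if (length(y) != nrow(X)) stop("features and outcomes differ in length")
  if (ncol(X) > 0) {
    sds <- vapply(X, stats::sd, numeric(1))
    if (any(!is.na(sds) & sds == 0)) {
      stop("zero-variance predictor(s): ",
           paste(names(X)[!is.na(sds) & sds == 0], collapse = ", "))
    }
  }
  if (length(y) <= ncol(X) + 1) stop("more terms than observations")

  dat <- cbind(.y = y, X)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(link = link))
  )
  p <- stats::fitted(fit)
  separated <- !fit$converged || any(p < 1e-8 | p > 1 - 1e-8) ||
    any(abs(stats::coef(fit)) > 1e3, na.rm = TRUE)
  ridge_used <- FALSE
  if (separated && ridge > 0) {
    rf <- ridge_binomial(stats::model.matrix(fit), y, link, lambda = ridge)
    est <- rf$coefficients; se <- rf$se; p <- rf$fitted
    converged <- rf$converged; ridge_used <- TRUE
  } else {
    if (!fit$converged && ridge <= 0) stop("IRLS did not converge")
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    converged <- fit$converged
  }
  names(est)[1] <- names(se)[1] <- "(Intercept)"
  structure(list(table = coef_table(est, se),
                 coefficients = est, se = se,
                 fitted = as.numeric(p), link = link, terms = names(X),
                 separation = separated, converged = converged,
                 ridge_used = ridge_used),
            class = "outcome_fit")
}

# Ridge-penalized IRLS for binomial GLMs; SEs from the penalized observed
# information (X'WX + 2*lambda*P)^-1. Intercept unpenalized.
ridge_binomial <- function(X, y, link, lambda = 1e-4, max_iter = 100,
                           tol = 1e-9) {
  fam <- stats::binomial(link = link)
  P <- diag(ncol(X)); P[1, 1] <- 0
  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    gprime <- fam$mu.eta(eta)
    w <- gprime^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / gprime
    A <- crossprod(X, w * X) + 2 * lambda * P
    b <- crossprod(X, w * z)
    beta_new <- drop(solve(A, b))
    if (max(abs(beta_new - beta)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  mu <- fam$linkinv(eta)
  gprime <- fam$mu.eta(eta)
  w <- gprime^2 / pmin(pmax(mu * (1 - mu), 1e-12), 1)
  A <- crossprod(X, w * X) + 2 * lambda * P
  se <- sqrt(diag(solve(A)))
  names(se) <- colnames(X)
  list(coefficients = stats::setNames(beta, colnames(X)), se = se,
       fitted = mu, converged = converged)
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("<outcome_fit> %s link, %d term(s)%s%s\n", x$link,
              length(x$terms),
              if (x$separation) ", separation flagged" else "",
              if (x$ridge_used) ", ridge refit" else ""))
  tab <- x$table
  tab[, 2:4] <- round(tab[, 2:4], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Survival probability for new feature rows
#'
#' Inverse link of the linear predictor built from the fit's terms.
#'
#' @param fit An `outcome_fit`.
#' @param features Data frame (or single named row) with every model term.
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict_prob <- function(fit, features) {
  if (!is.data.frame(features) && !is.matrix(features)) {
    features <- as.data.frame(as.list(features))
  }
  features <- as.data.frame(features)
  missing_terms <- setdiff(fit$terms, names(features))
  if (length(missing_terms) > 0) {
    stop("feature row is missing model term(s): ",
         paste(missing_terms, collapse = ", "))
  }
  X <- cbind(1, as.matrix(features[, fit$terms, drop = FALSE]))
  eta <- drop(X %*% fit$coefficients)
  stats::binomial(link = fit$link)$linkinv(eta)
}

#' Marginal pre-screening of the trend predictor pool
#'
#' With a few dozen patients and a 10 + 13(d+1) candidate pool the full
#' model is unfittable, so each mediator's trend block is fitted on its own
#' (alongside any always-kept clinical terms) and terms reaching `|t| >=
#' t_cut` survive into the pooled model.
#'
#' @param features Full candidate feature table.
#' @param outcomes Binary outcome vector.
#' @param blocks Named list mapping block label to column names (e.g. one
#'   block per mediator).
#' @param keep Columns always carried into each block fit (not screened).
#' @param link,t_cut,ridge See [fit_outcome()] / [select_terms()].
#' @return Character vector of surviving column names (block order).
#' @export
prescreen_terms <- function(features, outcomes, blocks, keep = character(0),
                            link = "logit", t_cut = 1.5, ridge = 1e-4) {
  survivors <- character(0)
  for (cols in blocks) {
    fit <- fit_outcome(features, outcomes, link = link,
                       terms = c(keep, cols), ridge = ridge)
    tab <- fit$table
    hit <- tab$term %in% cols & abs(tab$t_value) >= t_cut
    survivors <- c(survivors, tab$term[hit])
  }
  unique(survivors)
}

#' Backward elimination by t statistic
#'
#' Repeatedly drops the term with the smallest `|t|` (ties broken by column
#' order, later column dropped first) and refits, until every remaining
#' term satisfies `|t| >= t_cut`. The intercept is never dropped.
#'
#' @param features Feature table.
#' @param outcomes Binary outcome vector.
#' @param terms Starting term set (default all columns).
#' @param t_cut Retention threshold on `|t|` (default 1.5).
#' @param link,ridge Passed to [fit_outcome()].
#' @return List with `terms` (retained set, possibly empty = intercept-only)
#'   and `fit` (the final `outcome_fit`, `NULL` when everything was
#'   eliminated).
#' @export
select_terms <- function(features, outcomes, terms = NULL, t_cut = 1.5,
                         link = "logit", ridge = 1e-4) {
  features <- as.data.frame(features)
  if (is.null(terms)) terms <- names(features)
  while (length(terms) > 0) {
    fit <- fit_outcome(features, outcomes, link = link, terms = terms,
                       ridge = ridge)
    tab <- fit$table[fit$table$term != "(Intercept)", ]
    tvals <- abs(tab$t_value)
    if (all(tvals >= t_cut)) return(list(terms = terms, fit = fit))
    # smallest |t|; on a tie the later column goes first
    worst <- tab$term[max(which(tvals == min(tvals)))]
    terms <- setdiff(terms, worst)
  }
  warning("all terms eliminated; returning intercept-only model")
  list(terms = character(0), fit = NULL)
}

#' Ordinal (proportional-odds) model on the full 5-level GOS
#'
#' Companion variant to the binary model: a proportional-odds logistic
#' regression of the raw GOS score (1-5) on the same predictor pool, via
#' `MASS::polr`. The binary model remains the primary deliverable; this
#' variant exposes the full ordinal outcome when the cohort supports it.
#'
#' @param features Data frame of predictors.
#' @param gos Integer GOS scores (1-5), same length as rows of `features`.
#' @param terms Columns to use (default all).
#' @return List with `table` (term/value/SE/t for the slopes), `zeta`
#'   (cutpoints) and the underlying `polr` fit.
#' @export
fit_gos_ordinal <- function(features, gos, terms = NULL) {
  if (!requireNamespace("MASS", quietly = TRUE)) {
    stop("the ordinal variant requires the MASS package")
  }
  X <- as.data.frame(features)
  if (!is.null(terms)) X <- X[, terms, drop = FALSE]
  if (any(is.na(gos)) || any(gos < 1 | gos > 5)) {
    stop("gos must be within [1, 5] with no missing values")
  }
  dat <- cbind(.gos = factor(gos, levels = 1:5, ordered = TRUE), X)
  fit <- MASS::polr(.gos ~ ., data = dat, method = "logistic", Hess = TRUE)
  sm <- summary(fit)
  co <- sm$coefficients
  slopes <- co[rownames(co) %in% names(X), , drop = FALSE]
  list(table = coef_table(slopes[, 1], slopes[, 2], rownames(slopes)),
       zeta = fit$zeta, fit = fit)
}

#' Classification accuracy and confusion counts
#'
#' Classifies survival when the predicted probability strictly exceeds the
#' threshold (a probability of exactly 0.5 at the default threshold is
#' called non-survival).
#'
#' @param probabilities Predicted survival probabilities.
#' @param outcomes Observed binary outcomes (1 = survival).
#' @param threshold Classification threshold (default 0.5).
#' @return List with `accuracy`, `correct`, `n`, confusion counts `tp`,
#'   `fp`, `tn`, `fn`, and the index vector `misclassified`.
#' @export
evaluate_predictions <- function(probabilities, outcomes, threshold = 0.5) {
  if (length(probabilities) == 0) stop("empty input")
  if (length(probabilities) != length(outcomes)) {
    stop("probabilities and outcomes differ in length")
  }
  pred <- as.integer(probabilities > threshold)
  y <- as.integer(outcomes)
  list(accuracy = mean(pred == y),
       correct = sum(pred == y),
       n = length(y),
       tp = sum(pred == 1 & y == 1),
       fp = sum(pred == 1 & y == 0),
       tn = sum(pred == 0 & y == 0),
       fn = sum(pred == 0 & y == 1),
       misclassified = which(pred != y))
}
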