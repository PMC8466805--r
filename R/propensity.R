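#' Fit the enrollment propensity logit by maximum likelihood
#'
#' Estimates \eqn{P(W = 1 \mid x)} with a logistic regression fitted by
#' iteratively reweighted least squares. Covariates enter numerically
#' (ordinal education/region/wealth codes as integers) unless `onehot` is
#' set, mirroring the integer coding of the descriptive table. Convergence
#' is declared when the largest coefficient change falls below `tol`;
#' perfect separation and rank-deficient designs raise explicit errors.
#'
#' @param covariates data frame of covariates (numeric columns).
#' @param treatment 0/1 vector.
#' @param columns covariate columns to include; defaults to the canonical
#'   eight child/mother/household covariates present in the data.
#' @param onehot expand `mother_education`, `region`, `wealth_quintile`
#'   into indicator columns instead of entering them as integer codes.
#' @param tol convergence tolerance on the max absolute coefficient change.
#' @param max_iter iteration cap.
#' @return object of class `propensity_model`: `coefficients` (named,
#'   intercept first), `converged`, `iterations`, `loglik`, `columns`,
#'   `fitted`.
#' @export
fit_propensity_logit <- function(covariates, treatment, columns = NULL,
                                 onehot = FALSE, tol = 1e-8, max_iter = 100L) {
  if (!all(treatment %in% c(0, 1))) stop("treatment must be 0/1", call. = FALSE)
  if (length(unique(treatment)) < 2) {
    stop("treatment has no variation: cannot fit a propensity model", call. = FALSE)
  }
  if (is.null(columns)) columns <- intersect(covariate_columns(), names(covariates))
  X <- build_design(covariates, columns, onehot = onehot)
  if (nrow(X) != length(treatment)) stop("covariates/treatment length mismatch", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  w <- as.numeric(treatment)
  beta <- rep(0, ncol(X))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    wt <- mu * (1 - mu)
    # IRLS step: weighted least squares on the working response
    z <- eta + (w - mu) / pmax(wt, 1e-12)
    fit <- stats::lm.wfit(X, z, pmax(wt, 1e-12))
    new_beta <- fit$coefficients
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (!all(is.finite(beta)) || max(abs(beta)) > 50) {
      stop("propensity logit diverged (perfect or quasi-perfect separation)", call. = FALSE)
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  if (all(mu[w == 1] > 1 - 1e-6) && all(mu[w == 0] < 1e-6)) {
    stop("propensity logit diverged (perfect or quasi-perfect separation)", call. = FALSE)
  }
  loglik <- sum(w * log(pmax(mu, 1e-300)) + (1 - w) * log(pmax(1 - mu, 1e-300)))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 converged = converged, iterations = iter, loglik = loglik,
                 columns = columns, onehot = onehot, fitted = mu),
            class = "propensity_model")
}

# intercept + selected covariates, optionally one-hot encoding the ordinal codes
build_design <- function(covariates, columns, onehot = FALSE) {
  missing <- setdiff(columns, names(covariates))
  if (length(missing)) {
    stop("covariates are missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (onehot) {
    enc <- encode_covariates(covariates[columns])
    X <- cbind(intercept = 1, as.matrix(enc))
  } else {
    X <- cbind(intercept = 1, as.matrix(covariates[columns]))
  }
  storage.mode(X) <- "double"
  X
}

#' @export
print.propensity_model <- function(x, ...) {
  cat("Propensity logit (IRLS):", length(x$coefficients), "coefficients;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iterations; log-likelihood", format(x$loglik), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict propensity scores from a fitted model
#'
#' @param model a `propensity_model` from [fit_propensity_logit()].
#' @param covariates covariate table with the model's training columns.
#' @return numeric vector of scores in (0, 1).
#' @export
predict_propensity <- function(model, covariates) {
  stopifnot(inherits(model, "propensity_model"))
  if (!model$converged) stop("propensity model did not converge", call. = FALSE)
  X <- build_design(covariates, model$columns, onehot = model$onehot)
  if (!identical(colnames(X), names(model$coefficients))) {
    stop("covariate columns do not match the fitted model", call. = FALSE)
  }
  stats::plogis(drop(X %*% model$coefficients))
}

#' Common-support interval of the propensity scores
#'
#' The overlap interval is \[max of per-arm minima, min of per-arm maxima\];
#' records outside it are flagged and excluded from matching.
#'
#' @param scores propensity scores.
#' @param treatment 0/1 vector.
#' @return list with `interval` (length-2), `in_support` (logical vector),
#'   `n_dropped` (records outside support).
#' @export
common_support <- function(scores, treatment) {
  stopifnot(length(scores) == length(treatment))
  t_scores <- scores[treatment == 1]
  c_scores <- scores[treatment == 0]
  if (!length(t_scores) || !length(c_scores)) {
    stop("both treatment arms must be nonempty", call. = FALSE)
  }
  lo <- max(min(t_scores), min(c_scores))
  hi <- min(max(t_scores), max(c_scores))
  if (lo > hi) stop("common support is empty", call. = FALSE)
  in_support <- scores >= lo & scores <= hi
  list(interval = c(lo, hi), in_support = in_support, n_dropped = sum(!in_support))
}

#' Binned propensity-score histogram data by arm
#'
#' Emits the two-panel histogram (treated vs control score distributions)
#' as plain binned counts, suitable for plotting or CSV export.
#'
#' @param scores propensity scores.
#' @param treatment 0/1 vector.
#' @param breaks number of equal-width bins on \[0, 1\].
#' @return data frame with `bin_lower`, `bin_upper`, `arm`, `count`.
#' @export
propensity_histogram <- function(scores, treatment, breaks = 20) {
  edges <- seq(0, 1, length.out = breaks + 1)
  one_arm <- function(arm, w) {
    cnt <- as.vector(table(cut(scores[treatment == w], edges, include.lowest = TRUE)))
    data.frame(bin_lower = utils::head(edges, -1), bin_upper = edges[-1],
               arm = arm, count = cnt)
  }
  rbind(one_arm("treated", 1), one_arm("control", 0))
}
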