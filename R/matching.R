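#' Nearest-neighbor propensity-score matching
#'
#' For each treated unit inside common support, finds the `k` in-support
#' controls closest in propensity score (1-D Euclidean distance), each
#' with weight 1/k. Ties are broken by the lowest control record index;
#' matching is with replacement by default (controls are a small minority
#' of the sample, so without-replacement matching would exhaust the pool).
#'
#' @param scores propensity scores for all records.
#' @param treatment 0/1 vector.
#' @param k number of matched controls per treated unit.
#' @param with_replacement reuse controls across treated units (default).
#' @param support optional result of [common_support()]; computed when NULL.
#' @param caliper optional maximum score distance; matches beyond it are
#'   dropped (no caliper by default).
#' @return object of class `match_result`: `pairs` (data frame with
#'   `treated`, `control`, `weight` in original record indices), `method`,
#'   `k`, `n_treated_matched`, `n_dropped`, `support`.
#' @export
nn_match <- function(scores, treatment, k = 1L, with_replacement = TRUE,
                     support = NULL, caliper = NULL) {
  if (is.null(support)) support <- common_support(scores, treatment)
  t_idx <- which(treatment == 1 & support$in_support)
  c_idx <- which(treatment == 0 & support$in_support)
  if (!length(t_idx)) stop("no treated units inside common support", call. = FALSE)
  if (length(c_idx) < k) stop("k exceeds the in-support control pool", call. = FALSE)
  if (!with_replacement && length(c_idx) < k * length(t_idx)) {
    stop("control pool too small for matching without replacement", call. = FALSE)
  }
  pool <- c_idx
  tr_out <- vector("list", length(t_idx))
  ct_out <- vector("list", length(t_idx))
  wt_out <- vector("list", length(t_idx))
  for (ii in seq_along(t_idx)) {
    i <- t_idx[ii]
    d <- abs(scores[pool] - scores[i])
    ord <- order(d, pool)[seq_len(k)]
    if (!is.null(caliper)) ord <- ord[d[ord] <= caliper]
    if (!length(ord)) next
    tr_out[[ii]] <- rep.int(i, length(ord))
    ct_out[[ii]] <- pool[ord]
    wt_out[[ii]] <- rep.int(1 / length(ord), length(ord))
    if (!with_replacement) pool <- pool[-ord]
  }
  if (!length(unlist(tr_out))) stop("no treated unit could be matched", call. = FALSE)
  pairs <- data.frame(treated = unlist(tr_out), control = unlist(ct_out),
                      weight = unlist(wt_out))
  structure(list(pairs = pairs, method = if (k == 1L) "nn_1" else "nn_k",
                 k = k, bandwidth = NULL,
                 n_treated_matched = length(unique(pairs$treated)),
                 n_dropped = length(t_idx) - length(unique(pairs$treated)),
                 support = support),
            class = "match_result")
}

#' Kernel propensity-score matching weights
#'
#' Weights every in-support control for each treated unit by a kernel of
#' the propensity-score distance, normalized to sum to one per treated
#' unit. The Epanechnikov kernel \eqn{K(u) = 0.75 (1 - u^2) 1\{|u| < 1\}}
#' with bandwidth 0.06 is the default; a Gaussian kernel is available.
#' Treated units with zero total kernel mass are dropped with a warning.
#'
#' @param scores propensity scores.
#' @param treatment 0/1 vector.
#' @param bandwidth kernel bandwidth (> 0), default 0.06.
#' @param kernel `"epanechnikov"` (default) or `"gaussian"`.
#' @param support optional [common_support()] result.
#' @return a `match_result` (see [nn_match()]) with `method = "kernel"`.
#' @export
kernel_match_weights <- function(scores, treatment, bandwidth = 0.06,
                                 kernel = c("epanechnikov", "gaussian"),
                                 support = NULL) {
  kernel <- match.arg(kernel)
  if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  if (is.null(support)) support <- common_support(scores, treatment)
  t_idx <- which(treatment == 1 & support$in_support)
  c_idx <- which(treatment == 0 & support$in_support)
  if (!length(t_idx) || !length(c_idx)) stop("an arm is empty inside support", call. = FALSE)
  kfun <- switch(kernel,
                 epanechnikov = function(u) 0.75 * (1 - u^2) * (abs(u) < 1),
                 gaussian = stats::dnorm)
  tr_out <- vector("list", length(t_idx))
  ct_out <- vector("list", length(t_idx))
  wt_out <- vector("list", length(t_idx))
  dropped <- 0L
  c_scores <- scores[c_idx]
  for (ii in seq_along(t_idx)) {
    i <- t_idx[ii]
    kw <- kfun((scores[i] - c_scores) / bandwidth)
    tot <- sum(kw)
    if (tot <= 0) { dropped <- dropped + 1L; next }
    keep <- which(kw > 0)
    tr_out[[ii]] <- rep.int(i, length(keep))
    ct_out[[ii]] <- c_idx[keep]
    wt_out[[ii]] <- kw[keep] / tot
  }
  if (dropped > 0) {
    warning(sprintf("%d treated unit(s) dropped: zero kernel mass within bandwidth", dropped))
  }
  if (!length(unlist(tr_out))) stop("all treated units had zero kernel mass", call. = FALSE)
  pairs <- data.frame(treated = unlist(tr_out), control = unlist(ct_out),
                      weight = unlist(wt_out))
  structure(list(pairs = pairs, method = "kernel", k = NULL, bandwidth = bandwidth,
                 n_treated_matched = length(unique(pairs$treated)),
                 n_dropped = dropped, support = support),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Propensity-score match (", x$method, "): ", x$n_treated_matched,
      " treated units matched, ", x$n_dropped, " dropped\n", sep = "")
  invisible(x)
}

#' Average treatment effect on the treated from matched samples
#'
#' ATT = mean over matched treated units of the treated outcome minus the
#' weighted outcome of its matched controls.
#'
#' @param match_result a `match_result`.
#' @param outcome outcome vector for all records.
#' @param treatment 0/1 vector (used for bookkeeping counts).
#' @param se optional standard error to attach (e.g. from [bootstrap_se()]).
#' @return object of class `effect_estimate`: `estimand` ("ATT"), `value`,
#'   `se`, `stars`, `n_treated`, `n_control_used`.
#' @export
estimate_att <- function(match_result, outcome, treatment, se = NA_real_) {
  stopifnot(inherits(match_result, "match_result"))
  p <- match_result$pairs
  if (!nrow(p)) stop("match result covers no treated units", call. = FALSE)
  counterfactual <- tapply(p$weight * outcome[p$control], p$treated, sum)
  treated_ids <- as.integer(names(counterfactual))
  value <- mean(outcome[treated_ids] - counterfactual)
  stars <- if (is.finite(se) && se > 0) {
    significance_stars(2 * stats::pnorm(-abs(value / se)),
                       levels = c("***" = 0.01, "**" = 0.05))
  } else ""
  structure(list(estimand = "ATT", value = value, se = se, stars = stars,
                 n_treated = length(treated_ids),
                 n_control_used = length(unique(p$control))),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s = %.3f %s(SE %s; %d treated, %d controls used)\n",
              x$estimand, x$value, x$stars,
              if (is.finite(x$se)) sprintf("%.3f", x$se) else "not computed",
              x$n_treated, x$n_control_used))
  invisible(x)
}

#' Run a full PSM analysis on a dataset
#'
#' Convenience wrapper: fits the propensity logit on the canonical
#' covariates, trims to common support, matches by the requested method,
#' and estimates the ATT.
#'
#' @param data analysis table (covariates + `treatment` + `outcome`).
#' @param method `"nn_1"`, `"nn_k"`, or `"kernel"`.
#' @param k neighbors for `nn_k` (default 4).
#' @param bandwidth kernel bandwidth.
#' @param kernel kernel type, see [kernel_match_weights()].
#' @return list with `model`, `scores`, `support`, `match`, `att`.
#' @export
psm_att <- function(data, method = c("kernel", "nn_1", "nn_k"), k = 4L,
                    bandwidth = 0.06, kernel = "epanechnikov") {
  method <- match.arg(method)
  validate_dataset(data)
  model <- fit_propensity_logit(data, data$treatment)
  scores <- model$fitted
  support <- common_support(scores, data$treatment)
  match <- switch(method,
    nn_1 = nn_match(scores, data$treatment, k = 1L, support = support),
    nn_k = nn_match(scores, data$treatment, k = k, support = support),
    kernel = kernel_match_weights(scores, data$treatment, bandwidth = bandwidth,
                                  kernel = kernel, support = support))
  att <- estimate_att(match, data$outcome, data$treatment)
  list(model = model, scores = scores, support = support, match = match, att = att)
}

#' Bootstrap standard error of a matching estimator
#'
#' Nonparametric bootstrap over records: each resample re-fits the
#' propensity model, re-establishes common support, re-matches, and
#' re-estimates the ATT; the SE is the standard deviation of the resampled
#' estimates. Resamples where estimation fails (e.g. a degenerate arm) are
#' skipped; more than 10% failures is an error.
#'
#' @param data analysis table.
#' @param estimator function(data) -> numeric estimate; defaults to the
#'   kernel-matching ATT via [psm_att()].
#' @param B number of resamples (>= 2), default 200.
#' @param seed RNG seed.
#' @return list with `se`, `estimates` (successful resample values),
#'   `n_failed`.
#' @export
bootstrap_se <- function(data, estimator = NULL, B = 200L, seed = 1L) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  if (is.null(estimator)) estimator <- function(d) psm_att(d, method = "kernel")$att$value
  set.seed(seed)
  n <- nrow(data)
  est <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    # per-resample warnings (e.g. occasional zero-mass drops) are routine here
    est[b] <- tryCatch(suppressWarnings(estimator(data[idx, , drop = FALSE])),
                       error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(est))
  if (n_failed > 0.1 * B) {
    stop(sprintf("bootstrap estimator failed on %d of %d resamples", n_failed, B), call. = FALSE)
  }
  list(se = stats::sd(est, na.rm = TRUE), estimates = est[!is.na(est)], n_failed = n_failed)
}

#' Covariate balance before and after matching
#'
#' Standardized mean difference per covariate,
#' \eqn{(\bar{x}_T - \bar{x}_{C})/\sqrt{(s_T^2 + s_C^2)/2}}, where the
#' post-matching control mean reweights controls by their total matching
#' weight. The denominator uses the pre-matching arm variances in both
#' columns so the two are on the same scale. Covariates with zero pooled
#' variance are skipped with a warning.
#'
#' @param covariates covariate table.
#' @param treatment 0/1 vector.
#' @param match_result a `match_result`.
#' @param columns covariates to check; default the canonical eight.
#' @return data frame with `covariate`, `smd_before`, `smd_after`.
#' @export
balance_check <- function(covariates, treatment, match_result, columns = NULL) {
  stopifnot(inherits(match_result, "match_result"))
  if (is.null(columns)) columns <- intersect(covariate_columns(), names(covariates))
  p <- match_result$pairs
  treated_ids <- unique(p$treated)
  # aggregate weight each control receives across treated units
  cw <- tapply(p$weight, p$control, sum)
  c_ids <- as.integer(names(cw))
  cw <- as.numeric(cw) / sum(cw)
  rows <- lapply(columns, function(v) {
    x <- covariates[[v]]
    vt <- stats::var(x[treatment == 1])
    vc <- stats::var(x[treatment == 0])
    pooled <- sqrt((vt + vc) / 2)
    if (!is.finite(pooled) || pooled == 0) {
      warning("covariate '", v, "' skipped: zero pooled variance")
      return(NULL)
    }
    before <- (mean(x[treatment == 1]) - mean(x[treatment == 0])) / pooled
    after <- (mean(x[treated_ids]) - sum(cw * x[c_ids])) / pooled
    data.frame(covariate = v, smd_before = before, smd_after = after)
  })
  do.call(rbind, rows)
}
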