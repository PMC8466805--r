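#' Out-of-bag nuisance predictions from a regression forest
#'
#' Fits a random (regression) forest to a numeric target and returns
#' out-of-bag predictions for every training record, the cross-fitting
#' device that keeps each record's nuisance estimate independent of its
#' own outcome. For a binary target (the treatment indicator) predictions
#' are clipped to \[0.01, 0.99\] so downstream treatment residuals are
#' bounded away from zero. A constant target short-circuits to that
#' constant with a warning.
#'
#' @param X numeric data frame / matrix of predictors.
#' @param target numeric vector (outcome) or 0/1 vector (treatment).
#' @param num_trees trees in the forest.
#' @param min_node_size minimum node size.
#' @param seed RNG seed.
#' @return numeric vector of out-of-bag predictions, one per record.
#' @export
fit_regression_forest <- function(X, target, num_trees = 200L,
                                  min_node_size = 5L, seed = 1L) {
  stopifnot(nrow(X) == length(target), nrow(X) >= 10)
  binary <- all(target %in% c(0, 1))
  if (stats::var(target) == 0) {
    warning("constant target: returning constant nuisance predictions")
    return(rep(target[1], length(target)))
  }
  df <- as.data.frame(X)
  names(df) <- make.names(names(df), unique = TRUE)
  df$.target <- as.numeric(target)
  fit <- ranger::ranger(dependent.variable.name = ".target", data = df,
                        num.trees = num_trees, min.node.size = min_node_size,
                        seed = seed, num.threads = 1)
  pred <- fit$predictions
  # records never out-of-bag (possible with few trees) fall back to the mean
  pred[!is.finite(pred)] <- mean(target)
  if (binary) pred <- pmin(pmax(pred, 0.01), 0.99)
  pred
}

#' Estimate both nuisance functions for orthogonalization
#'
#' Convenience wrapper fitting the conditional-mean forest \eqn{\hat m(x)}
#' for the outcome and the propensity forest \eqn{\hat p(x)} for the
#' treatment, each with out-of-bag cross-fitting.
#'
#' @inheritParams fit_regression_forest
#' @param Y outcome vector.
#' @param W 0/1 treatment vector.
#' @return list with `m_hat`, `p_hat`.
#' @export
estimate_nuisances <- function(X, Y, W, num_trees = 200L, min_node_size = 5L,
                               seed = 1L) {
  list(m_hat = fit_regression_forest(X, Y, num_trees, min_node_size,
                                     seed = sub_seed(seed, 11L)),
       p_hat = fit_regression_forest(X, W, num_trees, min_node_size,
                                     seed = sub_seed(seed, 12L)))
}

#' Residualize outcome and treatment on the nuisance estimates
#'
#' The partialling-out step: returns the residual pairs
#' \eqn{(Y_i - \hat m(x_i),\; W_i - \hat p(x_i))} on which the causal
#' forest operates, so nuisance estimation error enters the effect
#' estimate only at second order.
#'
#' @param Y outcome vector.
#' @param W 0/1 treatment vector.
#' @param nuisance list with `m_hat`, `p_hat` (see [estimate_nuisances()]).
#' @return list with `y_res`, `w_res`.
#' @export
orthogonalize <- function(Y, W, nuisance) {
  if (length(Y) != length(nuisance$m_hat) || length(W) != length(nuisance$p_hat) ||
      length(Y) != length(W)) {
    stop("Y, W and nuisance predictions must have equal length", call. = FALSE)
  }
  if (!all(is.finite(nuisance$m_hat)) || !all(is.finite(nuisance$p_hat))) {
    stop("nuisance predictions must be finite", call. = FALSE)
  }
  list(y_res = Y - nuisance$m_hat, w_res = W - nuisance$p_hat)
}
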