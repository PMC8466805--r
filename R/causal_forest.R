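#' Fit an honest causal forest
#'
#' The full pipeline for conditional treatment-effect estimation:
#' (1) nuisance regression forests with out-of-bag cross-fitting for the
#' conditional outcome mean and the propensity; (2) residualization of
#' outcome and treatment on them; (3) an ensemble of honest causal trees,
#' each grown on an independent subsample split into a structure
#' (split) half and an estimation half. Predictions aggregate leaf-level
#' residual sums across trees, which is exactly the adaptive-neighborhood
#' weighted estimator: records sharing a leaf with the query point in a
#' tree's estimation half receive weight \eqn{\alpha_i(x)}, and
#' \deqn{\hat\tau(x) = \frac{\sum_i \alpha_i(x) (W_i - \hat p_i)(Y_i - \hat m_i)}
#'                          {\sum_i \alpha_i(x) (W_i - \hat p_i)^2}.}
#'
#' @param X covariate data frame or numeric matrix (typically the one-hot
#'   encoding from [encode_covariates()]).
#' @param Y numeric outcome.
#' @param W 0/1 treatment.
#' @param params a [forest_params()].
#' @param seed master seed: nuisances, subsamples and node-level draws all
#'   derive their streams from it.
#' @param nuisance optional precomputed list with `m_hat`, `p_hat`
#'   (skips the nuisance forests; used to share nuisances across stages).
#' @return object of class `causal_forest` with elements `trees`, `X`,
#'   `residuals`, `W`, `nuisance`, `covariates` (column names), `params`,
#'   `seed`.
#' @export
fit_causal_forest <- function(X, Y, W, params = forest_params(), seed = 1L,
                              nuisance = NULL) {
  X <- as.matrix(as.data.frame(X))
  storage.mode(X) <- "double"
  n <- nrow(X)
  stopifnot(length(Y) == n, length(W) == n, all(W %in% c(0, 1)))
  if (n < 50) stop("causal forest needs at least 50 records", call. = FALSE)
  if (sum(W == 1) < 4 * params$min_leaf || sum(W == 0) < 4 * params$min_leaf) {
    stop("each arm needs at least 4*min_leaf records", call. = FALSE)
  }
  m <- floor(n * params$sample_frac)
  if (m < 4 * params$min_leaf) {
    stop("min_leaf too large for the per-tree subsample size", call. = FALSE)
  }
  if (is.null(nuisance)) {
    nuisance <- estimate_nuisances(X, Y, W, num_trees = params$nuisance_trees,
                                   min_node_size = params$min_leaf, seed = seed)
  }
  residuals <- orthogonalize(Y, W, nuisance)
  trees <- vector("list", params$n_trees)
  for (t in seq_len(params$n_trees)) {
    tree_seed <- sub_seed(seed, 100L + t)
    set.seed(tree_seed)
    sub <- sample.int(n, m, replace = params$replace)
    if (length(unique(W[sub])) < 2) next  # degenerate subsample: skip tree
    trees[[t]] <- grow_causal_tree(X, residuals, W, sub, params,
                                   seed = sub_seed(seed, 10000L + t))
  }
  trees <- trees[!vapply(trees, is.null, logical(1))]
  if (!length(trees)) stop("no tree could be grown", call. = FALSE)
  structure(list(trees = trees, X = X, residuals = residuals, W = W,
                 nuisance = nuisance, covariates = colnames(X),
                 params = params, seed = seed),
            class = "causal_forest")
}

#' @export
print.causal_forest <- function(x, ...) {
  n_splits <- sum(vapply(x$trees, function(tr)
    sum(!vapply(tr$nodes, function(nd) isTRUE(nd$leaf), logical(1))), numeric(1)))
  cat("Honest causal forest:", length(x$trees), "trees on", nrow(x$X),
      "records,", length(x$covariates), "covariates,",
      round(n_splits / length(x$trees), 1), "splits/tree\n")
  invisible(x)
}

#' Forest neighborhood weights at query points
#'
#' The adaptive-neighborhood weights \eqn{\alpha_i(x)}: training record i
#' gets weight proportional to the average, over trees, of
#' \eqn{1\{i \in \text{leaf}(x)\} / |\text{leaf}(x)|} computed on each
#' tree's estimation half, renormalized to sum to one per query point.
#' Trees whose leaf at x has an empty estimation set are skipped; a query
#' point skipped by every tree is an error.
#'
#' @param forest a `causal_forest`.
#' @param newX query covariate rows (defaults to the training matrix).
#' @return numeric matrix (query rows x training records) of weights, each
#'   row summing to 1.
#' @export
forest_weights <- function(forest, newX = NULL) {
  Xq <- prepare_query(forest, newX)
  n <- nrow(forest$X)
  alpha <- matrix(0, nrow(Xq), n)
  contributing <- integer(nrow(Xq))
  for (tree in forest$trees) {
    ids <- tree_leaf_ids(tree, Xq)
    for (lid in unique(ids)) {
      node <- tree$nodes[[lid]]
      if (!node$n_est) next
      rows <- which(ids == lid)
      alpha[rows, node$est_idx] <- alpha[rows, node$est_idx] + 1 / node$n_est
      contributing[rows] <- contributing[rows] + 1L
    }
  }
  if (any(contributing == 0)) {
    stop("a query point fell in empty estimation leaves in every tree", call. = FALSE)
  }
  alpha / rowSums(alpha)
}

prepare_query <- function(forest, newX) {
  if (is.null(newX)) return(forest$X)
  Xq <- as.matrix(as.data.frame(newX))
  missing <- setdiff(forest$covariates, colnames(Xq))
  if (length(missing)) {
    stop("query rows are missing training covariates: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Xq <- Xq[, forest$covariates, drop = FALSE]
  storage.mode(Xq) <- "double"
  Xq
}

#' Conditional treatment effects from a fitted forest
#'
#' Evaluates the forest-weighted residual-on-residual estimator at each
#' query row. Computed by aggregating per-leaf residual sums across trees,
#' which is algebraically identical to forming the explicit
#' \eqn{\alpha_i(x)} weights of [forest_weights()] and applying the
#' weighted local estimator.
#'
#' @param forest a `causal_forest`.
#' @param newX query covariate rows (defaults to training rows, giving the
#'   per-record conditional individual treatment effects, "CITE").
#' @param min_denominator guard below which the weighted treatment-residual
#'   variance is considered degenerate (error).
#' @return numeric vector of effect estimates.
#' @export
predict_cate <- function(forest, newX = NULL, min_denominator = 1e-12) {
  Xq <- prepare_query(forest, newX)
  num <- numeric(nrow(Xq))
  den <- numeric(nrow(Xq))
  for (tree in forest$trees) {
    ids <- tree_leaf_ids(tree, Xq)
    s1 <- vapply(tree$nodes, function(nd) if (isTRUE(nd$leaf)) nd$s1 else 0, numeric(1))
    s2 <- vapply(tree$nodes, function(nd) if (isTRUE(nd$leaf)) nd$s2 else 0, numeric(1))
    num <- num + s1[ids]
    den <- den + s2[ids]
  }
  if (any(den <= min_denominator)) {
    stop("degenerate weighted treatment-residual variance at a query point", call. = FALSE)
  }
  num / den
}

#' Split-based covariate importance
#'
#' Scores each covariate by the depth-weighted frequency with which the
#' forest splits on it: a split at depth d (root = 1) contributes
#' \eqn{2^{-d}}, splits deeper than 4 levels are not counted, and scores
#' are normalized to sum to one. A forest with no splits returns an
#' all-zero table with a warning.
#'
#' @param forest a `causal_forest`.
#' @param max_count_depth deepest split level counted (default 4).
#' @return data frame with `covariate`, `importance`, `rank`, sorted by
#'   decreasing importance.
#' @export
variable_importance <- function(forest, max_count_depth = 4L) {
  score <- stats::setNames(numeric(length(forest$covariates)), forest$covariates)
  for (tree in forest$trees) {
    for (node in tree$nodes) {
      if (!isTRUE(node$leaf) && node$depth <= max_count_depth) {
        score[node$var] <- score[node$var] + 2^(-node$depth)
      }
    }
  }
  total <- sum(score)
  if (total == 0) {
    warning("forest contains no splits: importance is all zero")
  } else {
    score <- score / total
  }
  out <- data.frame(covariate = names(score), importance = unname(score))
  out <- out[order(-out$importance, out$covariate), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Screen covariates by above-average importance
#'
#' Keeps the covariates whose importance strictly exceeds the mean
#' importance (1/p after normalization). If none does (all importances
#' equal), all covariates are kept.
#'
#' @param importance_table output of [variable_importance()].
#' @return character vector of selected covariate names.
#' @export
select_covariates <- function(importance_table) {
  stopifnot(nrow(importance_table) > 0)
  keep <- importance_table$importance > mean(importance_table$importance)
  if (!any(keep)) return(importance_table$covariate)
  importance_table$covariate[keep]
}

#' Grid-search tuning of forest leaf size and mtry
#'
#' Small grid search over `(min_leaf, mtry)` scored by the out-of-sample
#' R-learner loss \eqn{\mathrm{mean}[(Y_i - \hat m_i - \hat\tau(x_i)(W_i -
#' \hat p_i))^2]} of a pilot forest, the tuning device used before the
#' full-size fits.
#'
#' @param X,Y,W as in [fit_causal_forest()].
#' @param params base [forest_params()]; the tuned fields are overridden.
#' @param min_leaf_grid,mtry_grid candidate values (`NA` in `mtry_grid`
#'   means the default `ceiling(sqrt(p))`).
#' @param pilot_trees trees per pilot forest.
#' @param seed RNG seed.
#' @param nuisance optional precomputed nuisances.
#' @return list with `min_leaf`, `mtry`, `losses` (the scored grid).
#' @export
tune_causal_forest <- function(X, Y, W, params = forest_params(),
                               min_leaf_grid = c(5L, 10L),
                               mtry_grid = c(NA, 0L),
                               pilot_trees = 50L, seed = 1L, nuisance = NULL) {
  Xm <- as.matrix(as.data.frame(X))
  p <- ncol(Xm)
  # NA = package default (sqrt(p)+20 capped at p); 0 = the classic sqrt(p)
  mtry_grid[is.na(mtry_grid)] <- min(ceiling(sqrt(p)) + 20L, p)
  mtry_grid[mtry_grid == 0] <- ceiling(sqrt(p))
  mtry_grid <- unique(pmin(as.integer(mtry_grid), p))
  if (is.null(nuisance)) {
    nuisance <- estimate_nuisances(Xm, Y, W, num_trees = params$nuisance_trees,
                                   min_node_size = params$min_leaf, seed = seed)
  }
  grid <- expand.grid(min_leaf = unique(min_leaf_grid), mtry = mtry_grid)
  grid$loss <- NA_real_
  res <- orthogonalize(Y, W, nuisance)
  for (g in seq_len(nrow(grid))) {
    pg <- params
    pg$min_leaf <- grid$min_leaf[g]
    pg$mtry <- grid$mtry[g]
    pg$n_trees <- as.integer(pilot_trees)
    fit <- tryCatch(
      fit_causal_forest(Xm, Y, W, pg, seed = sub_seed(seed, 500L + g),
                        nuisance = nuisance),
      error = function(e) NULL)
    if (is.null(fit)) next
    tau <- predict_cate(fit)
    grid$loss[g] <- mean((res$y_res - tau * res$w_res)^2)
  }
  if (all(is.na(grid$loss))) stop("no tuning candidate could be fitted", call. = FALSE)
  best <- which.min(grid$loss)
  list(min_leaf = grid$min_leaf[best], mtry = grid$mtry[best], losses = grid)
}

#' Two-stage causal forest with importance screening
#'
#' Stage 1 fits a causal forest on all encoded covariates and ranks them
#' by split importance; covariates above the mean importance are retained;
#' stage 2 refits the forest on the screened covariates and delivers the
#' final conditional-effect predictions. Nuisances are fitted once on the
#' full covariate set and shared. Optional pilot tuning of `(min_leaf,
#' mtry)` precedes each stage.
#'
#' @param data analysis table (covariates + `treatment` + `outcome`).
#' @param stage1_params,stage2_params [forest_params()] for the two stages.
#' @param seed master seed.
#' @param tune run [tune_causal_forest()] before each stage.
#' @return list with `stage1` (forest), `importance`, `selected`
#'   (covariate names), `stage2` (final forest), `cite` (per-record
#'   conditional individual treatment effects from the final forest).
#' @export
two_stage_fit <- function(data, stage1_params = forest_params(n_trees = 200L),
                          stage2_params = forest_params(n_trees = 500L),
                          seed = 1L, tune = FALSE) {
  validate_dataset(data)
  X <- encode_covariates(data[intersect(covariate_columns(), names(data))])
  Y <- data$outcome
  W <- data$treatment
  nuisance <- estimate_nuisances(X, Y, W, num_trees = stage1_params$nuisance_trees,
                                 min_node_size = stage1_params$min_leaf, seed = seed)
  if (tune) {
    tuned <- tune_causal_forest(X, Y, W, stage1_params, seed = seed, nuisance = nuisance)
    stage1_params$min_leaf <- tuned$min_leaf
    stage1_params$mtry <- tuned$mtry
  }
  stage1 <- fit_causal_forest(X, Y, W, stage1_params, seed = sub_seed(seed, 21L),
                              nuisance = nuisance)
  importance <- variable_importance(stage1)
  selected <- select_covariates(importance)
  X2 <- X[, selected, drop = FALSE]
  if (tune) {
    tuned2 <- tune_causal_forest(X2, Y, W, stage2_params, seed = sub_seed(seed, 22L),
                                 nuisance = nuisance)
    stage2_params$min_leaf <- tuned2$min_leaf
    stage2_params$mtry <- tuned2$mtry
  }
  stage2 <- fit_causal_forest(X2, Y, W, stage2_params, seed = sub_seed(seed, 23L),
                              nuisance = nuisance)
  list(stage1 = stage1, importance = importance, selected = selected,
       stage2 = stage2, cite = predict_cate(stage2))
}
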