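# fixture builders shared across test files

# residual pairs with deterministic values for oracle checks
toy_residuals <- function(y_res, w_res) list(y_res = y_res, w_res = w_res)

# leaf node with the sums predict_cate aggregates, computed independently here
manual_leaf <- function(est_idx, residuals, depth = 1L) {
  wr <- residuals$w_res[est_idx]
  yr <- residuals$y_res[est_idx]
  n <- length(est_idx)
  list(leaf = TRUE, depth = depth, est_idx = est_idx,
       tau = sum(wr * yr) / sum(wr^2), n_est = n,
       s1 = sum(wr * yr) / n, s2 = sum(wr^2) / n)
}

manual_split <- function(var, threshold, left, right, depth = 1L) {
  list(leaf = FALSE, depth = depth, var = var, threshold = threshold,
       left = left, right = right)
}

manual_tree <- function(nodes, root = 1L) {
  structure(list(nodes = nodes, root = root, split_idx = integer(),
                 est_idx = integer()), class = "causal_tree")
}

manual_forest <- function(trees, X, residuals, W) {
  X <- as.matrix(X)
  structure(list(trees = trees, X = X, residuals = residuals, W = W,
                 nuisance = NULL, covariates = colnames(X),
                 params = forest_params(n_trees = length(trees)), seed = 0L),
            class = "causal_forest")
}

# small covariate table with every column the package expects
toy_covariates <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    child_gender = rbinom(n, 1, 0.5),
    child_age = sample(0:5, n, replace = TRUE),
    mother_age = runif(n, 20, 45),
    mother_education = sample(1:7, n, replace = TRUE),
    log_income_pc = rnorm(n, 9, 1),
    living_area = rbinom(n, 1, 0.4),
    region = sample(1:3, n, replace = TRUE),
    wealth_quintile = sample(1:5, n, replace = TRUE)
  )
}

# independent brute-force evaluation of the local residual-on-residual ratio
brute_force_tau <- function(residuals, idx) {
  num <- 0; den <- 0
  for (i in idx) {
    num <- num + residuals$w_res[i] * residuals$y_res[i]
    den <- den + residuals$w_res[i]^2
  }
  num / den
}
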