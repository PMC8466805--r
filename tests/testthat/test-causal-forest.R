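test_that("regression forest nuisances behave on constant, null and signal targets", {
  set.seed(31)
  X <- data.frame(a = rnorm(2000), b = rnorm(2000))
  expect_warning(p <- fit_regression_forest(X, rep(3, 2000), seed = 1), "constant")
  expect_identical(p, rep(3, 2000))
  # pure-noise target: no positive out-of-bag signal at the default leaf
  # size, and R^2 pinned near zero once leaves are large enough to average
  # away the overfitting variance
  y_noise <- rnorm(2000)
  pred <- fit_regression_forest(X, y_noise, num_trees = 100, seed = 2)
  r2 <- 1 - mean((y_noise - pred)^2) / var(y_noise)
  expect_lt(r2, 0.05)
  pred_s <- fit_regression_forest(X, y_noise, num_trees = 100,
                                  min_node_size = 200, seed = 2)
  r2_s <- 1 - mean((y_noise - pred_s)^2) / var(y_noise)
  expect_lt(abs(r2_s), 0.05)
  # recoverable step signal: out-of-bag RMSE well under the target sd
  y_step <- ifelse(X$a > 0, 2, -2) + rnorm(2000, 0, 0.1)
  pred2 <- fit_regression_forest(X, y_step, num_trees = 100, seed = 3)
  expect_lt(sqrt(mean((y_step - pred2)^2)), 0.2 * sd(y_step))
  # binary targets are clipped away from 0 and 1
  w <- rbinom(2000, 1, plogis(X$a))
  ph <- fit_regression_forest(X, w, num_trees = 100, seed = 4)
  expect_true(all(ph >= 0.01 & ph <= 0.99))
})

test_that("orthogonalization returns exact residual pairs and recovers a constant effect", {
  y <- c(1, 2, 3); w <- c(1, 0, 1)
  # a perfect outcome model leaves zero outcome residuals
  r <- orthogonalize(y, w, list(m_hat = y, p_hat = rep(0.5, 3)))
  expect_identical(r$y_res, c(0, 0, 0))
  expect_identical(r$w_res, c(0.5, -0.5, 0.5))
  expect_error(orthogonalize(y, w, list(m_hat = 1:2, p_hat = rep(0.5, 3))), "length")
  # randomized treatment, constant effect: the residual-on-residual slope
  # (1-D least squares through the origin) recovers the effect
  set.seed(32)
  n <- 4000
  x <- rnorm(n)
  w2 <- rbinom(n, 1, 0.5)
  y2 <- x + 0.7 * w2 + rnorm(n)
  nuis <- list(m_hat = x + 0.35, p_hat = rep(0.5, n))
  r2 <- orthogonalize(y2, w2, nuis)
  expect_lt(abs(local_tau(r2, 1:n) - 0.7), 0.1)
})

test_that("forest weights on hand-built trees match direct arithmetic", {
  res <- toy_residuals(c(1, 2, 3, 4, 5), c(0.5, -0.5, 0.5, -0.5, 0.5))
  X <- matrix(0, 5, 1, dimnames = list(NULL, "x"))
  # one tree, single leaf with estimation set {2, 5}
  t1 <- manual_tree(list(manual_leaf(c(2L, 5L), res)))
  f1 <- manual_forest(list(t1), X, res, c(1, 0, 1, 0, 1))
  a1 <- forest_weights(f1)
  expect_equal(a1[1, ], c(0, 0.5, 0, 0, 0.5))
  # two trees with leaf sets {1,2} and {2,3}: weights 0.25, 0.5, 0.25
  t2 <- manual_tree(list(manual_leaf(c(1L, 2L), res)))
  t3 <- manual_tree(list(manual_leaf(c(2L, 3L), res)))
  f2 <- manual_forest(list(t2, t3), X, res, c(1, 0, 1, 0, 1))
  expect_equal(forest_weights(f2)[1, ], c(0.25, 0.5, 0.25, 0, 0))
  expect_equal(unname(rowSums(forest_weights(f2))), rep(1, 5))
})

test_that("forest prediction equals the hand-computed weighted estimator", {
  # <=10-record instance, hand-built 2-tree forest with a real split
  set.seed(33)
  res <- toy_residuals(rnorm(8), c(0.4, -0.6, 0.5, -0.5, 0.3, -0.4, 0.6, -0.3))
  W <- c(1, 0, 1, 0, 1, 0, 1, 0)
  X <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 8, 1, dimnames = list(NULL, "x"))
  # tree A splits x <= 4.5 with estimation leaves {1,2}/{5,6};
  # tree B is a single leaf on {3,4,7,8}
  treeA <- manual_tree(list(
    manual_split(1L, 4.5, 2L, 3L),
    manual_leaf(c(1L, 2L), res, depth = 2L),
    manual_leaf(c(5L, 6L), res, depth = 2L)))
  treeB <- manual_tree(list(manual_leaf(c(3L, 4L, 7L, 8L), res)))
  forest <- manual_forest(list(treeA, treeB), X, res, W)
  tau_hat <- predict_cate(forest)
  # independent route: explicit alpha weights into the weighted ratio
  alpha <- forest_weights(forest)
  manual <- vapply(1:8, function(i) {
    sum(alpha[i, ] * res$w_res * res$y_res) / sum(alpha[i, ] * res$w_res^2)
  }, numeric(1))
  expect_equal(tau_hat, manual, tolerance = 1e-12)
  # uniform weights over a set reduce to the unweighted local estimator
  expect_equal(predict_cate(manual_forest(list(treeB), X, res, W))[1],
               local_tau(res, c(3L, 4L, 7L, 8L)), tolerance = 1e-12)
})

test_that("a fitted forest agrees with its explicit weight representation", {
  set.seed(34)
  cfg <- sim_config(n_total = 150, seed = 34, effect = effect_spec(tau0 = 0.3))
  d <- simulate_sample(cfg)$data
  X <- encode_covariates(d[hetfx:::covariate_columns()])
  cf <- fit_causal_forest(X, d$outcome, d$treatment,
                          forest_params(n_trees = 12, min_leaf = 4), seed = 5)
  tau_fast <- predict_cate(cf)
  alpha <- forest_weights(cf)
  r <- cf$residuals
  tau_slow <- vapply(seq_len(nrow(X)), function(i) {
    sum(alpha[i, ] * r$w_res * r$y_res) / sum(alpha[i, ] * r$w_res^2)
  }, numeric(1))
  expect_equal(tau_fast, tau_slow, tolerance = 1e-10)
  expect_equal(unname(rowSums(alpha)), rep(1, nrow(X)), tolerance = 1e-12)
})

test_that("forests are deterministic and a 1-tree forest equals its tree", {
  d <- simulate_sample(sim_config(n_total = 200, seed = 36))$data
  X <- encode_covariates(d[hetfx:::covariate_columns()])
  p <- forest_params(n_trees = 5, min_leaf = 4)
  f1 <- fit_causal_forest(X, d$outcome, d$treatment, p, seed = 9)
  f2 <- fit_causal_forest(X, d$outcome, d$treatment, p, seed = 9)
  expect_identical(f1$trees, f2$trees)
  expect_identical(predict_cate(f1), predict_cate(f2))
  # replicate the forest's own subsample draw: tree 1 must match exactly
  p1 <- forest_params(n_trees = 1, min_leaf = 4)
  f3 <- fit_causal_forest(X, d$outcome, d$treatment, p1, seed = 9)
  set.seed(hetfx:::sub_seed(9, 101L))
  sub <- sample.int(nrow(X), floor(nrow(X) * 0.5))
  tree <- grow_causal_tree(as.matrix(X), f3$residuals, d$treatment, sub, p1,
                           seed = hetfx:::sub_seed(9, 10001L))
  expect_identical(f3$trees[[1]], tree)
})

test_that("variable importance is a normalized depth-weighted split count", {
  res <- toy_residuals(rnorm(8), rep(c(0.5, -0.5), 4))
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("a", "b")))
  # forest that only ever splits on covariate "a"
  tr <- manual_tree(list(
    manual_split(1L, 0, 2L, 3L),
    manual_leaf(c(1L, 2L), res, depth = 2L),
    manual_leaf(c(3L, 4L), res, depth = 2L)))
  f <- manual_forest(list(tr), X, res, rep(c(1, 0), 4))
  imp <- variable_importance(f)
  expect_equal(imp$importance[imp$covariate == "a"], 1)
  expect_equal(imp$importance[imp$covariate == "b"], 0)
  expect_equal(sum(imp$importance), 1)
  expect_identical(imp$rank, 1:2)
  # a split-free forest warns and returns zeros
  f0 <- manual_forest(list(manual_tree(list(manual_leaf(1:8, res)))), X, res,
                      rep(c(1, 0), 4))
  expect_warning(imp0 <- variable_importance(f0), "no splits")
  expect_equal(sum(imp0$importance), 0)
})

test_that("above-mean screening keeps the dominant covariates", {
  # importance profile shaped like a screening-stage ranking
  tab <- data.frame(
    covariate = paste0("v", 1:10),
    importance = c(0.368, 0.158, 0.155, 0.060, 0.036, 0.033, 0.031, 0.025,
                   0.022, 0.021) / 0.909,
    rank = 1:10)
  expect_identical(select_covariates(tab), c("v1", "v2", "v3"))
  # all-equal importances: the guard keeps everything
  flat <- data.frame(covariate = c("a", "b"), importance = c(0.5, 0.5), rank = 1:2)
  expect_identical(select_covariates(flat), c("a", "b"))
  one <- data.frame(covariate = c("a", "b"), importance = c(1, 0), rank = 1:2)
  expect_identical(select_covariates(one), "a")
})

test_that("constant effects are recovered and CITE spread shrinks with n", {
  # leaf size grows with n (here n/100), the honest-forest regularity under
  # which per-record predictions concentrate around a constant effect
  sds <- numeric(2)
  for (i in 1:2) {
    n <- c(1000, 4000)[i]
    cfg <- sim_config(n_total = n, seed = 37, selection_coefs = c(intercept = 0),
                      effect = effect_spec(tau0 = 0.5))
    d <- simulate_sample(cfg)$data
    X <- encode_covariates(d[hetfx:::covariate_columns()])
    cf <- fit_causal_forest(X, d$outcome, d$treatment,
                            forest_params(n_trees = 100, min_leaf = ceiling(n / 100)),
                            seed = 6)
    cite <- predict_cate(cf)
    expect_lt(abs(mean(cite) - 0.5), 0.1)
    sds[i] <- sd(cite)
  }
  expect_lt(sds[2], sds[1])
})

test_that("two-stage screening runs end-to-end, deterministically", {
  d <- simulate_sample(sim_config(n_total = 400, seed = 38))$data
  ts1 <- two_stage_fit(d, stage1_params = forest_params(n_trees = 10, min_leaf = 4),
                       stage2_params = forest_params(n_trees = 20, min_leaf = 4),
                       seed = 3)
  expect_s3_class(ts1$stage1, "causal_forest")
  expect_s3_class(ts1$stage2, "causal_forest")
  expect_true(all(ts1$selected %in% ts1$importance$covariate))
  expect_identical(sort(ts1$stage2$covariates), sort(ts1$selected))
  expect_length(ts1$cite, nrow(d))
  ts2 <- two_stage_fit(d, stage1_params = forest_params(n_trees = 10, min_leaf = 4),
                       stage2_params = forest_params(n_trees = 20, min_leaf = 4),
                       seed = 3)
  expect_identical(ts1$selected, ts2$selected)
  expect_identical(ts1$cite, ts2$cite)
})

test_that("impossible forest configurations fail before training", {
  d <- simulate_sample(sim_config(n_total = 100, seed = 39))$data
  X <- encode_covariates(d[hetfx:::covariate_columns()])
  expect_error(fit_causal_forest(X[1:30, ], d$outcome[1:30], d$treatment[1:30],
                                 forest_params()), "at least 50")
  expect_error(fit_causal_forest(X, d$outcome, d$treatment,
                                 forest_params(min_leaf = 40)), "min_leaf")
})
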