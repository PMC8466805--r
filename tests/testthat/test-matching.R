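# toy cases pass an explicit all-inclusive support so that tiny score sets
# are not trimmed by the degenerate overlap interval of one-treated toys
full_support <- function(n) list(interval = c(0, 1), in_support = rep(TRUE, n),
                                 n_dropped = 0L)

test_that("nearest-neighbor matching picks closest controls with index tie-break", {
  scores <- c(0.50, 0.10, 0.49, 0.90)
  w <- c(1, 0, 0, 0)
  m <- nn_match(scores, w, k = 1, support = full_support(4))
  expect_equal(m$pairs$control, 3L)
  expect_equal(m$pairs$weight, 1)
  # 1:2: both nearest controls at weight 1/2
  scores2 <- c(0.50, 0.49, 0.51, 0.90)
  m2 <- nn_match(scores2, c(1, 0, 0, 0), k = 2, support = full_support(4))
  expect_setequal(m2$pairs$control, c(2L, 3L))
  expect_equal(m2$pairs$weight, c(0.5, 0.5))
  # exact ties resolved toward the lowest record index
  scores3 <- c(0.50, 0.49, 0.49)
  m3 <- nn_match(scores3, c(1, 0, 0), k = 1, support = full_support(3))
  expect_equal(m3$pairs$control, 2L)
  expect_error(nn_match(scores3, c(1, 0, 0), k = 5, support = full_support(3)),
               "exceeds")
})

test_that("kernel weights equal the hand-evaluated Epanechnikov kernel", {
  scores <- c(0.50, 0.48, 0.53, 0.56)
  w <- c(1, 0, 0, 0)
  m <- kernel_match_weights(scores, w, bandwidth = 0.06, support = full_support(4))
  epa <- function(u) 0.75 * (1 - u^2) * (abs(u) < 1)
  kw <- epa(c(0.02, -0.03, -0.06) / 0.06)
  expect_equal(m$pairs$weight, kw[kw > 0] / sum(kw), tolerance = 1e-12)
  # single control takes all the weight whatever its distance (within mass)
  m1 <- kernel_match_weights(c(0.50, 0.52), c(1, 0), bandwidth = 0.06,
                             support = full_support(2))
  expect_equal(m1$pairs$weight, 1)
  # equidistant controls split the weight evenly
  m2 <- kernel_match_weights(c(0.50, 0.47, 0.53), c(1, 0, 0), bandwidth = 0.06,
                             support = full_support(3))
  expect_equal(m2$pairs$weight, c(0.5, 0.5))
  expect_error(kernel_match_weights(scores, w, bandwidth = 0), "bandwidth")
})

test_that("treated units with zero kernel mass are dropped with a warning", {
  scores <- c(0.50, 0.10, 0.52)
  w <- c(1, 1, 0)
  expect_warning(
    m <- kernel_match_weights(scores, w, bandwidth = 0.03, support = full_support(3)),
    "zero kernel mass")
  expect_equal(m$n_dropped, 1L)
  expect_equal(m$n_treated_matched, 1L)
})

test_that("matching weights always sum to one per treated unit", {
  set.seed(11)
  scores <- runif(300, 0.2, 0.8)
  w <- rbinom(300, 1, 0.6)
  for (m in list(nn_match(scores, w, k = 4),
                 kernel_match_weights(scores, w, bandwidth = 0.06))) {
    sums <- as.numeric(tapply(m$pairs$weight, m$pairs$treated, sum))
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-12)
    expect_true(all(m$pairs$weight >= 0))
    # matched controls all lie inside common support
    expect_true(all(m$support$in_support[m$pairs$control]))
  }
})

test_that("matched-sample ATT reduces to hand arithmetic on toys", {
  # two treated (Y = 3, 5) matched 1:1 to controls (Y = 1, 2)
  scores <- c(0.4, 0.6, 0.41, 0.59)
  w <- c(1, 1, 0, 0)
  y <- c(3, 5, 1, 2)
  m <- nn_match(scores, w, k = 1, support = full_support(4))
  att <- estimate_att(m, y, w)
  expect_equal(att$value, 2.5)
  expect_equal(att$estimand, "ATT")
  expect_equal(att$n_treated, 2)
  # identical outcomes for every matched control: ATT = 0
  expect_equal(estimate_att(m, c(3, 5, 3, 5), w)$value, 0)
})

test_that("exact score duplicates make 1:1 matching a paired mean difference", {
  # every treated unit has one control with an identical score: matching
  # must pair them (distance zero) and the ATT collapses to the paired
  # mean difference
  n <- 40
  set.seed(12)
  s <- runif(n, 0.2, 0.8)
  scores <- c(s, s)
  w <- rep(c(1, 0), each = n)
  y <- c(rnorm(n, 1), rnorm(n, 0))
  m <- nn_match(scores, w, k = 1)
  expect_equal(m$pairs$control, n + seq_len(n))
  expect_equal(estimate_att(m, y, w)$value, mean(y[1:n] - y[(n + 1):(2 * n)]),
               tolerance = 1e-12)
})

test_that("kernel matching converges to 1:1 nearest neighbor as bandwidth shrinks", {
  # controls on a coarse grid, treated offset by 0.001: with bandwidth 0.002
  # only each treated unit's unique nearest control keeps positive mass
  controls <- (10:60) / 101
  treated <- controls[seq(1, 51, 2)] + 0.001
  scores <- c(treated, controls)
  w <- rep(c(1, 0), c(length(treated), length(controls)))
  set.seed(13)
  y <- rnorm(length(scores))
  sup <- full_support(length(scores))
  att_nn <- estimate_att(nn_match(scores, w, k = 1, support = sup), y, w)$value
  att_kernel <- estimate_att(
    kernel_match_weights(scores, w, bandwidth = 0.002, support = sup), y, w)$value
  expect_equal(att_kernel, att_nn, tolerance = 1e-12)
})

test_that("bootstrap SE is zero for a flat noiseless outcome surface", {
  cfg <- sim_config(n_total = 300, seed = 14, noise_sd = 0,
                    effect = effect_spec(tau0 = 0.4),
                    outcome_coefs = c(intercept = 1))
  d <- simulate_sample(cfg)$data
  bs <- bootstrap_se(d, B = 20, seed = 2)
  expect_equal(bs$se, 0, tolerance = 1e-12)
  expect_equal(bs$n_failed, 0)
  expect_error(bootstrap_se(d, B = 1), "B must be")
})

test_that("bootstrap SE shrinks roughly as one over root n", {
  ses <- vapply(c(500, 2000), function(n) {
    d <- simulate_sample(sim_config(n_total = n, seed = 15))$data
    bootstrap_se(d, B = 60, seed = 3)$se
  }, numeric(1))
  ratio <- ses[1] / ses[2]  # expect ~sqrt(4) = 2
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})

test_that("bootstrap SE is stable in the number of resamples", {
  d <- simulate_sample(sim_config(n_total = 600, seed = 16))$data
  se200 <- bootstrap_se(d, B = 200, seed = 4)$se
  se400 <- bootstrap_se(d, B = 400, seed = 5)$se
  expect_lt(abs(se200 - se400) / se400, 0.15)
})

test_that("matching improves covariate balance on confounded data", {
  sim <- simulate_sample(sim_config(n_total = 2000, seed = 17))
  d <- sim$data
  fit <- psm_att(d, method = "kernel")
  bal <- balance_check(d, d$treatment, fit$match)
  # the strongest confounders must improve; the table must shrink on average
  for (v in c("log_income_pc", "living_area", "child_age")) {
    row <- bal[bal$covariate == v, ]
    expect_lt(abs(row$smd_after), abs(row$smd_before))
  }
  expect_lt(mean(abs(bal$smd_after)), mean(abs(bal$smd_before)))
})

test_that("balance is already near zero under randomized assignment", {
  cfg <- sim_config(n_total = 5000, seed = 18, selection_coefs = c(intercept = 0.5))
  d <- simulate_sample(cfg)$data
  m <- nn_match(fit_propensity_logit(d, d$treatment)$fitted, d$treatment, k = 1)
  bal <- balance_check(d, d$treatment, m)
  expect_true(all(abs(bal$smd_before) < 0.08))
})

test_that("perfectly duplicated matched pairs balance exactly", {
  n <- 30
  cov <- toy_covariates(n, seed = 19)
  dup <- rbind(cov, cov)  # each treated record has an identical control twin
  w <- rep(c(1, 0), each = n)
  set.seed(19)
  s <- runif(n, 0.2, 0.8)
  m <- nn_match(c(s, s), w, k = 1)
  bal <- balance_check(dup, w, m, columns = c("child_age", "log_income_pc"))
  expect_equal(bal$smd_after, rep(0, 2), tolerance = 1e-10)
})
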