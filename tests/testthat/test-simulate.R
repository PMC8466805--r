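test_that("generated cohorts satisfy record invariants and are reproducible", {
  cfg <- sim_config(n_total = 5552, seed = 1)
  sim <- simulate_sample(cfg)
  d <- sim$data
  expect_equal(nrow(d), 5552)
  expect_false(anyNA(d))
  expect_true(all(d$treatment %in% c(0, 1)))
  expect_true(all(d$child_age[d$cohort == "preschool"] %in% 0:5))
  expect_true(all(d$child_age[d$cohort == "school_age"] %in% 6:16))
  expect_true(all(d$mother_education %in% 1:7))
  expect_true(all(d$wealth_quintile %in% 1:5))
  expect_true(all(sim$truth$p_select > 0 & sim$truth$p_select < 1))
  # consistency identity holds bit-exactly
  expect_identical(d$outcome,
                   ifelse(d$treatment == 1, sim$truth$y1, sim$truth$y0))
  expect_identical(sim$truth$tau_true, sim$truth$y1 - sim$truth$y0)
  # same config, same seed: byte-identical draw
  sim2 <- simulate_sample(sim_config(n_total = 5552, seed = 1))
  expect_identical(sim, sim2)
})

test_that("covariate marginals match the configured distributions", {
  # preschool-only cohort: mother's age should average child age + gap mean
  cfg <- sim_config(n_total = 50000, cohort_split = 1, seed = 2)
  cov <- generate_covariates(cfg)
  expect_lt(abs(mean(cov$mother_age) - (2.5 + 27)), 0.1)
  expect_lt(abs(mean(cov$living_area) - 0.35), 0.01)
  # configuration errors are rejected up front
  expect_error(sim_config(covariate_params = list(income_sd = -1)), "standard deviations")
  expect_error(sim_config(covariate_params = list(education_probs = c(1, 1))), "education_probs")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(covariate_params = list(nonsense = 1)), "unknown")
})

test_that("treatment assignment follows the selection logit", {
  cov <- toy_covariates(200)
  # all-zero coefficients: every selection probability is exactly 1/2
  z <- assign_treatment(cov, c(intercept = 0, child_age = 0), seed = 1)
  expect_true(all(z$p_select == 0.5))
  # intercept-only at the logit of the emulated enrollment share
  share <- assign_treatment(cov, c(intercept = log(0.857 / 0.143)), seed = 1)
  expect_equal(unique(share$p_select), 0.857, tolerance = 1e-3)
  # saturated logit: nobody enrolls
  none <- assign_treatment(cov, c(intercept = -50), seed = 1)
  expect_true(all(none$treatment == 0))
  expect_error(assign_treatment(cov, c(intercept = 0, no_such = 1)), "absent")
  expect_error(assign_treatment(cov, c(0, 1)), "named")
})

test_that("default selection design reproduces the emulated enrollment share", {
  cfg <- sim_config(n_total = 50000, seed = 3)
  cov <- generate_covariates(cfg)
  z <- assign_treatment(cov, cfg$selection_coefs, seed = 4)
  expect_lt(abs(mean(z$treatment) - 0.857), 0.01)
})

test_that("outcomes realize the configured effect function exactly", {
  cov <- toy_covariates(100)
  w <- rbinom(100, 1, 0.5)
  # noiseless constant effect: every y1 - y0 is exactly the effect
  sim <- simulate_outcomes(cov, w, effect_spec(tau0 = 0.5), noise_sd = 0, seed = 1)
  expect_equal(sim$truth$y1 - sim$truth$y0, rep(0.5, 100), tolerance = 1e-12)
  # rural increment applies only to rural records
  spec <- effect_spec(tau0 = 0.1, rural = 0.2)
  sim2 <- simulate_outcomes(cov, w, spec, noise_sd = 0.3, seed = 2)
  expect_equal(sim2$truth$tau_true,
               ifelse(cov$living_area == 0, 0.3, 0.1), tolerance = 1e-12)
  # true_cate agrees with the generated truth element-wise
  spec3 <- effect_spec(tau0 = -0.2, western = 0.15, mother_age_slope = 0.01)
  sim3 <- simulate_outcomes(cov, w, spec3, noise_sd = 1, seed = 3)
  expect_equal(true_cate(cov, spec3), sim3$truth$tau_true, tolerance = 1e-12)
  expect_error(effect_spec(tau0 = 0, not_a_modifier = 1), "unknown effect modifier")
  expect_error(simulate_outcomes(cov, w, spec, noise_sd = -1), "noise_sd")
})

test_that("randomized assignment makes the naive difference unbiased for the mean effect", {
  cfg <- sim_config(n_total = 5000, seed = 5, noise_sd = 1,
                    selection_coefs = c(intercept = 0),
                    effect = effect_spec(tau0 = 0.3, rural = 0.1))
  sim <- simulate_sample(cfg)
  d <- sim$data
  naive <- mean(d$outcome[d$treatment == 1]) - mean(d$outcome[d$treatment == 0])
  expect_lt(abs(naive - mean(sim$truth$tau_true)), 0.06)
})

test_that("confounded selection biases the naive difference below the true effect", {
  cfg <- sim_config(n_total = 20000, seed = 6, effect = effect_spec(tau0 = 0.5))
  sim <- simulate_sample(cfg)
  d <- sim$data
  naive <- mean(d$outcome[d$treatment == 1]) - mean(d$outcome[d$treatment == 0])
  # enrolled children are poorer, so the naive contrast understates the
  # effect by more than Monte-Carlo noise (~0.015 at this n)
  expect_lt(naive, 0.5 - 0.045)
})

test_that("simulated cohorts round-trip through CSV and YAML config files", {
  tmp <- withr::local_tempdir()
  sim <- simulate_sample(sim_config(n_total = 120, seed = 9))
  csv <- file.path(tmp, "cohort.csv")
  write_simulation(sim, csv, truth_path = file.path(tmp, "truth.csv"), seed = 9)
  back <- read_dataset(csv)
  expect_equal(back$outcome, sim$data$outcome)
  expect_true(file.exists(paste0(csv, ".meta.json")))
  yml <- file.path(tmp, "cfg.yaml")
  writeLines(c("n_total: 80", "seed: 4", "noise_sd: 0.5",
               "effect:", "  tau0: 0.2", "  rural: 0.1"), yml)
  cfg <- read_sim_config(yml)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$n_total, 80L)
  expect_equal(cfg$effect$modifiers$rural, 0.1)
  expect_equal(nrow(simulate_sample(cfg)$data), 80)
})
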