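# study-level orchestration: simulate -> describe -> match -> forest -> report

# per-outcome generator settings: baseline surface, noise, and effect
# function chosen to emulate each outcome's scale and the direction of the
# published estimates (z-scores ~N(0,1)-scaled with small positive effects;
# BMI on its natural scale with a negative average effect concentrated in
# rural/less-educated households)
outcome_profiles <- function() {
  list(
    whz = list(cohort = "preschool",
               outcome_coefs = c(intercept = -3.0, mother_education = 0.05,
                                 log_income_pc = 0.30, child_age = 0.02),
               noise_sd = 0.75,
               effect = effect_spec(tau0 = 0.13, rural = 0.05,
                                    low_mother_education = 0.08,
                                    mother_age_slope = 0.008)),
    waz = list(cohort = "preschool",
               outcome_coefs = c(intercept = -2.75, mother_education = 0.05,
                                 log_income_pc = 0.30, child_age = 0.02),
               noise_sd = 0.95,
               effect = effect_spec(tau0 = 0.10, low_wealth = 0.05)),
    haz = list(cohort = "preschool",
               outcome_coefs = c(intercept = -2.75, mother_education = 0.05,
                                 log_income_pc = 0.30, child_age = 0.02),
               noise_sd = 0.95,
               effect = effect_spec(tau0 = 0.13)),
    bmi = list(cohort = "school_age",
               outcome_coefs = c(intercept = 9.0, mother_education = 0.05,
                                 log_income_pc = 0.05, child_age = 0.80),
               noise_sd = 4.5,
               effect = effect_spec(tau0 = -1.0, urban = 0.9,
                                    high_mother_education = 0.3))
  )
}

#' Simulate the full two-cohort study
#'
#' Generates one synthetic cohort (covariates and confounded enrollment
#' shared) and realizes the cohort-appropriate outcomes: WHZ, WAZ and HAZ
#' for preschool records and BMI for school-age records, each from its own
#' outcome profile and RNG stream.
#'
#' @param config a [sim_config()]; its `effect`, `outcome_coefs` and
#'   `noise_sd` fields are ignored in favour of the per-outcome profiles.
#' @return list with `preschool` (data frame: covariates, `treatment`,
#'   `whz`, `waz`, `haz`), `school_age` (covariates, `treatment`, `bmi`),
#'   and `truth` (per outcome: `y0`, `y1`, `tau_true` on the cohort rows,
#'   plus `p_select` for all records).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  covariates <- generate_covariates(config)
  trt <- assign_treatment(covariates, config$selection_coefs,
                          seed = sub_seed(config$seed, 2L))
  profiles <- outcome_profiles()
  truth <- list(p_select = trt$p_select)
  cohorts <- list()
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    rows <- which(covariates$cohort == pr$cohort)
    sim <- simulate_outcomes(covariates[rows, ], trt$treatment[rows], pr$effect,
                             pr$noise_sd, seed = sub_seed(config$seed, 30L + match(nm, names(profiles))),
                             outcome_coefs = pr$outcome_coefs)
    if (is.null(cohorts[[pr$cohort]])) {
      cohorts[[pr$cohort]] <- covariates[rows, ]
      cohorts[[pr$cohort]]$treatment <- trt$treatment[rows]
    }
    cohorts[[pr$cohort]][[nm]] <- sim$outcome
    truth[[nm]] <- sim$truth
  }
  list(preschool = cohorts$preschool, school_age = cohorts$school_age, truth = truth)
}

#' Descriptive table for a simulated two-cohort study
#'
#' Mirrors the published 11-row layout: one row per outcome (computed
#' within its cohort) followed by the seven descriptive covariates
#' (computed on the pooled sample; the wealth quintile, a derived analysis
#' variable, is not part of the descriptive table), each with group
#' means/SDs, the control-minus-treatment difference, and a Welch t-test.
#'
#' @param study output of [simulate_study()].
#' @return a group-summary data frame (see [summarize_by_group()]).
#' @export
describe_study <- function(study) {
  pre <- study$preschool
  sch <- study$school_age
  vars <- setdiff(covariate_columns(), "wealth_quintile")
  pooled <- rbind(pre[c(vars, "treatment")], sch[c(vars, "treatment")])
  rbind(summarize_by_group(pre, variables = c("whz", "waz", "haz")),
        summarize_by_group(sch, variables = "bmi"),
        summarize_by_group(pooled, variables = vars))
}

#' Configuration of a full analysis run
#'
#' @param sim a [sim_config()] for synthetic input, or NULL when reading
#'   from `csv`.
#' @param csv path to an analysis-table CSV (exactly one of `sim`/`csv`).
#' @param cohort `"preschool"` or `"school_age"`.
#' @param outcome `"whz"`, `"waz"`, `"haz"` (preschool) or `"bmi"`
#'   (school-age); must be compatible with the cohort.
#' @param bandwidth kernel-matching bandwidth.
#' @param k neighbors for 1:k nearest-neighbor matching.
#' @param bootstrap bootstrap resamples for the matching SEs (0 skips).
#' @param stage1_trees,stage2_trees causal-forest sizes for the screening
#'   and final stage.
#' @param min_leaf per-arm minimum leaf size of the causal forest.
#' @param seed master seed of the run.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(), csv = NULL, cohort = "preschool",
                       outcome = "whz", bandwidth = 0.06, k = 4L,
                       bootstrap = 0L, stage1_trees = 200L, stage2_trees = 500L,
                       min_leaf = 5L, seed = 1L) {
  if (is.null(sim) == is.null(csv)) {
    stop("exactly one input source (sim or csv) must be given", call. = FALSE)
  }
  profiles <- outcome_profiles()
  if (!outcome %in% names(profiles)) stop("unknown outcome: ", outcome, call. = FALSE)
  if (profiles[[outcome]]$cohort != cohort) {
    stop(sprintf("outcome '%s' is incompatible with cohort '%s'", outcome, cohort),
         call. = FALSE)
  }
  structure(list(sim = sim, csv = csv, cohort = cohort, outcome = outcome,
                 bandwidth = bandwidth, k = as.integer(k),
                 bootstrap = as.integer(bootstrap),
                 stage1_trees = as.integer(stage1_trees),
                 stage2_trees = as.integer(stage2_trees),
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full study replica for one cohort and outcome
#'
#' Executes the complete pipeline — simulate (or load), describe, match
#' with all three matching estimators, fit the two-stage honest causal
#' forest — and writes the output bundle to `outdir`: `descriptives.csv`,
#' `psm_estimates.csv`, `balance.csv`, `propensity_hist.csv`,
#' `importance.csv`, `subgroups.csv`, `cite.csv`, `cite_histogram.csv`,
#' `median_split.csv`, and `manifest.json` (seeds, parameters, record
#' counts, heterogeneity verdict). Deterministic given the master seed.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`data`,
#'   `descriptives`, `psm`, `balance`, `forest_fit`, `cite_summary`,
#'   `manifest`).
#' @export
run_full_analysis <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$csv)) {
    data <- read_dataset(config$csv)
  } else {
    sim <- config$sim
    sim$seed <- config$seed
    study <- simulate_study(sim)
    data <- study[[config$cohort]]
    data$outcome <- data[[config$outcome]]
    data <- data[c(covariate_columns(), "cohort", "treatment", "outcome")]
  }
  validate_dataset(data)

  desc <- summarize_by_group(data, variables = c("outcome", covariate_columns()))
  utils::write.csv(desc, file.path(outdir, "descriptives.csv"), row.names = FALSE)

  methods <- c("nn_1", "nn_k", "kernel")
  psm <- lapply(methods, function(mth) {
    fit <- psm_att(data, method = mth, k = config$k, bandwidth = config$bandwidth)
    se <- NA_real_
    if (config$bootstrap >= 2) {
      se <- bootstrap_se(data, function(d) psm_att(d, method = mth, k = config$k,
                                                   bandwidth = config$bandwidth)$att$value,
                         B = config$bootstrap, seed = sub_seed(config$seed, 40L))$se
      fit$att <- estimate_att(fit$match, data$outcome, data$treatment, se = se)
    }
    fit
  })
  names(psm) <- methods
  est <- do.call(rbind, lapply(methods, function(mth) {
    a <- psm[[mth]]$att
    data.frame(outcome = config$outcome, method = mth, estimand = a$estimand,
               estimate = a$value, se = a$se, stars = a$stars,
               n_treated = a$n_treated, n_control_used = a$n_control_used)
  }))
  utils::write.csv(est, file.path(outdir, "psm_estimates.csv"), row.names = FALSE)

  bal <- balance_check(data, data$treatment, psm$kernel$match)
  utils::write.csv(bal, file.path(outdir, "balance.csv"), row.names = FALSE)
  utils::write.csv(propensity_histogram(psm$kernel$scores, data$treatment),
                   file.path(outdir, "propensity_hist.csv"), row.names = FALSE)

  forest_fit <- two_stage_fit(
    data,
    stage1_params = forest_params(n_trees = config$stage1_trees, min_leaf = config$min_leaf),
    stage2_params = forest_params(n_trees = config$stage2_trees, min_leaf = config$min_leaf),
    seed = sub_seed(config$seed, 50L))
  utils::write.csv(forest_fit$importance, file.path(outdir, "importance.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(cite = forest_fit$cite),
                   file.path(outdir, "cite.csv"), row.names = FALSE)
  cite_summary <- cite_distribution_summary(forest_fit$cite)
  utils::write.csv(cite_summary$histogram, file.path(outdir, "cite_histogram.csv"),
                   row.names = FALSE)
  X_enc <- encode_covariates(data[covariate_columns()])
  subs <- subgroup_table(forest_fit$cite, data$treatment, X_enc,
                         columns = intersect(forest_fit$selected, names(X_enc)))
  utils::write.csv(subs, file.path(outdir, "subgroups.csv"), row.names = FALSE)
  med <- median_split_profile(forest_fit$cite, data[covariate_columns()])
  utils::write.csv(med, file.path(outdir, "median_split.csv"), row.names = FALSE)

  manifest <- list(
    cohort = config$cohort, outcome = config$outcome, seed = config$seed,
    n = nrow(data), n_treated = sum(data$treatment == 1),
    n_control = sum(data$treatment == 0),
    n_outside_support = psm$kernel$support$n_dropped,
    bandwidth = config$bandwidth, k = config$k, bootstrap = config$bootstrap,
    stage1_trees = config$stage1_trees, stage2_trees = config$stage2_trees,
    min_leaf = config$min_leaf,
    selected_covariates = forest_fit$selected,
    cite_interval = cite_summary$interval_display,
    heterogeneity_verdict = cite_summary$verdict)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(data = data, descriptives = desc, psm = psm, balance = bal,
                 forest_fit = forest_fit, cite_summary = cite_summary,
                 manifest = manifest))
}

#' Parameter-recovery experiment against synthetic ground truth
#'
#' Across replicates with fresh seeds, simulates a cohort with known
#' effects and scores every estimator against the truth: bias and RMSE of
#' the naive mean difference, 1:1 and 1:k nearest-neighbor ATT, kernel
#' ATT (all vs the true ATT) and the forest mean effect (vs the true
#' ATE); the RMSE of the per-record effect estimates against the true
#' \eqn{\tau(x)}; and the error of the rural-vs-urban subgroup contrast.
#' Replicates where an estimator raises are recorded and excluded.
#'
#' @param config a [sim_config()] defining the data-generating process.
#' @param n_replicates number of Monte-Carlo replicates (>= 1).
#' @param forest_trees trees of the (single-stage) forest per replicate.
#' @param min_leaf forest leaf size.
#' @param bandwidth kernel bandwidth.
#' @param k neighbors for the 1:k matcher.
#' @param outdir optional directory for `recovery.csv` / `recovery.json`.
#' @return list with `summary` (estimator, bias, rmse, n_ok),
#'   `cite_rmse` (mean over replicates), `tau_sd` (sd of the true effects,
#'   the predict-the-mean baseline), `subgroup_contrast_error`,
#'   `replicates` (per-replicate estimates), `n_failed`, `seeds`.
#' @export
parameter_recovery_experiment <- function(config, n_replicates = 10L,
                                          forest_trees = 100L, min_leaf = 5L,
                                          bandwidth = 0.06, k = 4L,
                                          outdir = NULL) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  seeds <- vapply(seq_len(n_replicates), function(r) sub_seed(config$seed, 700L + r),
                  numeric(1))
  estimators <- c("naive", "nn_1", "nn_4", "kernel", "forest_ate")
  reps <- data.frame(replicate = seq_len(n_replicates), seed = seeds)
  for (e in estimators) reps[[e]] <- NA_real_
  reps$true_att <- NA_real_; reps$true_ate <- NA_real_
  reps$cite_rmse <- NA_real_; reps$tau_sd <- NA_real_
  reps$subgroup_contrast <- NA_real_; reps$true_contrast <- NA_real_
  reps$failed <- FALSE
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seeds[r])
    # routine per-replicate warnings (e.g. zero-mass kernel drops) are expected
    res <- tryCatch(suppressWarnings({
      sim <- simulate_sample(cfg)
      d <- sim$data; tr <- sim$truth
      w <- d$treatment
      true_att <- mean(tr$tau_true[w == 1])
      true_ate <- mean(tr$tau_true)
      naive <- mean(d$outcome[w == 1]) - mean(d$outcome[w == 0])
      nn1 <- psm_att(d, "nn_1")$att$value
      nn4 <- psm_att(d, "nn_k", k = k)$att$value
      ker <- psm_att(d, "kernel", bandwidth = bandwidth)$att$value
      X <- encode_covariates(d[covariate_columns()])
      cf <- fit_causal_forest(X, d$outcome, w,
                              forest_params(n_trees = forest_trees, min_leaf = min_leaf),
                              seed = cfg$seed)
      cite <- predict_cate(cf)
      rural <- d$living_area == 0
      contrast <- if (any(rural & w == 0) && any(!rural & w == 0)) {
        subgroup_effect(cite, w, rural)$estimate -
          subgroup_effect(cite, w, !rural)$estimate
      } else NA_real_
      true_contrast <- if (any(rural & w == 0) && any(!rural & w == 0)) {
        mean(tr$tau_true[rural & w == 0]) - mean(tr$tau_true[!rural & w == 0])
      } else NA_real_
      list(naive = naive, nn_1 = nn1, nn_4 = nn4, kernel = ker,
           forest_ate = mean(cite), true_att = true_att, true_ate = true_ate,
           cite_rmse = sqrt(mean((cite - tr$tau_true)^2)),
           tau_sd = stats::sd(tr$tau_true),
           subgroup_contrast = contrast, true_contrast = true_contrast)
    }), error = function(e) NULL)
    if (is.null(res)) { reps$failed[r] <- TRUE; next }
    for (nm in names(res)) reps[[nm]][r] <- res[[nm]]
  }
  ok <- !reps$failed
  if (!any(ok)) stop("every replicate failed", call. = FALSE)
  truth_of <- function(e) if (e == "forest_ate") reps$true_ate[ok] else reps$true_att[ok]
  summary <- do.call(rbind, lapply(estimators, function(e) {
    err <- reps[[e]][ok] - truth_of(e)
    data.frame(estimator = e, bias = mean(err), rmse = sqrt(mean(err^2)),
               n_ok = sum(ok))
  }))
  out <- list(summary = summary,
              cite_rmse = mean(reps$cite_rmse[ok]),
              tau_sd = mean(reps$tau_sd[ok]),
              subgroup_contrast_error =
                mean(abs(reps$subgroup_contrast[ok] - reps$true_contrast[ok]), na.rm = TRUE),
              replicates = reps, n_failed = sum(!ok), seeds = seeds)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(reps, file.path(outdir, "recovery.csv"), row.names = FALSE)
    jsonlite::write_json(out[c("summary", "cite_rmse", "tau_sd",
                               "subgroup_contrast_error", "n_failed")],
                         file.path(outdir, "recovery.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}
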