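#' Configuration for the synthetic child-cohort generator
#'
#' Bundles every knob of the synthetic cohort: sample size, the split
#' between preschool (ages 0--5, z-score outcomes) and school-age (6--16,
#' BMI) records, covariate distribution parameters, the enrollment-selection
#' logit coefficients, the treatment-effect function, and outcome noise.
#' Defaults emulate the published CFPS 2018 rural-child sample: 5552
#' records, roughly 36% preschool, ~85.7% insurance enrollment with
#' selection loading negatively on household income and urban residence and
#' positively on child and mother age, and modestly heterogeneous effects
#' favouring disadvantaged households.
#'
#' @param n_total number of records (>= 2).
#' @param cohort_split fraction of preschool records, in \[0, 1\].
#' @param covariate_params list overriding any of: `gender_prob`,
#'   `mother_age_gap_mean`, `mother_age_gap_sd`, `mother_age_range`,
#'   `education_probs` (length 7), `income_mean`, `income_sd`, `urban_prob`,
#'   `region_probs` (length 3, eastern/central/western), `wealth_jitter_sd`.
#' @param selection_coefs named numeric vector for the enrollment logit:
#'   `intercept` plus any subset of the covariate columns.
#' @param effect an [effect_spec()] giving the true \eqn{\tau(x)}.
#' @param outcome_coefs named coefficients of the baseline outcome surface
#'   \eqn{f(x)}: `intercept`, `mother_education`, `log_income_pc`,
#'   `child_age`.
#' @param noise_sd standard deviation of the Normal outcome noise (>= 0).
#' @param seed master RNG seed; every stage derives its own stream from it.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_total = 500, seed = 1)
sim_config <- function(n_total = 5552,
                       cohort_split = 2015 / 5552,
                       covariate_params = list(),
                       selection_coefs = default_selection_coefs(),
                       effect = effect_spec(tau0 = 0.13, rural = 0.05,
                                            low_mother_education = 0.08,
                                            mother_age_slope = 0.008),
                       outcome_coefs = c(intercept = -3.0,
                                         mother_education = 0.05,
                                         log_income_pc = 0.30,
                                         child_age = 0.02),
                       noise_sd = 0.75,
                       seed = 1L) {
  stopifnot(is.numeric(n_total), length(n_total) == 1L, n_total >= 2)
  stopifnot(is.numeric(cohort_split), cohort_split >= 0, cohort_split <= 1)
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(inherits(effect, "effect_spec"))
  defaults <- list(
    gender_prob = 0.53,
    mother_age_gap_mean = 27, mother_age_gap_sd = 5,
    mother_age_range = c(16, 55),
    education_probs = c(0.10, 0.32, 0.33, 0.13, 0.06, 0.05, 0.01),
    income_mean = 9.0, income_sd = 0.95,
    urban_prob = 0.35,
    region_probs = c(0.30, 0.35, 0.35),
    wealth_jitter_sd = 0.30
  )
  unknown <- setdiff(names(covariate_params), names(defaults))
  if (length(unknown)) stop("unknown covariate_params: ", paste(unknown, collapse = ", "), call. = FALSE)
  params <- utils::modifyList(defaults, covariate_params)
  if (params$mother_age_gap_sd < 0 || params$income_sd < 0 || params$wealth_jitter_sd < 0) {
    stop("distribution standard deviations must be >= 0", call. = FALSE)
  }
  if (length(params$education_probs) != 7 || any(params$education_probs < 0)) {
    stop("education_probs must be 7 nonnegative weights", call. = FALSE)
  }
  if (length(params$region_probs) != 3 || any(params$region_probs < 0)) {
    stop("region_probs must be 3 nonnegative weights", call. = FALSE)
  }
  if (is.null(names(selection_coefs)) || !"intercept" %in% names(selection_coefs)) {
    stop("selection_coefs must be named and include an 'intercept'", call. = FALSE)
  }
  structure(list(n_total = as.integer(n_total), cohort_split = cohort_split,
                 covariate_params = params, selection_coefs = selection_coefs,
                 effect = effect, outcome_coefs = outcome_coefs,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default enrollment-selection coefficients
#'
#' Calibrated so the default generator yields ~85.7% enrollment (the
#' 4760/5552 treated share of the emulated sample), with enrolled children
#' drawn from poorer, more rural households with older mothers of lower
#' education.
#'
#' @return named numeric vector usable as `selection_coefs` in [sim_config()].
#' @export
default_selection_coefs <- function() {
  c(intercept = 5.24, child_gender = 0.05, child_age = 0.10,
    mother_age = 0.04, mother_education = -0.30, log_income_pc = -0.55,
    living_area = -0.60, region = 0.35)
}

#' Generate covariates for a synthetic child cohort
#'
#' Draws the eight covariate columns of the child-level table: child gender
#' and integer age (0--5 preschool, 6--16 school-age), mother's age
#' (child's age plus a Normal generation gap, truncated to a plausible
#' range) and 7-level education, log household income per capita, urban
#' indicator, 3-level region, and a wealth quintile formed by quintile-
#' ranking log income plus independent jitter.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `child_gender`, `child_age`,
#'   `mother_age`, `mother_education`, `log_income_pc`, `living_area`,
#'   `region`, `wealth_quintile`, `cohort`.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$covariate_params
  n <- config$n_total
  set.seed(sub_seed(config$seed, 1L))
  n_pre <- round(n * config$cohort_split)
  cohort <- c(rep("preschool", n_pre), rep("school_age", n - n_pre))
  child_age <- integer(n)
  if (n_pre > 0) child_age[seq_len(n_pre)] <- sample(0:5, n_pre, replace = TRUE)
  if (n - n_pre > 0) child_age[seq_len(n - n_pre) + n_pre] <- sample(6:16, n - n_pre, replace = TRUE)
  mother_age <- child_age + stats::rnorm(n, p$mother_age_gap_mean, p$mother_age_gap_sd)
  mother_age <- pmin(pmax(mother_age, p$mother_age_range[1]), p$mother_age_range[2])
  log_income_pc <- stats::rnorm(n, p$income_mean, p$income_sd)
  # wealth quintile: within-sample quintile rank of a jittered income signal
  jitter <- stats::rnorm(n, 0, p$wealth_jitter_sd)
  wealth_quintile <- as.integer(cut(rank(log_income_pc + jitter, ties.method = "first"),
                                    breaks = 5, labels = FALSE))
  data.frame(
    child_gender = stats::rbinom(n, 1, p$gender_prob),
    child_age = child_age,
    mother_age = mother_age,
    mother_education = sample(1:7, n, replace = TRUE, prob = p$education_probs),
    log_income_pc = log_income_pc,
    living_area = stats::rbinom(n, 1, p$urban_prob),
    region = sample(1:3, n, replace = TRUE, prob = p$region_probs),
    wealth_quintile = wealth_quintile,
    cohort = cohort
  )
}

#' Assign confounded insurance enrollment
#'
#' Draws the binary treatment (enrollment) indicator from a Bernoulli whose
#' probability is the inverse-logit of a linear index in the covariates, so
#' that selection into treatment depends on observables only (the
#' conditional-independence design every downstream estimator assumes).
#'
#' @param covariates covariate table from [generate_covariates()].
#' @param selection_coefs named coefficient vector: `intercept` plus any
#'   subset of the covariate columns.
#' @param seed RNG seed for the Bernoulli draws.
#' @return list with `treatment` (0/1 vector) and `p_select` (true
#'   enrollment probabilities).
#' @export
assign_treatment <- function(covariates, selection_coefs, seed = 1L) {
  if (is.null(names(selection_coefs)) || !"intercept" %in% names(selection_coefs)) {
    stop("selection_coefs must be named and include an 'intercept'", call. = FALSE)
  }
  vars <- setdiff(names(selection_coefs), "intercept")
  missing <- setdiff(vars, names(covariates))
  if (length(missing)) {
    stop("selection_coefs name columns absent from covariates: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lp <- rep(selection_coefs[["intercept"]], nrow(covariates))
  for (v in vars) lp <- lp + selection_coefs[[v]] * covariates[[v]]
  p_select <- stats::plogis(lp)
  set.seed(seed)
  list(treatment = stats::rbinom(length(p_select), 1, p_select), p_select = p_select)
}

#' Simulate potential outcomes and the observed outcome
#'
#' Realizes the partially linear outcome model \eqn{Y = f(X) + W \tau(X) +
#' \epsilon}: the untreated potential outcome is a linear baseline surface
#' plus Normal noise, the treated one adds the true effect \eqn{\tau(x)},
#' and the observed outcome obeys the consistency identity
#' \eqn{Y = W y_1 + (1 - W) y_0} exactly.
#'
#' @param covariates covariate table.
#' @param treatment 0/1 vector, one per record.
#' @param effect an [effect_spec()].
#' @param noise_sd outcome noise standard deviation (>= 0).
#' @param seed RNG seed for the noise draws.
#' @param outcome_coefs baseline-surface coefficients (see [sim_config()]).
#' @return list with `outcome` (observed Y) and `truth`, a data frame with
#'   per-record `y0`, `y1`, `tau_true`.
#' @export
simulate_outcomes <- function(covariates, treatment, effect, noise_sd, seed = 1L,
                              outcome_coefs = c(intercept = -3.0,
                                                mother_education = 0.05,
                                                log_income_pc = 0.30,
                                                child_age = 0.02)) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop("noise_sd must be a single number >= 0", call. = FALSE)
  }
  stopifnot(length(treatment) == nrow(covariates), all(treatment %in% c(0, 1)))
  f <- rep(outcome_coefs[["intercept"]], nrow(covariates))
  for (v in setdiff(names(outcome_coefs), "intercept")) {
    f <- f + outcome_coefs[[v]] * covariates[[v]]
  }
  tau <- true_cate(covariates, effect)
  set.seed(seed)
  y0 <- f + stats::rnorm(nrow(covariates), 0, noise_sd)
  y1 <- y0 + tau
  outcome <- ifelse(treatment == 1, y1, y0)
  # tau_true is stored as the realized y1 - y0 so the potential-outcome
  # identity holds bit-exactly; it agrees with true_cate() to rounding
  list(outcome = outcome,
       truth = data.frame(y0 = y0, y1 = y1, tau_true = y1 - y0))
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Runs the three generator stages (covariates, confounded enrollment,
#' outcomes) on their own RNG streams derived from the master seed, and
#' returns both the observable analysis table and the per-record synthetic
#' truth (potential outcomes, true effect, true selection probability).
#'
#' @param config a [sim_config()].
#' @return list with `data` (covariates + `treatment` + `outcome` +
#'   `cohort`) and `truth` (`y0`, `y1`, `tau_true`, `p_select`).
#' @export
#' @examples
#' sim <- simulate_sample(sim_config(n_total = 200, seed = 7))
#' stopifnot(all(sim$data$outcome ==
#'   ifelse(sim$data$treatment == 1, sim$truth$y1, sim$truth$y0)))
simulate_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  covariates <- generate_covariates(config)
  trt <- assign_treatment(covariates, config$selection_coefs,
                          seed = sub_seed(config$seed, 2L))
  out <- simulate_outcomes(covariates, trt$treatment, config$effect,
                           config$noise_sd, seed = sub_seed(config$seed, 3L),
                           outcome_coefs = config$outcome_coefs)
  data <- covariates
  data$treatment <- trt$treatment
  data$outcome <- out$outcome
  truth <- out$truth
  truth$p_select <- trt$p_select
  list(data = data, truth = truth)
}

#' Write / read a simulated cohort as CSV
#'
#' `write_simulation()` writes the analysis table (and, when given, the
#' synthetic truth) as plain CSV with documented column names, plus a small
#' JSON metadata file recording the seed. `read_dataset()` reads an
#' analysis table back and validates its columns.
#'
#' @param sim list as returned by [simulate_sample()].
#' @param path output path for the analysis table CSV.
#' @param truth_path optional path for the truth CSV.
#' @param seed seed recorded in the metadata JSON next to `path`.
#' @return `path`, invisibly.
#' @export
write_simulation <- function(sim, path, truth_path = NULL, seed = NULL) {
  utils::write.csv(sim$data, path, row.names = FALSE)
  if (!is.null(truth_path)) utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  meta <- list(columns = names(sim$data), n = nrow(sim$data), seed = seed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_simulation
#' @param file CSV path of an analysis table.
#' @export
read_dataset <- function(file) {
  validate_dataset(utils::read.csv(file))
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; `effect` is given as a map
#' with a `tau0` key plus modifier names.
#'
#' @param file YAML path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(file) {
  y <- yaml::read_yaml(file)
  if (!is.null(y$effect)) {
    y$effect <- do.call(effect_spec, y$effect)
  }
  if (!is.null(y$selection_coefs)) y$selection_coefs <- unlist(y$selection_coefs)
  if (!is.null(y$outcome_coefs)) y$outcome_coefs <- unlist(y$outcome_coefs)
  do.call(sim_config, y)
}
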