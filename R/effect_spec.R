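#' Specify a heterogeneous treatment-effect function
#'
#' Defines the true conditional average treatment effect (CATE)
#' \eqn{\tau(x)} used by the synthetic cohort generator: a baseline effect
#' plus named increments for covariate-defined subgroups and linear slopes
#' in continuous covariates. The recognized modifier names, with the record
#' condition each encodes, are:
#'
#' * `rural` / `urban`: `living_area == 0` / `== 1`
#' * `male` / `female`: `child_gender == 1` / `== 0`
#' * `low_mother_education` (levels 1--2), `high_mother_education` (5--7)
#' * `low_wealth` (quintiles 1--2), `high_wealth` (quintiles 4--5)
#' * `eastern` / `central` / `western`: `region == 1 / 2 / 3`
#' * `mother_age_slope`: increment per year of mother's age, centered at 34
#' * `child_age_slope`: increment per year of child's age, centered at 8
#' * `income_slope`: increment per unit of log income per capita, centered at 9
#'
#' @param tau0 baseline treatment effect (outcome units).
#' @param ... named modifier increments/slopes from the list above.
#' @return an object of class `effect_spec`.
#' @export
#' @examples
#' spec <- effect_spec(tau0 = 0.1, rural = 0.2)
effect_spec <- function(tau0 = 0, ...) {
  check_finite_scalar(tau0, "tau0")
  mods <- list(...)
  if (length(mods) && (is.null(names(mods)) || any(names(mods) == ""))) {
    stop("all effect modifiers must be named", call. = FALSE)
  }
  unknown <- setdiff(names(mods), names(effect_modifier_terms()))
  if (length(unknown)) {
    stop("unknown effect modifier(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(mods)) check_finite_scalar(mods[[nm]], nm)
  structure(list(tau0 = tau0, modifiers = mods), class = "effect_spec")
}

# modifier vocabulary: each entry maps covariates to the multiplier of its
# increment (indicator for subgroups, centered value for slopes)
effect_modifier_terms <- function() {
  list(
    rural                 = function(x) as.numeric(x$living_area == 0),
    urban                 = function(x) as.numeric(x$living_area == 1),
    male                  = function(x) as.numeric(x$child_gender == 1),
    female                = function(x) as.numeric(x$child_gender == 0),
    low_mother_education  = function(x) as.numeric(x$mother_education <= 2),
    high_mother_education = function(x) as.numeric(x$mother_education >= 5),
    low_wealth            = function(x) as.numeric(x$wealth_quintile <= 2),
    high_wealth           = function(x) as.numeric(x$wealth_quintile >= 4),
    eastern               = function(x) as.numeric(x$region == 1),
    central               = function(x) as.numeric(x$region == 2),
    western               = function(x) as.numeric(x$region == 3),
    mother_age_slope      = function(x) x$mother_age - 34,
    child_age_slope       = function(x) x$child_age - 8,
    income_slope          = function(x) x$log_income_pc - 9
  )
}

#' True conditional average treatment effect of a generated record
#'
#' Evaluates the effect function \eqn{\tau(x) = E[y_1 - y_0 \mid X = x]}
#' encoded by an [effect_spec()] on a covariate table. For data produced by
#' [simulate_outcomes()] this equals `truth$tau_true` element-wise.
#'
#' @param covariates data frame with the covariate columns (see
#'   [generate_covariates()]).
#' @param spec an [effect_spec()].
#' @return numeric vector of per-record true effects.
#' @export
true_cate <- function(covariates, spec) {
  stopifnot(inherits(spec, "effect_spec"))
  terms <- effect_modifier_terms()
  tau <- rep(spec$tau0, nrow(covariates))
  for (nm in names(spec$modifiers)) {
    tau <- tau + spec$modifiers[[nm]] * terms[[nm]](covariates)
  }
  tau
}
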