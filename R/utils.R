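# internal helpers shared across modules

#' Derive a reproducible sub-seed from a master seed
#'
#' Each stochastic stage of the pipeline draws from its own RNG stream,
#' seeded deterministically from the master seed, so stages can be re-run
#' independently without disturbing each other.
#'
#' @param seed master seed (integer).
#' @param stream small integer identifying the stage.
#' @return an integer seed below 2^31.
#' @keywords internal
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 65011 + 1) * 7919 + stream * 104729) %% 2147483629L
}

#' Significance stars for a p-value
#'
#' Default thresholds follow the descriptive-table convention: `***` below
#' 1%, `**` below 5%, `*` below 10%. Matching estimates use only the 1% and
#' 5% levels (pass `levels = c("***" = 0.01, "**" = 0.05)`).
#'
#' @param p p-value(s) in \[0, 1\].
#' @param levels named numeric vector of thresholds, names are the star
#'   strings, in increasing threshold order.
#' @return character vector of star strings ("" when not significant).
#' @export
#' @examples
#' significance_stars(c(0.005, 0.03, 0.08, 0.5))
significance_stars <- function(p, levels = c("***" = 0.01, "**" = 0.05, "*" = 0.10)) {
  stopifnot(is.numeric(p), all(is.finite(p)), all(p >= 0 & p <= 1))
  out <- rep("", length(p))
  for (i in rev(seq_along(levels))) out[p < levels[i]] <- names(levels)[i]
  out
}

# scalar finiteness check with a readable error
check_finite_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

# names of the child/mother/household covariates, in canonical order
covariate_columns <- function() {
  c("child_gender", "child_age", "mother_age", "mother_education",
    "log_income_pc", "living_area", "region", "wealth_quintile")
}

# validate a child-level analysis table; returns it invisibly
validate_dataset <- function(data, require_outcome = TRUE) {
  need <- c(covariate_columns(), "treatment", if (require_outcome) "outcome")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("dataset is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyNA(data[need])) stop("dataset contains missing values", call. = FALSE)
  if (!all(data$treatment %in% c(0, 1))) stop("treatment must be 0/1", call. = FALSE)
  if (!all(data$mother_education %in% 1:7)) stop("mother_education must be in 1..7", call. = FALSE)
  if (!all(data$wealth_quintile %in% 1:5)) stop("wealth_quintile must be in 1..5", call. = FALSE)
  invisible(data)
}
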