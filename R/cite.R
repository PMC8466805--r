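#' Summarize the distribution of conditional individual treatment effects
#'
#' Reports the empirical 2.5th--97.5th percentile interval of the
#' per-record effect estimates (the "CITE" distribution), histogram bin
#' counts for plotting, and a heterogeneity verdict. The default verdict
#' rule reads the interval as describing sign variation of the individual
#' effects: an interval straddling 0 is called "heterogeneous
#' (sign-varying)", otherwise "homogeneous-sign". The conventional
#' opposite reading (straddling 0 interpreted as absence of a significant
#' effect) is available via `rule = "conventional"`.
#'
#' @param cite numeric vector of per-record effect estimates (>= 2 values).
#' @param breaks number of histogram bins.
#' @param rule verdict rule, `"sign_variation"` (default) or
#'   `"conventional"`.
#' @return list with `interval` (length 2, rounded to 3 decimals in
#'   `interval_display`), `histogram` (data frame `bin_lower`,
#'   `bin_upper`, `count`), `mean`, `verdict`.
#' @export
cite_distribution_summary <- function(cite, breaks = 30,
                                      rule = c("sign_variation", "conventional")) {
  rule <- match.arg(rule)
  if (length(cite) < 2) stop("need at least 2 effect estimates", call. = FALSE)
  interval <- unname(stats::quantile(cite, c(0.025, 0.975)))
  straddles <- interval[1] < 0 && interval[2] > 0
  verdict <- if (rule == "sign_variation") {
    if (straddles) "heterogeneous (sign-varying)" else "homogeneous-sign"
  } else {
    if (straddles) "no significant heterogeneity" else "heterogeneous"
  }
  h <- graphics::hist(cite, breaks = breaks, plot = FALSE)
  list(interval = interval,
       interval_display = round(interval, 3),
       histogram = data.frame(bin_lower = utils::head(h$breaks, -1),
                              bin_upper = h$breaks[-1], count = h$counts),
       mean = mean(cite), verdict = verdict)
}

#' Subgroup conditional average treatment effect
#'
#' Averages the per-record effect estimates over a subgroup. The default
#' estimand, CATC, averages over the subgroup's control units (the
#' conditional effect on the untreated); `"CATE"` averages over all
#' subgroup members. The SE is the naive `sd/sqrt(n)` of the averaged
#' effect estimates; it ignores estimation error in the effects themselves
#' and is a descriptive scale, not a calibrated forest variance.
#'
#' @param cite per-record effect estimates.
#' @param W 0/1 treatment vector.
#' @param subgroup_mask logical vector selecting the subgroup.
#' @param estimand `"CATC"` (default) or `"CATE"`.
#' @param label optional subgroup description.
#' @return data frame row with `subgroup`, `estimand`, `estimate`, `se`,
#'   `n`.
#' @export
subgroup_effect <- function(cite, W, subgroup_mask, estimand = c("CATC", "CATE"),
                            label = "") {
  estimand <- match.arg(estimand)
  stopifnot(length(cite) == length(W), length(cite) == length(subgroup_mask))
  if (!any(subgroup_mask)) stop("subgroup is empty", call. = FALSE)
  keep <- if (estimand == "CATC") subgroup_mask & W == 0 else subgroup_mask
  if (!any(keep)) stop("no control units in subgroup for CATC", call. = FALSE)
  vals <- cite[keep]
  data.frame(subgroup = label, estimand = estimand, estimate = mean(vals),
             se = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else NA_real_,
             n = length(vals))
}

#' Subgroup effects for every level of the selected covariates
#'
#' Builds the subgroup table: one CATC (or CATE) row per level of each
#' screened one-hot covariate column.
#'
#' @param cite per-record effect estimates.
#' @param W 0/1 treatment vector.
#' @param X encoded covariate data (columns are 0/1 indicators or numeric).
#' @param columns indicator columns to report; default all binary columns.
#' @param estimand passed to [subgroup_effect()].
#' @return data frame of subgroup rows.
#' @export
subgroup_table <- function(cite, W, X, columns = NULL, estimand = "CATC") {
  X <- as.data.frame(X)
  if (is.null(columns)) {
    columns <- names(X)[vapply(X, function(x) all(x %in% c(0, 1)), logical(1))]
  }
  rows <- lapply(columns, function(v) {
    tryCatch(subgroup_effect(cite, W, X[[v]] == 1, estimand = estimand, label = v),
             error = function(e) NULL)
  })
  do.call(rbind, rows)
}

#' Covariate profile of above- vs below-median effect groups
#'
#' Splits records at the median of the effect estimates (median assigned
#' to the lower half), then compares per-covariate means between the two
#' halves with a Welch t-test, profiling who benefits most.
#'
#' @param cite per-record effect estimates (length >= 4, not constant).
#' @param covariates covariate data frame (numeric columns).
#' @return data frame with `covariate`, `mean_below`, `mean_above`, `gap`
#'   (above minus below), `t`, `p`, `stars`.
#' @export
median_split_profile <- function(cite, covariates) {
  if (length(cite) < 4) stop("need at least 4 records", call. = FALSE)
  if (stats::var(cite) == 0) stop("effect estimates are constant: no median split", call. = FALSE)
  med <- stats::median(cite)
  below <- cite <= med
  vars <- names(covariates)[vapply(covariates, is.numeric, logical(1))]
  rows <- lapply(vars, function(v) {
    x <- covariates[[v]]
    # a covariate constant within both halves separates them perfectly (or
    # not at all): the t-test degenerates, so report the limit directly
    if (stats::var(x[below]) == 0 && stats::var(x[!below]) == 0 &&
        mean(x[below]) != mean(x[!below])) {
      g <- mean(x[!below]) - mean(x[below])
      return(data.frame(covariate = v, mean_below = mean(x[below]),
                        mean_above = mean(x[!below]), gap = g,
                        t = sign(g) * Inf, p = 0, stars = "***"))
    }
    tt <- welch_t_test(x[!below], x[below])
    data.frame(covariate = v, mean_below = mean(x[below]),
               mean_above = mean(x[!below]),
               gap = mean(x[!below]) - mean(x[below]),
               t = tt$t, p = tt$p, stars = tt$stars)
  })
  do.call(rbind, rows)
}
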