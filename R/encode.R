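#' One-hot encode the child-cohort covariates
#'
#' Expands the ordinal/categorical covariates into indicator columns, the
#' representation the causal forest trains on (so importance can be
#' reported at the level of individual categories such as "mother's
#' education: no formal education"), while continuous covariates pass
#' through unchanged. `living_area` is recoded as a rural indicator.
#'
#' @param covariates data frame with any subset of the canonical covariate
#'   columns; other numeric columns pass through.
#' @return numeric data frame of encoded columns.
#' @export
encode_covariates <- function(covariates) {
  out <- list()
  for (v in names(covariates)) {
    x <- covariates[[v]]
    if (v == "mother_education") {
      labs <- c("no_formal_education", "primary_school", "junior_high_school",
                "high_school", "junior_college", "bachelor_degree", "master")
      for (lev in sort(unique(x))) {
        out[[paste0("mother_education_", labs[lev])]] <- as.numeric(x == lev)
      }
    } else if (v == "region") {
      labs <- c("eastern", "central", "western")
      for (lev in sort(unique(x))) {
        out[[paste0("region_", labs[lev])]] <- as.numeric(x == lev)
      }
    } else if (v == "wealth_quintile") {
      for (lev in sort(unique(x))) {
        out[[paste0("wealth_quintile_", lev)]] <- as.numeric(x == lev)
      }
    } else if (v == "living_area") {
      out[["living_area_rural"]] <- as.numeric(x == 0)
    } else if (v == "child_gender") {
      out[["child_gender_male"]] <- as.numeric(x == 1)
    } else if (is.numeric(x)) {
      out[[v]] <- as.numeric(x)
    }
  }
  as.data.frame(out)
}
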