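#' Published descriptive statistics of the emulated child cohort
#'
#' Group means and standard deviations, by insurance-enrollment status, of
#' the 2018 CFPS rural-child sample the synthetic generator emulates (4760
#' enrolled, 792 uninsured), together with the differences column as
#' printed in the published descriptive table. Used to validate the
#' control-minus-treatment sign convention of [mean_difference()]:
#' `rounding_consistent` marks the rows where the printed difference
#' equals the arithmetic on the printed (rounded) group means; the
#' remaining rows were evidently computed from unrounded microdata and are
#' not forced to agree.
#'
#' @return list with `table` (one row per variable: `variable`,
#'   `treat_mean`, `treat_sd`, `control_mean`, `control_sd`,
#'   `printed_difference`, `rounding_consistent`), `n_treat`, `n_control`.
#' @export
reference_descriptives <- function() {
  table <- data.frame(
    variable = c("whz", "waz", "haz", "bmi", "child_gender", "child_age",
                 "mother_age", "mother_education", "log_income_pc",
                 "living_area", "region"),
    treat_mean = c(-0.185, 0.022, 0.020, 18.283, 0.539, 7.813,
                   34.211, 2.676, 8.994, 0.332, 2.047),
    treat_sd = c(0.802, 1.012, 0.991, 5.209, 0.499, 4.241,
                 6.590, 1.143, 0.890, 0.471, 0.819),
    control_mean = c(-0.376, -0.091, -0.069, 18.944, 0.501, 5.765,
                     32.694, 3.057, 9.079, 0.455, 1.816),
    control_sd = c(0.770, 0.929, 1.012, 6.703, 0.500, 4.807,
                   6.895, 1.393, 1.059, 0.498, 0.827),
    printed_difference = c(-0.191, -0.112, -0.090, 0.661, -0.037, -2.048,
                           -1.517, 0.381, 0.085, 0.123, -0.232),
    rounding_consistent = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE,
                            TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  list(table = table, n_treat = 4760L, n_control = 792L)
}
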