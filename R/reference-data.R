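#' Published phantom alignment summaries
#'
#' Reference summary statistics from a CT-on-rail motion-phantom study of
#' longitudinal alignment error: the mean of the 10 absolute longitudinal
#' alignments (the systematic component, \eqn{\Sigma}) and their standard
#' deviation (the random component, \eqn{\sigma}) for every combination of
#' the standard and slow CT protocols, motion amplitudes of 5/10/15 mm, and
#' breathing rates of 8/20/28 BPM. These are the measured inputs to the
#' margin formula and to the protocol comparisons; the package's simulator
#' reproduces their qualitative trends, not these physical values.
#'
#' @return a data.frame with columns `protocol` (`"standard"`/`"slow"`),
#'   `amplitude_mm`, `rate_bpm`, `n` (10), `sigma_sys_mm`, `sigma_rand_mm`.
#' @examples
#' margin_table(quasar_phantom_summaries())
#' @export
quasar_phantom_summaries <- function() {
  grid <- expand.grid(
    rate_bpm = c(28, 20, 8),
    amplitude_mm = c(5, 10, 15),
    protocol = c("standard", "slow"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  # AVG (1 SD) of the 10 longitudinal alignments, mm, by
  # amplitude (5,10,15) x rate (28,20,8), standard protocol then slow
  std_mean <- c(0.7, 1.6, 1.7,   1.3, 2.3, 4.3,   2.1, 3.2, 5.2)
  std_sd   <- c(0.68, 1.60, 1.25, 0.83, 1.64, 2.00, 1.60, 2.10, 2.00)
  slow_mean <- c(1.0, 1.6, 1.3,  0.9, 1.4, 2.0,   1.6, 1.3, 1.6)
  slow_sd   <- c(0.00, 0.52, 0.95, 0.74, 1.27, 1.70, 0.85, 0.68, 1.69)
  grid$n <- 10L
  grid$sigma_sys_mm <- c(std_mean, slow_mean)
  grid$sigma_rand_mm <- c(std_sd, slow_sd)
  grid[, c("protocol", "amplitude_mm", "rate_bpm", "n",
           "sigma_sys_mm", "sigma_rand_mm")]
}

#' Published patient cohort drift summary
#'
#' Reference longitudinal bone-minus-GTV systematic difference observed over
#' daily CBCT fractions in a 31-patient thoracic SBRT cohort: mean -1.9 mm,
#' SD 1.7 mm, range +2.8 to -11.4 mm. These values parameterize the default
#' synthetic cohort generator.
#'
#' @return a list with `mean_mm`, `sd_mm`, `max_mm`, `min_mm`, `n_patients`.
#' @export
reference_cohort_drift <- function() {
  list(mean_mm = -1.9, sd_mm = 1.7, max_mm = 2.8, min_mm = -11.4,
       n_patients = 31L)
}
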