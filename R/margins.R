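#' Summarize alignment errors for one condition
#'
#' Reduces the repeated alignments of one protocol x amplitude x rate
#' condition to the two margin inputs: the systematic component
#' \eqn{\Sigma} (the mean of the absolute longitudinal errors, default) and
#' the random component \eqn{\sigma} (the sample standard deviation, n-1
#' denominator, of the same series). The signed mode summarizes the signed
#' errors instead, for sensitivity analysis.
#'
#' @param records alignment records (data.frame as from
#'   [run_phantom_experiment()]); all rows must share one condition.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return a one-row data.frame: `protocol`, `amplitude_mm`, `rate_bpm`, `n`,
#'   `sigma_sys_mm`, `sigma_rand_mm`.
#' @export
summarize_condition <- function(records, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  if (nrow(records) < 2L) {
    stop("undefined sigma: need at least 2 records per condition", call. = FALSE)
  }
  key <- unique(records[, c("protocol", "amplitude_mm", "rate_bpm")])
  if (nrow(key) != 1L) {
    stop("aggregation error: records mix more than one condition", call. = FALSE)
  }
  x <- if (mode == "absolute") records$abs_error_mm else records$signed_error_mm
  data.frame(
    protocol = key$protocol,
    amplitude_mm = key$amplitude_mm,
    rate_bpm = key$rate_bpm,
    n = nrow(records),
    sigma_sys_mm = mean(x),
    sigma_rand_mm = stats::sd(x),
    stringsAsFactors = FALSE
  )
}

#' Summarize alignment errors over all conditions
#'
#' Applies [summarize_condition()] per protocol x amplitude x rate cell.
#'
#' @inheritParams summarize_condition
#' @return a data.frame of condition summaries, one row per cell, ordered by
#'   protocol, amplitude, rate.
#' @export
summarize_alignments <- function(records, mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  split_key <- interaction(records$protocol, records$amplitude_mm,
                           records$rate_bpm, drop = TRUE)
  out <- do.call(rbind, lapply(split(records, split_key),
                               summarize_condition, mode = mode))
  out <- out[order(out$protocol, out$amplitude_mm, out$rate_bpm), ]
  rownames(out) <- NULL
  out
}

#' Margin formula parameters
#'
#' The coefficients of the PTV margin recipe: 2.5 on the (quadrature-combined)
#' systematic uncertainty, 0.7 on the random uncertainty, a 2 mm baseline
#' systematic term covering table and image resolution combined in quadrature
#' with the measured alignment systematic, and a 3 mm offset subtracted at the
#' end.
#'
#' @param systematic_multiplier weight on the systematic term (default 2.5).
#' @param random_multiplier weight on the random term (default 0.7).
#' @param baseline_systematic_mm system/patient-related systematic
#'   uncertainty added in quadrature (default 2 mm).
#' @param offset_mm constant subtracted from the margin (default 3 mm).
#' @return a list of class `margin_parameters`.
#' @export
margin_parameters <- function(systematic_multiplier = 2.5,
                              random_multiplier = 0.7,
                              baseline_systematic_mm = 2,
                              offset_mm = 3) {
  vals <- c(systematic_multiplier, random_multiplier,
            baseline_systematic_mm, offset_mm)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals < 0)) {
    stop("margin parameters must be finite and non-negative", call. = FALSE)
  }
  structure(list(systematic_multiplier = systematic_multiplier,
                 random_multiplier = random_multiplier,
                 baseline_systematic_mm = baseline_systematic_mm,
                 offset_mm = offset_mm),
            class = "margin_parameters")
}

#' PTV margin with quadrature baseline
#'
#' The margin recipe used for the phantom conditions:
#' \deqn{PTV = 2.5 \sqrt{b^2 + \Sigma^2} + 0.7\,\sigma - o}
#' with baseline \eqn{b = 2} mm and offset \eqn{o = 3} mm by default. The
#' baseline folds the system-related systematic uncertainty (table, image
#' resolution) into the measured alignment systematic in quadrature.
#'
#' @param sigma_sys_mm systematic uncertainty \eqn{\Sigma} (mm), >= 0.
#'   Vectorized.
#' @param sigma_rand_mm random uncertainty \eqn{\sigma} (mm), >= 0.
#'   Vectorized.
#' @param params a [margin_parameters()].
#' @return margin in mm (unrounded; see [round_margin()]).
#' @examples
#' eq1_margin(4.3, 2.0)   # 10.256 -> reported as 10.3
#' eq1_margin(0, 0)       # 2.5 * 2 - 3 = 2
#' @export
eq1_margin <- function(sigma_sys_mm, sigma_rand_mm,
                       params = margin_parameters()) {
  check_uncertainties(sigma_sys_mm, sigma_rand_mm)
  params$systematic_multiplier *
    sqrt(params$baseline_systematic_mm^2 + sigma_sys_mm^2) +
    params$random_multiplier * sigma_rand_mm - params$offset_mm
}

#' Linear van Herk margin
#'
#' The classic linear recipe \eqn{2.5\,\Sigma + 0.7\,\sigma - o}, with no
#' quadrature baseline. With \eqn{\Sigma = 2.64} mm, \eqn{\sigma = 2} mm and
#' a 3 mm offset this gives exactly 5.0 mm — the worked example motivating a
#' 5 mm PTV margin.
#'
#' @inheritParams eq1_margin
#' @param offset_mm offset subtracted (default 3 mm; use 0 for the textbook
#'   form).
#' @param systematic_multiplier,random_multiplier recipe weights.
#' @return margin in mm.
#' @export
van_herk_margin <- function(sigma_sys_mm, sigma_rand_mm, offset_mm = 3,
                            systematic_multiplier = 2.5,
                            random_multiplier = 0.7) {
  check_uncertainties(sigma_sys_mm, sigma_rand_mm)
  if (offset_mm < 0) stop("offset_mm must be >= 0", call. = FALSE)
  systematic_multiplier * sigma_sys_mm +
    random_multiplier * sigma_rand_mm - offset_mm
}

check_uncertainties <- function(sigma_sys_mm, sigma_rand_mm) {
  if (any(!is.finite(sigma_sys_mm)) || any(sigma_sys_mm < 0) ||
      any(!is.finite(sigma_rand_mm)) || any(sigma_rand_mm < 0)) {
    stop("uncertainties must be finite and >= 0", call. = FALSE)
  }
  invisible(NULL)
}

#' Round a margin for reporting
#'
#' Margins are reported to 0.1 mm, rounding half up to match the printed
#' clinical tables (base [round()] rounds half to even).
#'
#' @param margin_mm numeric vector of margins.
#' @return rounded margins.
#' @export
round_margin <- function(margin_mm) round_half_up(margin_mm, 1)

#' Margin table over a grid of condition summaries
#'
#' Applies [eq1_margin()] to each condition summary and reports both the
#' unrounded and the 0.1 mm-rounded margin, plus the per-protocol maximum.
#'
#' @param summaries condition summaries as from [summarize_alignments()] (or
#'   [quasar_phantom_summaries()]); needs columns `protocol`, `amplitude_mm`,
#'   `rate_bpm`, `sigma_sys_mm`, `sigma_rand_mm`.
#' @param params a [margin_parameters()].
#' @return a data.frame with columns of `summaries` plus `margin_mm`
#'   (rounded to 0.1 mm) and `margin_exact_mm`; attribute `protocol_max`
#'   holds the per-protocol maximum rounded margins.
#' @export
margin_table <- function(summaries, params = margin_parameters()) {
  if (nrow(summaries) == 0L) {
    out <- cbind(summaries, margin_mm = numeric(0), margin_exact_mm = numeric(0))
    attr(out, "protocol_max") <- numeric(0)
    return(out)
  }
  exact <- eq1_margin(summaries$sigma_sys_mm, summaries$sigma_rand_mm, params)
  out <- summaries
  out$margin_exact_mm <- exact
  out$margin_mm <- round_margin(exact)
  attr(out, "protocol_max") <- tapply(out$margin_mm, out$protocol, max)
  out
}
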