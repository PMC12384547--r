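#' Welch two-sample t-test from summary statistics
#'
#' Computes the two-sided Welch (unequal-variance) t-test directly from group
#' means, standard deviations and sizes:
#' \deqn{t = \frac{\bar x_1 - \bar x_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}}
#' with real-valued Welch-Satterthwaite degrees of freedom. This is the form
#' needed when only a table of per-condition means and SDs is available, as
#' with published alignment summaries.
#'
#' Degenerate inputs: if both SDs are zero and the means are equal the test
#' is vacuous (`t = 0`, `p = 1`); if both SDs are zero and the means differ,
#' `p = 0` is returned with a warning (infinite evidence under the model).
#'
#' @param mean1,mean2 group means.
#' @param sd1,sd2 group standard deviations (>= 0).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha significance level for the `significant` flag (default 0.05,
#'   i.e. the 95% confidence level).
#' @return a list of class `welch_result`: `t_statistic`, `df`, `p_value`,
#'   `alpha`, `significant`, and the inputs.
#' @examples
#' welch_from_summary(4.3, 2.00, 10, 2.0, 1.70, 10)  # p ~ 0.013
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2, alpha = 0.05) {
  if (n1 < 2 || n2 < 2) stop("insufficient data: need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se2 <- v1 + v2
  if (se2 == 0) {
    if (mean1 == mean2) {
      t_stat <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      warning("both groups have zero variance with unequal means; p = 0 is degenerate")
      t_stat <- sign(mean1 - mean2) * Inf; df <- n1 + n2 - 2; p <- 0
    }
  } else {
    t_stat <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(
    list(t_statistic = t_stat, df = df, p_value = p, alpha = alpha,
         significant = p < alpha,
         mean1 = mean1, sd1 = sd1, n1 = n1,
         mean2 = mean2, sd2 = sd2, n2 = n2),
    class = "welch_result"
  )
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.4g, p = %.2g%s\n",
              x$t_statistic, x$df, x$p_value,
              if (x$significant) sprintf(" (significant at alpha = %g)", x$alpha)
              else ""))
  invisible(x)
}

#' Welch two-sample t-test from raw samples
#'
#' Definitionally identical to [welch_from_summary()] applied to the samples'
#' means, SDs and sizes.
#'
#' @param xs,ys numeric samples, each of length >= 2.
#' @inheritParams welch_from_summary
#' @return a `welch_result`.
#' @export
welch_from_samples <- function(xs, ys, alpha = 0.05) {
  if (length(xs) < 2L || length(ys) < 2L) {
    stop("insufficient data: need at least 2 observations per sample", call. = FALSE)
  }
  welch_from_summary(mean(xs), stats::sd(xs), length(xs),
                     mean(ys), stats::sd(ys), length(ys), alpha = alpha)
}

#' Standard-vs-slow protocol comparison per condition
#'
#' Runs the Welch test between the two protocols for every amplitude x rate
#' condition of a summary table (absolute alignment errors; mean = Sigma,
#' SD = sigma, size = n), returning the full results and flagging the
#' significant conditions.
#'
#' @param summaries condition summaries covering both protocols for each
#'   condition (as from [summarize_alignments()] or
#'   [quasar_phantom_summaries()]).
#' @param alpha significance level (default 0.05).
#' @param protocols length-2 character vector naming the comparison pair;
#'   group 1 vs group 2.
#' @return a data.frame: `rate_bpm`, `amplitude_mm`, `t`, `df`, `p`,
#'   `significant`, ordered by rate then amplitude.
#' @export
protocol_comparison <- function(summaries, alpha = 0.05,
                                protocols = c("standard", "slow")) {
  stopifnot(length(protocols) == 2L)
  conds <- unique(summaries[, c("rate_bpm", "amplitude_mm")])
  conds <- conds[order(conds$rate_bpm, conds$amplitude_mm), , drop = FALSE]
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- summaries$rate_bpm == conds$rate_bpm[i] &
      summaries$amplitude_mm == conds$amplitude_mm[i]
    g1 <- summaries[sel & summaries$protocol == protocols[1], , drop = FALSE]
    g2 <- summaries[sel & summaries$protocol == protocols[2], , drop = FALSE]
    if (nrow(g1) != 1L || nrow(g2) != 1L) {
      stop(sprintf(
        "pairing error: condition (rate %g BPM, amplitude %g mm) lacks a '%s' vs '%s' pair",
        conds$rate_bpm[i], conds$amplitude_mm[i], protocols[1], protocols[2]
      ), call. = FALSE)
    }
    res <- welch_from_summary(g1$sigma_sys_mm, g1$sigma_rand_mm, g1$n,
                              g2$sigma_sys_mm, g2$sigma_rand_mm, g2$n,
                              alpha = alpha)
    data.frame(rate_bpm = conds$rate_bpm[i], amplitude_mm = conds$amplitude_mm[i],
               t = res$t_statistic, df = res$df, p = res$p_value,
               significant = res$significant)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "multiple_testing") <- "none (per-comparison p-values)"
  out
}

#' Conditions with a significant protocol difference
#'
#' @inheritParams protocol_comparison
#' @return a data.frame of the `(rate_bpm, amplitude_mm)` pairs where the
#'   standard-vs-slow Welch test has `p < alpha`.
#' @export
significance_pattern <- function(summaries, alpha = 0.05,
                                 protocols = c("standard", "slow")) {
  cmp <- protocol_comparison(summaries, alpha = alpha, protocols = protocols)
  out <- cmp[cmp$significant, c("rate_bpm", "amplitude_mm"), drop = FALSE]
  rownames(out) <- NULL
  out
}
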