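test_that("summary-statistics Welch test agrees with stats::t.test on exact samples", {
  # build samples with exactly the target mean/sd, so the summary route and
  # the sample route must coincide
  make_sample <- function(m, s, n) {
    x <- seq_len(n)
    m + s * (x - mean(x)) / sd(x)
  }
  cases <- list(c(4.3, 2.00, 2.0, 1.70), c(1.7, 1.25, 1.3, 0.95),
                c(3.2, 2.10, 1.3, 0.68), c(0.7, 0.68, 1.0, 0.3))
  for (cs in cases) {
    xs <- make_sample(cs[1], cs[2], 10)
    ys <- make_sample(cs[3], cs[4], 10)
    ours <- welch_from_summary(cs[1], cs[2], 10, cs[3], cs[4], 10)
    ref <- t.test(xs, ys)
    expect_equal(ours$t_statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("summary and sample routes are definitionally equivalent", {
  set.seed(31)
  for (i in 1:5) {
    xs <- rnorm(7 + i, 2, 1.3)
    ys <- rnorm(12, 1.1, 0.8)
    a <- welch_from_samples(xs, ys)
    b <- welch_from_summary(mean(xs), sd(xs), length(xs),
                            mean(ys), sd(ys), length(ys))
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$t_statistic, b$t_statistic, tolerance = 1e-12)
  }
  xs <- c(1, 2, 3)
  expect_equal(welch_from_samples(xs, xs)$p_value, 1)
  expect_lt(welch_from_samples(xs, xs + 10)$p_value, 0.001)
  expect_error(welch_from_samples(1, c(1, 2)), "insufficient")
})

test_that("degenerate and boundary Welch cases behave as documented", {
  eq <- welch_from_summary(2, 0, 10, 2, 0, 10)
  expect_equal(eq$t_statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_warning(ne <- welch_from_summary(2, 0, 10, 3, 0, 10), "degenerate")
  expect_equal(ne$p_value, 0)
  # one-sided variance collapse: df reduces to n1 - 1
  one <- welch_from_summary(0.7, 0.68, 10, 1.0, 0, 10)
  expect_equal(one$df, 9)
  expect_equal(one$p_value, 0.19644639, tolerance = 1e-6)
})

test_that("t is antisymmetric and p symmetric under group swap; p monotone in |diff|", {
  a <- welch_from_summary(4.3, 2.0, 10, 2.0, 1.7, 10)
  b <- welch_from_summary(2.0, 1.7, 10, 4.3, 2.0, 10)
  expect_equal(a$t_statistic, -b$t_statistic)
  expect_equal(a$p_value, b$p_value)
  deltas <- seq(0, 3, by = 0.25)
  ps <- vapply(deltas, function(d)
    welch_from_summary(1 + d, 1.5, 10, 1, 1.2, 10)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("protocol comparison reproduces the published significance pattern", {
  tab <- quasar_phantom_summaries()
  cmp <- protocol_comparison(tab)
  expect_equal(nrow(cmp), 9)
  # frozen oracle values (independent t-distribution implementation)
  row <- cmp[cmp$rate_bpm == 8 & cmp$amplitude_mm == 10, ]
  expect_equal(row$t, 2.77088324, tolerance = 1e-6)
  expect_equal(row$df, 17.544643, tolerance = 1e-4)
  expect_equal(row$p, 0.012810589, tolerance = 1e-6)
  row2 <- cmp[cmp$rate_bpm == 20 & cmp$amplitude_mm == 15, ]
  expect_equal(row2$p, 0.020058617, tolerance = 1e-6)
  sig <- significance_pattern(tab)
  expect_equal(sig[order(sig$rate_bpm, sig$amplitude_mm), ],
               data.frame(rate_bpm = c(8, 8, 20), amplitude_mm = c(10, 15, 15)),
               ignore_attr = TRUE)
  # alpha boundaries: strict p < alpha, and the equal-means condition
  # (20 BPM, 5 mm) has p = 1 exactly, so alpha = 1 captures the other 8
  expect_equal(nrow(significance_pattern(tab, alpha = 1.0)), 8)
  expect_equal(nrow(significance_pattern(tab, alpha = 0)), 0)
  # pairing error when a protocol is missing
  expect_error(protocol_comparison(tab[tab$protocol == "standard", ]),
               "pairing error")
})
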