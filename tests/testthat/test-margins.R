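test_that("condition summaries compute mean |error| and sample SD", {
  r <- records_from_errors(c(1, -1, 1, -1))
  s <- summarize_condition(r)
  expect_equal(s$sigma_sys_mm, 1)
  expect_equal(s$sigma_rand_mm, 0)
  s2 <- summarize_condition(records_from_errors(c(0, 0, 0)))
  expect_equal(c(s2$sigma_sys_mm, s2$sigma_rand_mm), c(0, 0))
  s3 <- summarize_condition(records_from_errors(c(1, 2, 3)))
  expect_equal(s3$sigma_sys_mm, 2)
  expect_equal(s3$sigma_rand_mm, 1)  # n-1 denominator
  expect_equal(s3$n, 3)
  # signed mode keeps the sign structure
  s4 <- summarize_condition(records_from_errors(c(1, -1, 1, -1)), mode = "signed")
  expect_equal(s4$sigma_sys_mm, 0)
  # error handling
  expect_error(summarize_condition(records_from_errors(1)), "at least 2")
  mixed <- rbind(records_from_errors(c(1, 2)),
                 records_from_errors(c(1, 2), amplitude_mm = 15))
  expect_error(summarize_condition(mixed), "aggregation")
})

test_that("quadrature margin formula matches its closed form and worked values", {
  expect_equal(round_margin(eq1_margin(4.3, 2.0)), 10.3)
  expect_equal(round_margin(eq1_margin(5.2, 2.0)), 12.3)
  expect_equal(eq1_margin(0, 0), 2)  # 2.5 * sqrt(4) - 3
  # strictly increasing in both arguments
  sig <- seq(0, 6, by = 0.5)
  expect_true(all(diff(eq1_margin(sig, 1)) > 0))
  expect_true(all(diff(eq1_margin(1, sig)) > 0))
  expect_true(all(eq1_margin(sig, sig) >= 2))
  expect_error(eq1_margin(-1, 0), ">= 0")
})

test_that("linear van Herk margin reproduces the 5 mm worked statement", {
  expect_equal(van_herk_margin(2.64, 2, offset_mm = 3), 5.0)
  expect_equal(van_herk_margin(0, 0, offset_mm = 0), 0)
  expect_equal(van_herk_margin(1, 1, offset_mm = 0), 3.2)
  # quadrature baseline contributes exactly 5 mm at zero systematic
  sig <- c(0, 0.5, 2, 3.7)
  expect_equal(eq1_margin(0, sig) - van_herk_margin(0, sig, offset_mm = 3),
               rep(5, length(sig)))
})

test_that("margin table reproduces the published margins from the published summaries", {
  mt <- margin_table(quasar_phantom_summaries())
  published <- data.frame(
    protocol = rep(c("standard", "slow"), each = 9),
    amplitude_mm = rep(rep(c(5, 10, 15), each = 3), 2),
    rate_bpm = rep(c(28, 20, 8), 6),
    margin_mm = c(2.8, 4.5, 4.4, 3.5, 5.8, 10.3, 5.4, 7.9, 12.3,
                  2.6, 3.8, 3.6, 3.0, 4.0, 5.3, 4.0, 3.4, 4.6)
  )
  merged <- merge(mt, published,
                  by = c("protocol", "amplitude_mm", "rate_bpm"),
                  suffixes = c("", "_pub"))
  expect_equal(nrow(merged), 18)
  expect_true(all(abs(merged$margin_mm - merged$margin_mm_pub) <= 0.05))
  pm <- attr(mt, "protocol_max")
  expect_equal(unname(pm["slow"]), 5.3)
  expect_equal(unname(pm["standard"]), 12.3)
  # empty input passes through empty
  expect_equal(nrow(margin_table(quasar_phantom_summaries()[0, ])), 0)
})

test_that("reported margins round half-up to 0.1 mm", {
  expect_equal(round_margin(c(2.7734, 10.256, 5.25, 3.4395)),
               c(2.8, 10.3, 5.3, 3.4))
})

test_that("summarize_alignments splits by condition and matches per-cell summaries", {
  rec <- rbind(records_from_errors(c(1, 2, 3), amplitude_mm = 5),
               records_from_errors(c(-2, 2, 4), amplitude_mm = 10),
               records_from_errors(c(0.5, 1.5), protocol = "slow", amplitude_mm = 5))
  sm <- summarize_alignments(rec)
  expect_equal(nrow(sm), 3)
  row <- sm[sm$protocol == "standard" & sm$amplitude_mm == 10, ]
  expect_equal(row$sigma_sys_mm, mean(abs(c(-2, 2, 4))))
  expect_equal(row$sigma_rand_mm, sd(abs(c(-2, 2, 4))))
})
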