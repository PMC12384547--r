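test_that("built-in protocols carry the printed geometry, consistently", {
  std <- standard_protocol()
  slw <- slow_protocol()
  expect_equal(std$rotation_time_s, 0.5)
  expect_equal(std$pitch, 1.75)
  expect_equal(std$scan_time_s, 9.9)
  expect_equal(slw$rotation_time_s, 1)
  expect_equal(slw$pitch, 0.562)
  expect_equal(slw$scan_time_s, 59.5)
  expect_equal(std$slice_thickness_mm, 2.5)
  # scan-time ratio consistent with the pitch/rotation speed ratio
  expect_equal(59.5 / 9.9, (1.75 / 0.5) / (0.562 / 1), tolerance = 0.05)
  expect_gt(std$table_speed_mm_s, 0)
  expect_error(scan_protocol("bad", 0, 1, 10), "positive")
})

test_that("a static sphere is reconstructed at its true position and extent", {
  p <- standard_protocol()
  s <- target_sphere()  # 30 mm sphere
  a <- acquire(p, breathing_waveform(0, 20), s)
  occupied <- sum(a$occupancy > 0)
  expect_true(occupied %in% c(12, 13))  # 30 mm at 2.5 mm slices
  expect_equal(apparent_center(a), s$center_mm)
  expect_equal(apparent_center(a, "area_weighted"), s$center_mm)
  expect_equal(apparent_extent(a), 30, tolerance = 2.5)
})

test_that("apparent_center modes reduce occupancy as midpoint and weighted mean", {
  obj <- structure(list(slice_positions_mm = c(0, 2.5),
                        occupancy = c(1, 1), slice_thickness_mm = 2.5),
                   class = "apparent_object")
  expect_equal(apparent_center(obj, "midpoint"), 1.25)
  obj$occupancy <- c(3, 1)
  expect_equal(apparent_center(obj, "area_weighted"), 0.625)
  obj$occupancy <- c(0, 0)
  expect_error(apparent_center(obj), "not captured")
})

test_that("zero amplitude gives exactly zero error for both protocols at any phase", {
  s <- target_sphere()
  w0 <- breathing_waveform(0, 20)
  for (p in list(standard_protocol(), slow_protocol(),
                 standard_protocol(direction = "feet_to_head"))) {
    for (ph in c(0, 0.7, 2.2)) {
      rec <- alignment_error(p, w0, s, ph, readout_quantum_mm = 0)
      expect_identical(rec$signed_error_mm, 0)
    }
  }
})

test_that("a scan out of reach of the sphere raises target-not-captured", {
  p <- scan_protocol("short", 0.5, 1.75, 1, scan_length_mm = 50)
  expect_error(acquire(p, breathing_waveform(0, 20), target_sphere(30, 100)),
               "scan length")
})

test_that("fast-scan snapshot: apparent object is a displaced near-rigid sphere", {
  # exhale-plateau phase: the sphere is caught at its positive extreme
  p <- standard_protocol()
  s <- target_sphere()
  w <- breathing_waveform(10, 8, shape = "exhale_weighted", n = 2)
  t_cross <- (p$scan_length_mm - s$center_mm) / p$table_speed_mm_s
  # choose phase so the crossing instant sits on the exhale plateau
  ph <- (0.5 * w$period_s - t_cross) %% w$period_s
  rec <- alignment_error(p, w, s, ph, readout_quantum_mm = 0)
  expect_gt(rec$signed_error_mm, 0)
  expect_lte(rec$signed_error_mm, 5)
})

test_that("slow scan blurs the target beyond its physical extent", {
  p <- slow_protocol()
  s <- target_sphere()
  w <- breathing_waveform(15, 28)
  a <- acquire(p, w, s, start_phase_s = 0.4)
  expect_gt(apparent_extent(a), 30)
})

test_that("readout quantization snaps errors to the recorded granularity", {
  p <- standard_protocol()
  s <- target_sphere()
  w <- breathing_waveform(15, 8)
  r1 <- alignment_error(p, w, s, 1.1, readout_quantum_mm = 1)
  expect_equal(r1$signed_error_mm %% 1, 0)
  r0 <- alignment_error(p, w, s, 1.1, readout_quantum_mm = 0)
  expect_lte(abs(r1$signed_error_mm - r0$signed_error_mm), 0.5)
  expect_equal(r1$abs_error_mm, abs(r1$signed_error_mm))
})

test_that("factorial experiment: bookkeeping, alternation, determinism", {
  cfg <- default_run_config(seed = 99)
  rec <- run_phantom_experiment(cfg)
  expect_equal(nrow(rec), 180)  # 2 protocols x 3 amplitudes x 3 rates x 10
  counts <- table(rec$protocol, rec$amplitude_mm, rec$rate_bpm)
  expect_true(all(counts == 10))
  # within every condition, directions alternate and split evenly
  by_cond <- split(rec, interaction(rec$protocol, rec$amplitude_mm, rec$rate_bpm))
  for (b in by_cond) {
    expect_equal(b$direction[order(b$`repeat`)],
                 rep(c("head_to_feet", "feet_to_head"), 5))
  }
  # repeats = 4 alternation rule
  cfg4 <- cfg
  cfg4$repeats <- 4L
  cfg4$amplitudes <- 10
  cfg4$rates <- 20
  cfg4$protocols <- cfg$protocols[1]
  rec4 <- run_phantom_experiment(cfg4)
  expect_equal(rec4$direction,
               c("head_to_feet", "feet_to_head", "head_to_feet", "feet_to_head"))
  # determinism under the same seed
  expect_equal(run_phantom_experiment(cfg), rec)
  # start phases lie within one period
  expect_true(all(rec$start_phase_s >= 0))
  expect_true(all(rec$start_phase_s <= 60 / rec$rate_bpm))
})

test_that("signed error distribution is phase-symmetric for a sinusoid", {
  p <- fast_limit_protocol()
  s <- limit_sphere()
  w <- breathing_waveform(10, 20)
  errs <- mc_mean_abs_error(p, w, s, 3000, seed = 5)
  se <- sd(errs) / sqrt(length(errs))
  expect_lt(abs(mean(errs)), 3 * se)
})
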