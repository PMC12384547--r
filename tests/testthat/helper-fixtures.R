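# shared fixtures for the simulator tests

# a near-instantaneous scan: the snapshot limit of the helical sweep
fast_limit_protocol <- function() {
  scan_protocol("snapshot", rotation_time_s = 0.01, pitch = 1,
                scan_time_s = 0.05, scan_length_mm = 60,
                slice_thickness_mm = 0.5)
}

# a crawl: the sphere crossing spans many breathing periods
slow_limit_protocol <- function() {
  scan_protocol("crawl", rotation_time_s = 1, pitch = 0.5,
                scan_time_s = 120, scan_length_mm = 60,
                slice_thickness_mm = 2.5)
}

limit_sphere <- function() target_sphere(30, 30)

# build an alignment record data.frame from raw signed errors
records_from_errors <- function(errors, protocol = "standard",
                                amplitude_mm = 10, rate_bpm = 20) {
  data.frame(
    protocol = protocol, amplitude_mm = amplitude_mm, rate_bpm = rate_bpm,
    `repeat` = seq_along(errors), direction = "head_to_feet",
    start_phase_s = 0, signed_error_mm = errors, abs_error_mm = abs(errors),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}

# Monte-Carlo mean absolute alignment error over uniform start phases
mc_mean_abs_error <- function(protocol, waveform, sphere, n_phases, seed,
                              centroid_mode = "area_weighted",
                              rotation_supersample = 1L) {
  set.seed(seed)
  phases <- runif(n_phases, 0, waveform$period_s)
  errs <- vapply(phases, function(ph) {
    alignment_error(protocol, waveform, sphere, ph,
                    readout_quantum_mm = 0, centroid_mode = centroid_mode,
                    rotation_supersample = rotation_supersample)$signed_error_mm
  }, numeric(1))
  errs
}
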