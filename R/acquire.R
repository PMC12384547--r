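#' Simulate helical acquisition of a moving sphere
#'
#' The 1-D interplay model. Reconstructed slice centers are laid out at
#' `z = (k - 1/2) * slice_thickness` across the scan length; each slice is
#' acquired at the instant the table sweep reaches it,
#' `t_k = distance from scan start / table speed` (head-to-feet scans start at
#' the cranial end). A slice "sees" the sphere cross-section present at its
#' acquisition instant: the occupancy weight of slice `k` is the
#' cross-sectional area `pi * (r^2 - (z_k - c(t_k))^2)` if the plane cuts the
#' sphere at its displaced center `c(t) = center + displacement(t + phase)`,
#' else 0. Optionally the occupancy is averaged by supersampling over the
#' beam dwell window `rotation_time / pitch` centered on `t_k` — the time a
#' table position stays in the beam, which is what smears each slice over
#' its data-collection interval (a low-pitch slow scan integrates each
#' position over several rotations).
#'
#' Because scanner motion and breathing share the longitudinal axis, the
#' apparent object is a distorted imprint of the sphere: a near-rigid but
#' displaced snapshot when the sweep crosses the sphere quickly (fast
#' standard protocol), or a blurred envelope approaching the full motion
#' extent when the crossing spans many breathing periods (slow protocol).
#'
#' @param protocol a [scan_protocol()].
#' @param waveform a [breathing_waveform()].
#' @param sphere a [target_sphere()].
#' @param start_phase_s additional start-phase offset (s) added to the
#'   waveform's own phase; scans beginning at a random point of the breathing
#'   cycle are modelled by drawing this uniformly over one period.
#' @param rotation_supersample number of time samples across the dwell
#'   window (default 11); 1 disables the temporal smear.
#' @return An object of class `apparent_object`: a list with
#'   `slice_positions_mm`, `occupancy` (cross-sectional-area weights, 0 for
#'   empty slices), `acquisition_times_s`, and the generating geometry.
#' @export
acquire <- function(protocol, waveform, sphere, start_phase_s = 0,
                    rotation_supersample = 11L) {
  stopifnot(inherits(protocol, "scan_protocol"),
            inherits(waveform, "breathing_waveform"),
            inherits(sphere, "target_sphere"))
  r <- sphere$diameter_mm / 2
  half_ptp <- waveform$peak_to_peak_mm / 2
  if (sphere$center_mm - r - half_ptp < 0 ||
      sphere$center_mm + r + half_ptp > protocol$scan_length_mm) {
    stop("sphere motion envelope extends outside the scan length", call. = FALSE)
  }
  n_slices <- floor(protocol$scan_length_mm / protocol$slice_thickness_mm)
  z <- (seq_len(n_slices) - 0.5) * protocol$slice_thickness_mm
  dist_from_start <- if (protocol$direction == "head_to_feet") {
    protocol$scan_length_mm - z
  } else {
    z
  }
  t_k <- dist_from_start / protocol$table_speed_mm_s

  # temporal acquisition window per slice: the beam dwell time at a table
  # position, collimation / table_speed = rotation_time / pitch (a low-pitch
  # slow scan irradiates each position over several rotations)
  window_s <- protocol$rotation_time_s / protocol$pitch
  m <- max(1L, as.integer(rotation_supersample))
  offsets <- if (m == 1L) 0 else
    seq(-window_s / 2, window_s / 2, length.out = m)
  # slices x supersamples matrix of sphere-center positions
  tt <- outer(t_k, offsets, "+")
  ctr <- sphere$center_mm + displacement(waveform, as.vector(tt) + start_phase_s)
  d2 <- (z - matrix(ctr, nrow = n_slices))^2
  occ <- pi * pmax(r^2 - d2, 0)
  occupancy <- if (m == 1L) as.vector(occ) else rowMeans(occ)

  if (!any(occupancy > 0)) {
    stop("target not captured: sphere never intersects an acquisition plane",
         call. = FALSE)
  }
  structure(
    list(
      slice_positions_mm = z,
      occupancy = occupancy,
      acquisition_times_s = t_k,
      slice_thickness_mm = protocol$slice_thickness_mm,
      protocol = protocol$name,
      direction = protocol$direction
    ),
    class = "apparent_object"
  )
}

#' Apparent longitudinal center of an acquired object
#'
#' Reduces the per-slice occupancy to a single longitudinal position, the
#' simulated analog of aligning to the imaged target. Two modes:
#' `"midpoint"` (default) takes the midpoint of the occupied extent,
#' emulating manual centering of the GTV within the iGTV contour;
#' `"area_weighted"` takes the occupancy-weighted centroid, emulating an
#' intensity-centroid registration.
#'
#' @param object an `apparent_object` from [acquire()].
#' @param mode `"midpoint"` or `"area_weighted"`.
#' @return apparent center position (mm).
#' @export
apparent_center <- function(object, mode = c("midpoint", "area_weighted")) {
  stopifnot(inherits(object, "apparent_object"))
  mode <- match.arg(mode)
  occ <- object$occupancy
  z <- object$slice_positions_mm
  keep <- occ > 0
  if (!any(keep)) {
    stop("target not captured: apparent object has no occupied slice",
         call. = FALSE)
  }
  if (mode == "midpoint") {
    (min(z[keep]) + max(z[keep])) / 2
  } else {
    sum(z[keep] * occ[keep]) / sum(occ[keep])
  }
}

#' Occupied longitudinal extent of an acquired object
#'
#' Edge-to-edge length of the occupied slice range (outer slice edges), a
#' measure of how much of the breathing excursion was blurred into the image.
#'
#' @param object an `apparent_object`.
#' @return extent in mm.
#' @export
apparent_extent <- function(object) {
  stopifnot(inherits(object, "apparent_object"))
  keep <- object$occupancy > 0
  if (!any(keep)) return(0)
  z <- object$slice_positions_mm[keep]
  diff(range(z)) + object$slice_thickness_mm
}

#' Longitudinal alignment error of one simulated scan
#'
#' Runs [acquire()] and reports the signed error of the apparent center
#' against the sphere's mean (reference) position — the quantity a therapist
#' reads off when aligning the daily image to the average 4DCT reference.
#' The error is optionally quantized to the couch/manual readout granularity.
#'
#' @inheritParams acquire
#' @param readout_quantum_mm recorded-alignment granularity in mm (default
#'   1, matching millimetre-granular clinical readouts); 0 disables
#'   quantization.
#' @param centroid_mode passed to [apparent_center()].
#' @param amplitude_label,rate_label condition metadata to carry in the
#'   record; default to the waveform's own values.
#' @param repeat_index repeat number within the condition (metadata).
#' @return a one-row data.frame (an alignment record) with columns
#'   `protocol`, `amplitude_mm`, `rate_bpm`, `repeat`, `direction`,
#'   `start_phase_s`, `signed_error_mm`, `abs_error_mm`.
#' @export
alignment_error <- function(protocol, waveform, sphere, start_phase_s = 0,
                            readout_quantum_mm = 1,
                            centroid_mode = c("midpoint", "area_weighted"),
                            rotation_supersample = 11L,
                            repeat_index = 1L,
                            amplitude_label = waveform$amplitude_mm,
                            rate_label = waveform$rate_bpm) {
  centroid_mode <- match.arg(centroid_mode)
  obj <- acquire(protocol, waveform, sphere, start_phase_s,
                 rotation_supersample = rotation_supersample)
  err <- apparent_center(obj, mode = centroid_mode) - sphere$center_mm
  if (readout_quantum_mm > 0) {
    err <- round(err / readout_quantum_mm) * readout_quantum_mm
  }
  data.frame(
    protocol = protocol$name,
    amplitude_mm = amplitude_label,
    rate_bpm = rate_label,
    `repeat` = as.integer(repeat_index),
    direction = protocol$direction,
    start_phase_s = start_phase_s,
    signed_error_mm = err,
    abs_error_mm = abs(err),
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Run the full factorial phantom experiment
#'
#' Simulates the phantom study: every protocol x amplitude x breathing-rate
#' condition, `repeats` scans per condition with the scan direction
#' alternating head-to-feet / feet-to-head on successive repeats and the
#' breathing start phase drawn uniformly over one period from a seeded
#' generator. The default configuration (2 protocols x 3 amplitudes x
#' 3 rates x 10 repeats) yields 180 alignment records.
#'
#' @param config experiment configuration as produced by
#'   [default_run_config()]; any subset of fields may be overridden.
#' @param seed integer seed; overrides `config$seed` when given.
#' @return a data.frame of alignment records (one row per simulated scan)
#'   with attribute `seed`.
#' @export
run_phantom_experiment <- function(config = default_run_config(), seed = NULL) {
  cfg <- validate_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)

  sphere <- target_sphere(cfg$sphere$diameter_mm,
                          cfg$sphere$center_mm %||% cfg$scan_length_mm / 2)
  protos <- lapply(cfg$protocols, function(p) {
    scan_protocol(p$name, p$rotation_time_s, p$pitch, p$scan_time_s,
                  scan_length_mm = cfg$scan_length_mm,
                  slice_thickness_mm = p$slice_thickness_mm %||% 2.5)
  })

  local_rng(cfg$seed)
  out <- vector("list", length(protos) * length(cfg$amplitudes) *
                  length(cfg$rates) * max(cfg$repeats, 0L))
  i <- 0L
  for (p in protos) {
    for (amp in cfg$amplitudes) {
      for (rate in cfg$rates) {
        w <- breathing_waveform(
          amp, rate, shape = cfg$waveform$shape, n = cfg$waveform$n,
          amplitude_convention = cfg$waveform$amplitude_convention
        )
        phases <- stats::runif(cfg$repeats, 0, w$period_s)
        for (k in seq_len(cfg$repeats)) {
          dir_k <- if (k %% 2L == 1L) "head_to_feet" else "feet_to_head"
          pk <- p
          pk$direction <- dir_k
          i <- i + 1L
          out[[i]] <- alignment_error(
            pk, w, sphere, start_phase_s = phases[k],
            readout_quantum_mm = cfg$readout_quantum_mm,
            centroid_mode = cfg$centroid_mode,
            rotation_supersample = cfg$rotation_supersample,
            repeat_index = k
          )
        }
      }
    }
  }
  records <- if (i == 0L) empty_alignment_records() else
    do.call(rbind, out[seq_len(i)])
  rownames(records) <- NULL
  attr(records, "seed") <- cfg$seed
  records
}

empty_alignment_records <- function() {
  data.frame(
    protocol = character(), amplitude_mm = numeric(), rate_bpm = numeric(),
    `repeat` = integer(), direction = character(), start_phase_s = numeric(),
    signed_error_mm = numeric(), abs_error_mm = numeric(),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
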