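#' Helical scan protocol
#'
#' Describes the acquisition geometry and timing of a helical CT protocol.
#' Only the longitudinal table sweep matters for the interplay with breathing
#' motion, so the table speed is derived from the total scan time over the
#' configured scan length rather than from pitch and collimation (collimation
#' is not part of the model). Rotation time and pitch set the per-slice
#' temporal acquisition window (the beam dwell time `rotation_time / pitch`)
#' used to smear each slice over its data-collection interval.
#'
#' @param name protocol label.
#' @param rotation_time_s gantry rotation period (s).
#' @param pitch table advance per rotation / collimation width (dimensionless).
#' @param scan_time_s total time to cover `scan_length_mm` (s).
#' @param scan_length_mm longitudinal coverage (mm).
#' @param slice_thickness_mm reconstructed slice spacing (mm).
#' @param direction `"head_to_feet"` or `"feet_to_head"`. The scan axis is in
#'   mm with positive toward the head; a head-to-feet scan starts at the
#'   cranial end of the scan range.
#' @return An object of class `scan_protocol` with derived field
#'   `table_speed_mm_s = scan_length_mm / scan_time_s`.
#' @seealso [standard_protocol()], [slow_protocol()]
#' @export
scan_protocol <- function(name, rotation_time_s, pitch, scan_time_s,
                          scan_length_mm = 345, slice_thickness_mm = 2.5,
                          direction = c("head_to_feet", "feet_to_head")) {
  direction <- match.arg(direction)
  for (v in list(rotation_time_s = rotation_time_s, pitch = pitch,
                 scan_time_s = scan_time_s, scan_length_mm = scan_length_mm,
                 slice_thickness_mm = slice_thickness_mm)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid protocol: all geometry/timing fields must be single positive values",
           call. = FALSE)
    }
  }
  structure(
    list(
      name = as.character(name),
      rotation_time_s = rotation_time_s,
      pitch = pitch,
      scan_time_s = scan_time_s,
      scan_length_mm = scan_length_mm,
      slice_thickness_mm = slice_thickness_mm,
      table_speed_mm_s = scan_length_mm / scan_time_s,
      direction = direction
    ),
    class = "scan_protocol"
  )
}

#' @export
print.scan_protocol <- function(x, ...) {
  cat(sprintf(
    paste0("Scan protocol '%s': rotation %.3g s, pitch %.3g, scan %.4g mm in ",
           "%.3g s (%.3g mm/s), slices %.3g mm, %s\n"),
    x$name, x$rotation_time_s, x$pitch, x$scan_length_mm, x$scan_time_s,
    x$table_speed_mm_s, x$slice_thickness_mm, gsub("_", "-", x$direction)
  ))
  invisible(x)
}

#' Built-in CT-on-rail protocols
#'
#' The two clinical protocols: the standard diagnostic protocol (rotation
#' 0.5 s, pitch 1.75:1, 9.9 s scan time) and the slow protocol (rotation 1 s,
#' pitch 0.562:1, 59.5 s for the same scan length). The scan-time ratio
#' 59.5/9.9 is consistent with the pitch/rotation ratio
#' (1.75/0.5)/(0.562/1) to within a few percent, as it must be for equal
#' collimation.
#'
#' @param scan_length_mm longitudinal coverage (mm); the default 345 mm is a
#'   typical thoracic range. Only the derived table speed affects the
#'   interplay.
#' @param direction scan direction, see [scan_protocol()].
#' @return a `scan_protocol`.
#' @export
standard_protocol <- function(scan_length_mm = 345,
                              direction = "head_to_feet") {
  scan_protocol("standard", rotation_time_s = 0.5, pitch = 1.75,
                scan_time_s = 9.9, scan_length_mm = scan_length_mm,
                direction = direction)
}

#' @rdname standard_protocol
#' @export
slow_protocol <- function(scan_length_mm = 345,
                          direction = "head_to_feet") {
  scan_protocol("slow", rotation_time_s = 1, pitch = 0.562,
                scan_time_s = 59.5, scan_length_mm = scan_length_mm,
                direction = direction)
}

#' Spherical target
#'
#' The moving target: a sphere of a given diameter whose mean longitudinal
#' position sits at `center_mm` on the scan axis. The phantom's target is a
#' 3 cm sphere; the default center is half the default scan length so that a
#' static sphere is symmetric on the reconstructed slice grid.
#'
#' @param diameter_mm sphere diameter (mm), > 0.
#' @param center_mm mean longitudinal position on the scan axis (mm).
#' @return an object of class `target_sphere`.
#' @export
target_sphere <- function(diameter_mm = 30, center_mm = 172.5) {
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L ||
      !is.finite(diameter_mm) || diameter_mm <= 0) {
    stop("invalid target: 'diameter_mm' must be a single positive value",
         call. = FALSE)
  }
  if (!is.numeric(center_mm) || length(center_mm) != 1L || !is.finite(center_mm)) {
    stop("invalid target: 'center_mm' must be a single finite value", call. = FALSE)
  }
  structure(list(diameter_mm = diameter_mm, center_mm = center_mm),
            class = "target_sphere")
}
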