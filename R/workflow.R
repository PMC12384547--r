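#' Couch shift triplet
#'
#' One alignment's couch shifts in the three cardinal directions.
#'
#' @param lateral_mm,longitudinal_mm,vertical_mm shifts in mm (finite).
#' @return a named numeric vector of class `shift_triplet`.
#' @export
shift_triplet <- function(lateral_mm = 0, longitudinal_mm = 0, vertical_mm = 0) {
  v <- c(lateral_mm = lateral_mm, longitudinal_mm = longitudinal_mm,
         vertical_mm = vertical_mm)
  if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v))) {
    stop("shift triplet components must be finite numbers", call. = FALSE)
  }
  structure(v, class = "shift_triplet")
}

as_shift_triplet <- function(x) {
  if (inherits(x, "shift_triplet")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(shift_triplet(x[1], x[2], x[3]))
  stop("expected a shift_triplet or a length-3 numeric vector", call. = FALSE)
}

#' Image-guidance modality selection
#'
#' Encodes the clinic's selection rule for targets with poor CBCT
#' visibility: CT-on-rail is chosen when the motion amplitude is 5 mm or
#' less, or when it is under 10 mm and the breathing rate is 20 BPM or
#' greater; otherwise the MR linac is chosen. Thresholds are inclusive/strict
#' exactly as stated: amplitude <= 5 inclusive, < 10 strict, rate >= 20
#' inclusive.
#'
#' @param amplitude_mm lesion motion amplitude (mm), >= 0.
#' @param rate_bpm breathing rate (BPM), > 0.
#' @return a list of class `guidance_decision`: `amplitude_mm`, `rate_bpm`,
#'   `modality` (`"CTOR"` or `"MR_Linac"`), `rule` (which branch fired).
#' @examples
#' select_guidance(4, 12)$modality   # "CTOR"  (small motion)
#' select_guidance(8, 22)$modality   # "CTOR"  (moderate motion, fast breathing)
#' select_guidance(12, 25)$modality  # "MR_Linac"
#' @export
select_guidance <- function(amplitude_mm, rate_bpm) {
  if (!is.numeric(amplitude_mm) || amplitude_mm < 0 ||
      !is.numeric(rate_bpm) || rate_bpm <= 0) {
    stop("amplitude must be >= 0 and rate > 0", call. = FALSE)
  }
  if (amplitude_mm <= 5) {
    modality <- "CTOR"; rule <- "amplitude <= 5 mm"
  } else if (amplitude_mm < 10 && rate_bpm >= 20) {
    modality <- "CTOR"; rule <- "amplitude < 10 mm and rate >= 20 BPM"
  } else {
    modality <- "MR_Linac"; rule <- "otherwise"
  }
  structure(list(amplitude_mm = amplitude_mm, rate_bpm = rate_bpm,
                 modality = modality, rule = rule),
            class = "guidance_decision")
}

#' @export
print.guidance_decision <- function(x, ...) {
  cat(sprintf("Guidance: %s for amplitude %g mm at %g BPM (rule: %s)\n",
              x$modality, x$amplitude_mm, x$rate_bpm, x$rule))
  invisible(x)
}

#' Bone-vs-GTV stability check
#'
#' The tumor is deemed stable relative to bony anatomy when the bone-based
#' and soft-tissue (GTV) alignments differ by less than the threshold in
#' every cardinal direction (strict inequality; a 5.0 mm difference triggers
#' re-imaging).
#'
#' @param bone,gtv [shift_triplet()]s (or length-3 numeric vectors) of the
#'   bone-based and GTV-based couch shifts.
#' @param threshold_mm stability threshold (default 5 mm).
#' @return logical.
#' @export
is_stable <- function(bone, gtv, threshold_mm = 5) {
  bone <- as_shift_triplet(bone)
  gtv <- as_shift_triplet(gtv)
  max(abs(unclass(bone) - unclass(gtv))) < threshold_mm
}

#' Re-imaging decision for one guidance session
#'
#' Encodes the first-day imaging procedure. Each image contributes a
#' bone-minus-GTV difference triplet; an image is "stable" when that
#' difference is below 5 mm in every direction.
#' \itemize{
#'   \item Image 1 stable: proceed.
#'   \item Image 1 unstable: a second image is required. With two images,
#'     proceed iff image 2 is stable and the two images' longitudinal
#'     alignments agree within 5 mm; otherwise a third image is required.
#'   \item Image 3 stable: proceed; unstable: escalate (the procedure allows
#'     at most three images).
#' }
#' The final longitudinal alignment value on proceeding depends on the
#' modality: CBCT uses the most recent image's value; CT-on-rail averages
#' over all images (snapshots at random breathing phases average toward the
#' mean target position). The longitudinal component of each difference
#' triplet serves as that image's alignment value.
#'
#' @param diffs a list of 1-3 bone-minus-GTV difference triplets
#'   ([shift_triplet()] or length-3 numeric), in acquisition order; or a
#'   matrix/data.frame with 3 columns (lateral, longitudinal, vertical).
#' @param modality `"CBCT"` or `"CTOR"`.
#' @param threshold_mm stability / consistency threshold (default 5 mm).
#' @return a list of class `imaging_session`: `modality`, `n_images`,
#'   `decision` (`"proceed"`, `"acquire_again"`, `"escalate"`),
#'   `final_longitudinal_mm` (NA unless proceeding), `stable` (per-image
#'   logical).
#' @export
imaging_decision <- function(diffs, modality = c("CBCT", "CTOR"),
                             threshold_mm = 5) {
  modality <- match.arg(modality)
  if (is.matrix(diffs) || is.data.frame(diffs)) {
    diffs <- lapply(seq_len(nrow(diffs)), function(i) as.numeric(diffs[i, 1:3]))
  }
  if (!is.list(diffs) || length(diffs) < 1L) {
    stop("protocol violation: need 1 to 3 images", call. = FALSE)
  }
  if (length(diffs) > 3L) {
    stop("protocol violation: at most 3 images are acquired", call. = FALSE)
  }
  diffs <- lapply(diffs, as_shift_triplet)
  stable <- vapply(diffs, function(d) max(abs(unclass(d))) < threshold_mm,
                   logical(1))
  long_vals <- vapply(diffs, function(d) unclass(d)[["longitudinal_mm"]],
                      numeric(1))
  k <- length(diffs)

  # decision after the last supplied image: image 1 proceeds on its own
  # stability; image 2 proceeds when stable and longitudinally consistent
  # with image 1; image 3 is the last chance and proceeds on stability alone
  decision <- if (k == 1L) {
    if (stable[1]) "proceed" else "acquire_again"
  } else if (k == 2L) {
    if (stable[2] && abs(long_vals[2] - long_vals[1]) < threshold_mm) {
      "proceed"
    } else {
      "acquire_again"
    }
  } else {
    if (stable[3]) "proceed" else "escalate"
  }

  final <- NA_real_
  if (decision == "proceed") {
    final <- if (modality == "CBCT") long_vals[k] else mean(long_vals)
  }
  structure(
    list(modality = modality, n_images = k, decision = decision,
         final_longitudinal_mm = final, stable = stable,
         longitudinal_mm = long_vals, threshold_mm = threshold_mm),
    class = "imaging_session"
  )
}

#' @export
print.imaging_session <- function(x, ...) {
  cat(sprintf("Imaging session (%s, %d image%s): %s",
              x$modality, x$n_images, if (x$n_images > 1) "s" else "",
              x$decision))
  if (!is.na(x$final_longitudinal_mm)) {
    cat(sprintf("; final longitudinal alignment %.2f mm", x$final_longitudinal_mm))
  }
  cat("\n")
  invisible(x)
}

#' Cohort longitudinal drift summary
#'
#' Summarizes the longitudinal bone-minus-GTV systematic differences across
#' all fractions of a patient cohort: the drift of the mean tumor position
#' relative to bony anatomy between simulation and treatment.
#'
#' @param records patient fraction records as from [generate_cohort()] (or
#'   any data.frame with a `diff_long_mm` column, or a numeric vector of
#'   longitudinal differences in mm).
#' @return a list of class `drift_summary` with `mean_mm`, `sd_mm`,
#'   `min_mm`, `max_mm`, `n`, and the same fields in cm (`mean_cm`, ...).
#' @export
cohort_drift_summary <- function(records) {
  x <- if (is.numeric(records)) records
  else if (is.data.frame(records) && "diff_long_mm" %in% names(records))
    records$diff_long_mm
  else stop("expected patient fraction records or a numeric vector", call. = FALSE)
  if (length(x) < 2L) {
    stop("insufficient data: need at least 2 fraction records", call. = FALSE)
  }
  out <- list(mean_mm = mean(x), sd_mm = stats::sd(x),
              min_mm = min(x), max_mm = max(x), n = length(x))
  out[c("mean_cm", "sd_cm", "min_cm", "max_cm")] <-
    lapply(out[c("mean_mm", "sd_mm", "min_mm", "max_mm")], function(v) v / 10)
  structure(out, class = "drift_summary")
}

#' @export
print.drift_summary <- function(x, ...) {
  cat(sprintf(
    "Longitudinal bone-GTV drift over %d fractions: %.2f +/- %.2f mm (range %.2f to %.2f mm)\n",
    x$n, x$mean_mm, x$sd_mm, x$max_mm, x$min_mm))
  invisible(x)
}
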