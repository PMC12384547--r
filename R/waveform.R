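#' Breathing waveform model
#'
#' Constructs a periodic longitudinal tumor-displacement waveform, the motion
#' a respiratory phantom is programmed to perform. Displacements are reported
#' relative to the waveform's time-average position, so the time average over
#' one full breathing period is exactly zero. This makes the mean position the
#' natural alignment reference, standing in for the average-intensity 4DCT
#' image used clinically.
#'
#' Two shapes are available:
#' \describe{
#'   \item{\code{"sinusoid"}}{A pure cosine. Phase 0 places the exhale peak at
#'     \code{t = 0}.}
#'   \item{\code{"exhale_weighted"}}{A \eqn{\cos^{2n}}-type profile
#'     (Lujan-style), \eqn{z(t) = A (c_n - \cos^{2n}(\pi t / T))} with
#'     \eqn{c_n = \binom{2n}{n} / 4^n}, which dwells longer near the flat
#'     exhale top than near the brief inhale trough. Exhale is the positive
#'     (cranial) extreme, matching the convention that the top of the trace is
#'     exhale.}
#' }
#'
#' @param amplitude_mm motion amplitude in mm. Interpreted per
#'   `amplitude_convention`: peak-to-peak excursion (default) or peak
#'   (half-excursion) so that peak-to-peak is twice this value.
#' @param rate_bpm breathing rate in breaths per minute; period is
#'   `60 / rate_bpm` seconds.
#' @param shape `"sinusoid"` or `"exhale_weighted"`.
#' @param n exponent half-order for the exhale-weighted profile (the waveform
#'   is `cos^(2n)`-shaped); ignored for the sinusoid. Default 2.
#' @param phase_s start-phase offset in seconds. Callers that model scans
#'   starting at an arbitrary breath phase should sample this uniformly over
#'   one period.
#' @param amplitude_convention `"peak_to_peak"` (default) or `"peak"`.
#' @return An object of class `breathing_waveform`.
#' @examples
#' w <- breathing_waveform(10, 20)
#' displacement(w, 0)        # exhale peak: +5 mm
#' mean_abs_displacement(w)  # 10 / pi
#' @export
breathing_waveform <- function(amplitude_mm, rate_bpm,
                               shape = c("sinusoid", "exhale_weighted"),
                               n = 2L, phase_s = 0,
                               amplitude_convention = c("peak_to_peak", "peak")) {
  shape <- match.arg(shape)
  amplitude_convention <- match.arg(amplitude_convention)
  if (!is.numeric(amplitude_mm) || length(amplitude_mm) != 1L ||
      !is.finite(amplitude_mm) || amplitude_mm < 0) {
    stop("invalid waveform: 'amplitude_mm' must be a single finite value >= 0",
         call. = FALSE)
  }
  if (!is.numeric(rate_bpm) || length(rate_bpm) != 1L ||
      !is.finite(rate_bpm) || rate_bpm <= 0) {
    stop("invalid waveform: 'rate_bpm' must be a single finite value > 0",
         call. = FALSE)
  }
  if (shape == "exhale_weighted" && (!is.numeric(n) || n < 1 || n != round(n))) {
    stop("invalid waveform: 'n' must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(phase_s) || length(phase_s) != 1L || !is.finite(phase_s)) {
    stop("invalid waveform: 'phase_s' must be a single finite value", call. = FALSE)
  }
  ptp <- if (amplitude_convention == "peak") 2 * amplitude_mm else amplitude_mm
  structure(
    list(
      amplitude_mm = amplitude_mm,
      peak_to_peak_mm = ptp,
      rate_bpm = rate_bpm,
      period_s = 60 / rate_bpm,
      shape = shape,
      n = as.integer(n),
      phase_s = phase_s,
      amplitude_convention = amplitude_convention
    ),
    class = "breathing_waveform"
  )
}

#' @export
print.breathing_waveform <- function(x, ...) {
  shp <- if (x$shape == "exhale_weighted") {
    sprintf("exhale_weighted (cos^%d)", 2L * x$n)
  } else {
    x$shape
  }
  cat(sprintf(
    "Breathing waveform: %s, %.3g mm %s, %.3g BPM (period %.3g s), phase %.3g s\n",
    shp, x$amplitude_mm, gsub("_", "-", x$amplitude_convention),
    x$rate_bpm, x$period_s, x$phase_s
  ))
  invisible(x)
}

# central tendency of cos^(2n) over its period; subtracting it centers the
# exhale-weighted profile at zero time-average
cos2n_mean <- function(n) choose(2L * n, n) / 4^n

#' Longitudinal displacement at time t
#'
#' Evaluates the waveform's displacement about its time-average position.
#' Vectorized over `t`.
#'
#' @param w a [breathing_waveform()].
#' @param t time in seconds (any finite value; the waveform is periodic).
#' @return displacement in mm, bounded by the half-peak-to-peak envelope.
#' @export
displacement <- function(w, t) {
  stopifnot(inherits(w, "breathing_waveform"))
  if (any(!is.finite(t))) stop("'t' must be finite", call. = FALSE)
  tt <- t + w$phase_s
  A <- w$peak_to_peak_mm
  if (A == 0) return(rep(0, length(t)))
  if (w$shape == "sinusoid") {
    (A / 2) * cos(2 * pi * tt / w$period_s)
  } else {
    A * (cos2n_mean(w$n) - cos(pi * tt / w$period_s)^(2L * w$n))
  }
}

#' Time-average of |displacement| over one breathing period
#'
#' Numerically integrates the rectified waveform over one period. For a
#' sinusoid with peak-to-peak excursion A this equals A/pi; it is the
#' expected absolute alignment error in the fast-scan (snapshot) limit of the
#' helical simulator under a uniformly random start phase, which is what makes
#' it a useful closed-form check.
#'
#' @param w a [breathing_waveform()].
#' @param subdivisions number of subdivisions passed to [stats::integrate()].
#' @return mean absolute displacement in mm.
#' @export
mean_abs_displacement <- function(w, subdivisions = 1000L) {
  stopifnot(inherits(w, "breathing_waveform"))
  if (w$peak_to_peak_mm == 0) return(0)
  f <- function(t) abs(displacement(w, t))
  stats::integrate(f, 0, w$period_s, subdivisions = subdivisions,
                   rel.tol = 1e-10)$value / w$period_s
}
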