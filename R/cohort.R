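#' Synthetic patient cohort model
#'
#' Parameterizes a synthetic stand-in for a daily-CBCT thoracic SBRT cohort.
#' The per-fraction longitudinal bone-minus-GTV difference is drawn from a
#' normal distribution whose defaults are the published cohort's observed
#' mean (-1.9 mm) and SD (1.7 mm). Lateral and vertical differences are
#' zero-mean normal nuisance components. Two optional extensions:
#' a patient-level random intercept (off by default; all variance at the
#' fraction level), and a rare outlier component that widens the range
#' toward the extremes seen clinically (off by default, since a pure normal
#' at these parameters will essentially never produce a -11 mm drift).
#'
#' @param n_patients number of patients (default 31).
#' @param fractions_per_patient CBCT fractions per patient (default 4, a
#'   typical SBRT course with daily imaging; the real count per patient is
#'   not fixed).
#' @param mean_long_mm,sd_long_mm longitudinal difference distribution (mm).
#' @param sd_lat_mm,sd_vert_mm SD of the zero-mean lateral/vertical
#'   differences (default 1.5 mm).
#' @param sd_patient_mm SD of the optional patient-level intercept (default
#'   0 = disabled; 1.0 mm is a reasonable hierarchical setting).
#' @param outlier_rate probability a fraction is drawn from the outlier
#'   component (default 0).
#' @param outlier_range_mm range (min, max) of the uniform outlier component
#'   (default the published extremes, -11.4 to +2.8 mm).
#' @param seed integer seed.
#' @return a list of class `cohort_model`.
#' @export
cohort_model <- function(n_patients = 31L, fractions_per_patient = 4L,
                         mean_long_mm = -1.9, sd_long_mm = 1.7,
                         sd_lat_mm = 1.5, sd_vert_mm = 1.5,
                         sd_patient_mm = 0,
                         outlier_rate = 0,
                         outlier_range_mm = c(-11.4, 2.8),
                         seed = 20260101L) {
  if (n_patients < 1L || fractions_per_patient < 1L) {
    stop("config error: need at least 1 patient and 1 fraction", call. = FALSE)
  }
  if (sd_long_mm < 0 || sd_lat_mm < 0 || sd_vert_mm < 0 || sd_patient_mm < 0) {
    stop("config error: SDs must be >= 0", call. = FALSE)
  }
  if (outlier_rate < 0 || outlier_rate > 1) {
    stop("config error: outlier_rate must be in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_patients = as.integer(n_patients),
    fractions_per_patient = as.integer(fractions_per_patient),
    mean_long_mm = mean_long_mm, sd_long_mm = sd_long_mm,
    sd_lat_mm = sd_lat_mm, sd_vert_mm = sd_vert_mm,
    sd_patient_mm = sd_patient_mm,
    outlier_rate = outlier_rate,
    outlier_range_mm = sort(outlier_range_mm),
    seed = as.integer(seed)
  ), class = "cohort_model")
}

#' Generate a synthetic patient cohort
#'
#' Draws per-fraction bone and GTV couch-shift triplets under a
#' [cohort_model()]. Bone shifts are zero by construction (the bone
#' alignment is the reference frame); the GTV shift differs from bone by the
#' drawn difference, so `diff_long_mm = bone - gtv` follows the configured
#' longitudinal distribution. Reproducible under a fixed seed.
#'
#' @param model a [cohort_model()].
#' @param seed optional integer seed overriding `model$seed`.
#' @return a data.frame of patient fraction records: `patient_id`,
#'   `fraction`, `modality` (`"CBCT"`), `bone_lat_mm`, `bone_long_mm`,
#'   `bone_vert_mm`, `gtv_lat_mm`, `gtv_long_mm`, `gtv_vert_mm`,
#'   `diff_long_mm`.
#' @export
generate_cohort <- function(model = cohort_model(), seed = NULL) {
  stopifnot(inherits(model, "cohort_model"))
  if (!is.null(seed)) model$seed <- as.integer(seed)
  local_rng(model$seed)
  n <- model$n_patients * model$fractions_per_patient
  patient <- rep(seq_len(model$n_patients), each = model$fractions_per_patient)
  intercept <- stats::rnorm(model$n_patients, 0, model$sd_patient_mm)[patient]
  d_long <- intercept +
    stats::rnorm(n, model$mean_long_mm, model$sd_long_mm)
  if (model$outlier_rate > 0) {
    is_out <- stats::runif(n) < model$outlier_rate
    d_long[is_out] <- stats::runif(sum(is_out), model$outlier_range_mm[1],
                                   model$outlier_range_mm[2])
  }
  d_lat <- stats::rnorm(n, 0, model$sd_lat_mm)
  d_vert <- stats::rnorm(n, 0, model$sd_vert_mm)
  out <- data.frame(
    patient_id = sprintf("P%03d", patient),
    fraction = rep(seq_len(model$fractions_per_patient), model$n_patients),
    modality = "CBCT",
    bone_lat_mm = 0, bone_long_mm = 0, bone_vert_mm = 0,
    gtv_lat_mm = -d_lat, gtv_long_mm = -d_long, gtv_vert_mm = -d_vert,
    stringsAsFactors = FALSE
  )
  out$diff_long_mm <- out$bone_long_mm - out$gtv_long_mm
  attr(out, "seed") <- model$seed
  attr(out, "model") <- model
  out
}

#' Generate a synthetic phantom alignment dataset
#'
#' Wraps [run_phantom_experiment()] and layers on the measurement chain of a
#' real readout: optional zero-mean Gaussian manual-alignment jitter followed
#' by quantization to the recorded-readout granularity. The underlying
#' simulation runs unquantized so the jitter is applied to the physical
#' error.
#'
#' @param config experiment configuration ([default_run_config()] fields).
#' @param readout_quantum_mm readout granularity applied after jitter
#'   (default 1 mm; 0 disables).
#' @param jitter_sd_mm SD of the manual-alignment jitter (default 0.3 mm).
#' @param seed optional integer seed overriding `config$seed`.
#' @return alignment records as from [run_phantom_experiment()], with
#'   attributes `seed`, `readout_quantum_mm`, `jitter_sd_mm`.
#' @export
generate_phantom_dataset <- function(config = default_run_config(),
                                     readout_quantum_mm = 1,
                                     jitter_sd_mm = 0.3,
                                     seed = NULL) {
  cfg <- validate_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg$readout_quantum_mm <- 0  # quantize after jitter, below
  records <- run_phantom_experiment(cfg)
  local_rng(cfg$seed + 1L)  # independent stream for the measurement chain
  err <- records$signed_error_mm
  if (jitter_sd_mm > 0 && nrow(records) > 0) {
    err <- err + stats::rnorm(nrow(records), 0, jitter_sd_mm)
  }
  if (readout_quantum_mm > 0) {
    err <- round(err / readout_quantum_mm) * readout_quantum_mm
  }
  records$signed_error_mm <- err
  records$abs_error_mm <- abs(err)
  attr(records, "seed") <- cfg$seed
  attr(records, "readout_quantum_mm") <- readout_quantum_mm
  attr(records, "jitter_sd_mm") <- jitter_sd_mm
  records
}
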