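#' Pipeline drivers
#'
#' High-level entry points that chain the package's modules into the standard
#' analyses and write their outputs to disk. Each driver is deterministic
#' given (config, seed), and the CSV/JSON formats are those documented in
#' [write_alignment_csv()], [write_patient_csv()] and [margin_table()]. A
#' thin command-line wrapper over these functions ships at
#' `system.file("cli", "ctinterplay.R", package = "ctinterplay")`.
#'
#' @name pipeline-drivers
NULL

#' @describeIn pipeline-drivers simulate the factorial phantom experiment and
#'   write the alignment CSV. With `repeats = 0` an empty (header-only) CSV
#'   is written with a warning.
#' @param config a run configuration (see [default_run_config()]) or a path
#'   to a YAML config file.
#' @param out output file path.
#' @param seed optional integer seed overriding the config's.
#' @return `cmd_simulate` returns the records invisibly.
#' @export
cmd_simulate <- function(config = default_run_config(), out, seed = NULL) {
  cfg <- load_config(config)
  records <- run_phantom_experiment(cfg, seed = seed)
  if (nrow(records) == 0L) {
    warning("configuration yields no scans (repeats = 0); writing header-only CSV")
  }
  write_alignment_csv(records, out)
  message(sprintf("wrote %d alignment record(s) to %s (seed %d)",
                  nrow(records), out, attr(records, "seed")))
  invisible(records)
}

#' @describeIn pipeline-drivers summarize an alignment CSV into per-condition
#'   systematic/random components and PTV margins; writes a summary CSV and
#'   returns the margin table with the rendered text report as attribute
#'   `report`. Conditions with fewer than 2 records are skipped with a
#'   warning.
#' @param alignment_csv path to an alignment CSV.
#' @param params a [margin_parameters()].
#' @export
cmd_margins <- function(alignment_csv, out = NULL,
                        params = margin_parameters()) {
  records <- read_alignment_csv(alignment_csv)
  key <- interaction(records$protocol, records$amplitude_mm,
                     records$rate_bpm, drop = TRUE)
  parts <- split(records, key)
  small <- vapply(parts, nrow, integer(1)) < 2L
  if (any(small)) {
    warning(sprintf("skipping %d condition(s) with fewer than 2 records",
                    sum(small)))
    parts <- parts[!small]
  }
  if (!length(parts)) stop("no condition has enough records", call. = FALSE)
  summaries <- do.call(rbind, lapply(parts, summarize_condition))
  summaries <- summaries[order(summaries$protocol, summaries$amplitude_mm,
                               summaries$rate_bpm), ]
  rownames(summaries) <- NULL
  mt <- margin_table(summaries, params)
  if (!is.null(out)) utils::write.csv(mt, out, row.names = FALSE)
  attr(mt, "report") <- render_margin_report(mt)
  invisible(mt)
}

#' @describeIn pipeline-drivers Welch standard-vs-slow comparison per
#'   condition from an alignment CSV; writes the results CSV.
#' @param alpha significance level.
#' @export
cmd_stats <- function(alignment_csv, out = NULL, alpha = 0.05) {
  records <- read_alignment_csv(alignment_csv)
  summaries <- summarize_alignments(records)
  cmp <- protocol_comparison(summaries, alpha = alpha)
  if (!is.null(out)) utils::write.csv(cmp, out, row.names = FALSE)
  invisible(cmp)
}

#' @describeIn pipeline-drivers audit a patient CSV: cohort drift summary
#'   (JSON, in mm and cm) plus a per-session imaging decision for each
#'   patient-fraction's difference triplet.
#' @param patient_csv path to a patient fraction CSV.
#' @export
cmd_patient_audit <- function(patient_csv, out = NULL) {
  records <- read_patient_csv(patient_csv)
  summary <- cohort_drift_summary(records)
  decisions <- lapply(seq_len(nrow(records)), function(i) {
    d <- with(records[i, ],
              c(bone_lat_mm - gtv_lat_mm, bone_long_mm - gtv_long_mm,
                bone_vert_mm - gtv_vert_mm))
    s <- imaging_decision(list(d), modality = records$modality[i])
    list(patient_id = records$patient_id[i], fraction = records$fraction[i],
         decision = s$decision,
         final_longitudinal_mm = s$final_longitudinal_mm)
  })
  result <- list(drift = unclass(summary), decisions = decisions)
  if (!is.null(out)) {
    jsonlite::write_json(result, out, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(result)
}

#' @describeIn pipeline-drivers generate a synthetic patient cohort and
#'   write the patient CSV.
#' @param model a [cohort_model()].
#' @export
cmd_generate_cohort <- function(model = cohort_model(), out, seed = NULL) {
  records <- generate_cohort(model, seed = seed)
  write_patient_csv(records, out)
  invisible(records)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    read_run_config(config)
  } else {
    validate_run_config(config)
  }
}
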