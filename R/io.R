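ALIGNMENT_COLS <- c("protocol", "amplitude_mm", "rate_bpm", "repeat",
                    "direction", "start_phase_s", "signed_error_mm",
                    "abs_error_mm")
PATIENT_COLS <- c("patient_id", "fraction", "modality",
                  "bone_lat_mm", "bone_long_mm", "bone_vert_mm",
                  "gtv_lat_mm", "gtv_long_mm", "gtv_vert_mm")

meta_header <- function(records, extra = character()) {
  seed <- attr(records, "seed")
  c(sprintf("# generator: ctinterplay %s",
            as.character(utils::packageVersion("ctinterplay"))),
    if (!is.null(seed)) sprintf("# seed: %d", seed),
    extra)
}

#' Read / write alignment record CSV
#'
#' Alignment records are exchanged as plain CSV with the fixed column set
#' `protocol, amplitude_mm, rate_bpm, repeat, direction, start_phase_s,
#' signed_error_mm, abs_error_mm`, preceded by `#` comment lines embedding
#' the generator version and seed. Reading validates the schema and reports
#' offending columns.
#'
#' @param records alignment records data.frame.
#' @param path file path.
#' @return `read_alignment_csv` returns the records; `write_alignment_csv`
#'   returns `path` invisibly.
#' @export
write_alignment_csv <- function(records, path) {
  check_schema(records, ALIGNMENT_COLS, "alignment")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(records), con)
  utils::write.csv(records[, ALIGNMENT_COLS], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_alignment_csv
#' @export
read_alignment_csv <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  check_schema(out, ALIGNMENT_COLS, "alignment")
  hdr <- readLines(path, n = 10L)
  seed_line <- grep("^# seed:", hdr, value = TRUE)
  if (length(seed_line)) {
    attr(out, "seed") <- as.integer(sub("^# seed:\\s*", "", seed_line[1]))
  }
  out
}

#' Read / write patient fraction record CSV
#'
#' Patient records carry per-fraction bone and GTV shift triplets with the
#' column set `patient_id, fraction, modality, bone_lat_mm, bone_long_mm,
#' bone_vert_mm, gtv_lat_mm, gtv_long_mm, gtv_vert_mm`; the longitudinal
#' bone-minus-GTV difference is (re)derived on read.
#'
#' @param records patient fraction records data.frame.
#' @param path file path.
#' @return `read_patient_csv` returns the records with `diff_long_mm`
#'   recomputed; `write_patient_csv` returns `path` invisibly.
#' @export
write_patient_csv <- function(records, path) {
  check_schema(records, PATIENT_COLS, "patient")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(records), con)
  utils::write.csv(records[, PATIENT_COLS], con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_patient_csv
#' @export
read_patient_csv <- function(path) {
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  check_schema(out, PATIENT_COLS, "patient")
  out$diff_long_mm <- out$bone_long_mm - out$gtv_long_mm
  out
}

check_schema <- function(df, cols, what) {
  if (!is.data.frame(df)) {
    stop(sprintf("schema error: %s records must be a data.frame", what),
         call. = FALSE)
  }
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error: %s records lack column(s): %s",
                 what, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  num_cols <- setdiff(cols, c("protocol", "direction", "patient_id",
                              "modality"))
  for (cc in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad)) {
      stop(sprintf("schema error: %s records, column '%s': non-numeric value at row(s) %s",
                   what, cc, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Render condition summaries and margins as a text report
#'
#' Lays out the per-condition systematic/random components and PTV margins
#' as amplitude rows x breathing-rate columns per protocol, mirroring the
#' clinical summary-table layout (values to 0.1 mm).
#'
#' @param mt a margin table from [margin_table()].
#' @return a character vector of report lines (also printed when
#'   `print = TRUE`).
#' @param print print the report to the console (default FALSE).
#' @export
render_margin_report <- function(mt, print = FALSE) {
  lines <- character()
  rates <- sort(unique(mt$rate_bpm), decreasing = TRUE)
  amps <- sort(unique(mt$amplitude_mm))
  header <- sprintf("%-10s %-10s %s", "Amplitude", "Protocol",
                    paste(sprintf("%8s", paste0(rates, " BPM")), collapse = " "))
  for (block in list(
    list(title = "Systematic (mean |error|) and random (SD) components, mm: mean (SD)",
         fmt = function(r) sprintf("%.1f (%.2f)", r$sigma_sys_mm, r$sigma_rand_mm)),
    list(title = "Estimated PTV margins, mm",
         fmt = function(r) sprintf("%.1f", r$margin_mm))
  )) {
    lines <- c(lines, block$title, header)
    for (a in amps) {
      for (p in unique(mt$protocol)) {
        cells <- vapply(rates, function(rt) {
          row <- mt[mt$amplitude_mm == a & mt$rate_bpm == rt &
                      mt$protocol == p, , drop = FALSE]
          if (nrow(row) == 0) "-" else block$fmt(row)
        }, character(1))
        lines <- c(lines, sprintf("%-10s %-10s %s", paste0(a, " mm"), p,
                                  paste(sprintf("%8s", cells), collapse = " ")))
      }
    }
    lines <- c(lines, "")
  }
  pm <- attr(mt, "protocol_max")
  if (!is.null(pm) && length(pm)) {
    lines <- c(lines, sprintf("Per-protocol maximum margin: %s",
                              paste(sprintf("%s %.1f mm", names(pm), pm),
                                    collapse = ", ")))
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
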