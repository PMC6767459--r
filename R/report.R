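#' Run the full rhythm-analysis chain on an ECG record
#'
#' Composes every analysis stage: the noise-adequation bench, QRS detection,
#' RR-series construction, rhythm warnings (alterations, pauses), segmental
#' atrial-fibrillation screening, time-domain HRV indices, and the averaged
#' beat template. Degenerate records (no detectable beats) produce a report
#' with empty tables rather than an error, so batch analysis never stops on
#' a flatline.
#'
#' @param record An `ecg_tbl` (raw device samples).
#' @param config An [analysis_config()].
#' @return A list of class `rhythm_report` with elements `meta` (fs, length,
#'   stages, subject), `config`, `beats`, `rr`, `alterations`, `pauses`,
#'   `af_segments`, `hrv`, `template`. Use [tidy()][generics::tidy] for a
#'   long warnings table and [glance()][generics::glance] for a one-row
#'   summary.
#' @examples
#' sim <- synth_ecg(synth_spec(duration_s = 90, seed = 3))
#' rep <- analyze_ecg(sim$record)
#' glance(rep)
#' @export
analyze_ecg <- function(record, config = analysis_config()) {
  beats <- detect_beats(record, config)
  filtered <- attr(beats, "filtered")
  empty_hrv <- tibble::tibble(n_intervals = 0L, mean_hr_bpm = NA_real_,
                              sdnn_s = NA_real_, rr_range_s = NA_real_,
                              triangular_index = NA_real_)
  if (nrow(beats) >= 2L) {
    rr <- build_rr(beats, filtered)
    alterations <- detect_rhythm_alterations(rr, config$alteration_frac)
    pauses <- detect_pauses(rr, config$pause_s)
    af_segments <- suppressWarnings(classify_af(rr, config))
    hrv <- if (sum(rr$valid) >= 2L) hrv_indices(rr, config$triangular_bin_s)
           else empty_hrv
    template <- tryCatch(suppressWarnings(beat_template(filtered, beats, config)),
                         error = function(e) NULL)
  } else {
    rr <- NULL
    alterations <- tibble::tibble(interval = integer(), onset_time = numeric(),
                                  rr = numeric(), rr_prev = numeric(),
                                  rel_change = numeric())
    pauses <- tibble::tibble(interval = integer(), onset_time = numeric(),
                             rr = numeric())
    af_segments <- tibble::tibble(segment = integer(), t_start = numeric(),
                                  t_end = numeric(), n_intervals = integer(),
                                  disorganization = numeric(), af = logical())
    hrv <- empty_hrv
    template <- NULL
  }
  structure(list(
    meta = list(fs = ecg_fs(record), n_samples = nrow(record),
                duration_s = nrow(record) / ecg_fs(record),
                subject_id = attr(record, "subject_id", exact = TRUE),
                stages_applied = stages_applied(filtered),
                n_beats = nrow(beats)),
    config = config,
    beats = beats,
    rr = rr,
    alterations = alterations,
    pauses = pauses,
    af_segments = af_segments,
    hrv = hrv,
    template = template
  ), class = "rhythm_report")
}

#' @export
print.rhythm_report <- function(x, ...) {
  cat("<rhythm_report>\n")
  cat(sprintf("  %.1f s record at %g Hz, %d beats detected\n",
              x$meta$duration_s, x$meta$fs, x$meta$n_beats))
  if (is.finite(x$hrv$mean_hr_bpm)) {
    cat(sprintf("  mean HR %.1f bpm, SDNN %.1f ms\n",
                x$hrv$mean_hr_bpm, 1000 * x$hrv$sdnn_s))
  }
  cat(sprintf("  warnings: %d rhythm alteration(s), %d pause(s), %d/%d AF segment(s)\n",
              nrow(x$alterations), nrow(x$pauses),
              sum(x$af_segments$af), nrow(x$af_segments)))
  invisible(x)
}

#' Tidy a rhythm report into a long warnings table
#'
#' @param x A `rhythm_report`.
#' @param ... Unused.
#' @return A tibble with one row per warning: `type` (`"alteration"`,
#'   `"pause"`, `"af_segment"`), `onset_time`, `value` (the triggering RR in
#'   seconds, or the disorganization index for AF segments), `detail`.
#' @export
tidy.rhythm_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(type = rep("alteration", nrow(x$alterations)),
                   onset_time = x$alterations$onset_time,
                   value = x$alterations$rr,
                   detail = sprintf("RR changed %.0f%% vs previous",
                                    100 * x$alterations$rel_change)),
    tibble::tibble(type = rep("pause", nrow(x$pauses)),
                   onset_time = x$pauses$onset_time,
                   value = x$pauses$rr,
                   detail = sprintf("RR = %.2f s", x$pauses$rr)),
    {
      af <- x$af_segments[x$af_segments$af, ]
      tibble::tibble(type = rep("af_segment", nrow(af)),
                     onset_time = af$t_start,
                     value = af$disorganization,
                     detail = sprintf("disorganization %.3f over segment %d",
                                      af$disorganization, af$segment))
    }
  )
}

#' One-row summary of a rhythm report
#'
#' @param x A `rhythm_report`.
#' @param ... Unused.
#' @return One-row tibble: duration, beat count, HRV indices, warning and
#'   AF-segment counts, template contributor count.
#' @export
glance.rhythm_report <- function(x, ...) {
  tibble::tibble(
    duration_s = x$meta$duration_s,
    n_beats = x$meta$n_beats,
    mean_hr_bpm = x$hrv$mean_hr_bpm,
    sdnn_s = x$hrv$sdnn_s,
    rr_range_s = x$hrv$rr_range_s,
    triangular_index = x$hrv$triangular_index,
    n_alterations = nrow(x$alterations),
    n_pauses = nrow(x$pauses),
    n_af_segments = sum(x$af_segments$af),
    n_segments = nrow(x$af_segments),
    template_beats = if (is.null(x$template)) 0L else
      attr(x$template, "n_contributing", exact = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

report_as_list <- function(report) {
  list(
    meta = report$meta[c("fs", "n_samples", "duration_s", "n_beats")],
    hrv = as.list(report$hrv),
    alterations = as.data.frame(report$alterations),
    pauses = as.data.frame(report$pauses),
    af_segments = as.data.frame(report$af_segments),
    beats = list(r_index = report$beats$r_index,
                 n_removed_refractory =
                   attr(report$beats, "n_removed_refractory", exact = TRUE) %||% 0L),
    template = if (is.null(report$template)) NULL else
      list(n_contributing = attr(report$template, "n_contributing", exact = TRUE),
           min_corr = attr(report$template, "min_corr", exact = TRUE),
           time = report$template$time,
           voltage = report$template$voltage)
  )
}

#' Write a rhythm report to disk
#'
#' `format = "json"` writes a machine-readable document containing the
#' warnings, AF verdicts, HRV indices, beat indices and template; `format =
#' "text"` writes the human-readable rendering of [render_report_text()].
#'
#' @param report A `rhythm_report`.
#' @param path Destination file.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown report format",
                                              call. = FALSE))
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), path,
                         auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    writeLines(render_report_text(report), path)
  }
  invisible(path)
}

#' Render a rhythm report as human-readable text
#'
#' @param report A `rhythm_report`.
#' @return Character vector of lines.
#' @export
render_report_text <- function(report) {
  h <- report$hrv
  lines <- c(
    "ECG rhythm analysis report",
    "==========================",
    sprintf("Record: %.1f s at %g Hz (%d samples), %d beats detected",
            report$meta$duration_s, report$meta$fs, report$meta$n_samples,
            report$meta$n_beats),
    "",
    "Heart-rate variability (time domain)",
    sprintf("  mean heart rate:   %s bpm", fmt_num(h$mean_hr_bpm, 1)),
    sprintf("  SDNN:              %s ms", fmt_num(1000 * h$sdnn_s, 1)),
    sprintf("  max-min RR:        %s ms", fmt_num(1000 * h$rr_range_s, 0)),
    sprintf("  triangular index:  %s", fmt_num(h$triangular_index, 2)),
    "",
    sprintf("Rhythm alterations (>%d%% RR change): %d",
            round(100 * report$config$alteration_frac),
            nrow(report$alterations))
  )
  if (nrow(report$alterations)) {
    lines <- c(lines, sprintf("  at %.1f s: RR %.2f s after %.2f s (%.0f%%)",
                              report$alterations$onset_time,
                              report$alterations$rr,
                              report$alterations$rr_prev,
                              100 * report$alterations$rel_change))
  }
  lines <- c(lines,
             sprintf("Pauses (RR > %g s): %d", report$config$pause_s,
                     nrow(report$pauses)))
  if (nrow(report$pauses)) {
    lines <- c(lines, sprintf("  at %.1f s: RR = %.2f s",
                              report$pauses$onset_time, report$pauses$rr))
  }
  lines <- c(lines,
             sprintf("AF screening (%g s segments, index > %.3f): %d of %d flagged",
                     report$config$af_segment_s, report$config$af_threshold,
                     sum(report$af_segments$af), nrow(report$af_segments)))
  if (nrow(report$af_segments)) {
    lines <- c(lines,
               sprintf("  segment %d [%5.0f-%5.0f s]: index %s%s",
                       report$af_segments$segment,
                       report$af_segments$t_start, report$af_segments$t_end,
                       fmt_num(report$af_segments$disorganization, 4),
                       ifelse(report$af_segments$af, "  ** AF suspected **", "")))
  }
  if (!is.null(report$template)) {
    lines <- c(lines, "",
               sprintf("Beat template: %d contributing beats, min correlation %s",
                       attr(report$template, "n_contributing", exact = TRUE),
                       fmt_num(attr(report$template, "min_corr", exact = TRUE), 4)))
  }
  lines
}

fmt_num <- function(x, digits) {
  ifelse(is.finite(x), formatC(x, format = "f", digits = digits), "n/a")
}

#' Write a beat template as CSV
#'
#' Two columns: `time` (seconds relative to the R wave) and `voltage` (mV).
#'
#' @param template A `beat_template`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_template_csv <- function(template, path) {
  utils::write.csv(template[, c("time", "voltage")], path, row.names = FALSE)
  invisible(path)
}
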