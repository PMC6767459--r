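#' Construct a single-lead ECG record
#'
#' An `ecg_tbl` is a tibble with one row per sample and columns `time`
#' (seconds from record start), `voltage` (millivolts) and `valid` (logical;
#' set to `FALSE` by the large-amplitude-noise stage where a block has been
#' excised). The sampling rate and acquisition metadata travel as attributes
#' so the record can be piped through `dplyr` verbs that preserve attributes.
#'
#' Portable single-lead devices expose several electrode configurations
#' (two embedded dry electrodes, two wired electrodes, or a two-by-two mix);
#' all are treated as a single analysis channel, so `lead_mode` is metadata
#' only.
#'
#' @param voltage Numeric vector of sampled voltages, in millivolts.
#' @param fs Sampling rate in Hz. Must be positive. Portable devices rarely
#'   embed the rate in their CSV export, so it is always an explicit input;
#'   250 Hz is the package-wide default for synthetic data.
#' @param start_time Optional `POSIXct` timestamp of the first sample.
#' @param lead_mode One of `"embedded_2"`, `"wired_2"`, `"two_by_two"`.
#' @param subject_id Opaque subject identifier string.
#' @param notes Free-text notes (e.g. the symptom description attached to an
#'   exceptional measurement).
#'
#' @return A tibble of class `ecg_tbl` with columns `time`, `voltage`,
#'   `valid`, and attributes `fs`, `lead_mode`, `subject_id`, `notes`,
#'   `start_time`, `stages_applied`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * seq(0, 1, by = 1 / 250)), fs = 250)
#' ecg_fs(rec)
#' @export
ecg_record <- function(voltage, fs,
                       start_time = NULL,
                       lead_mode = c("embedded_2", "wired_2", "two_by_two"),
                       subject_id = NA_character_,
                       notes = NA_character_) {
  lead_mode <- match.arg(lead_mode)
  voltage <- as.numeric(voltage)
  if (length(voltage) < 1L) {
    stop("ECG record must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(voltage))) {
    stop("all ECG samples must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  out <- tibble::tibble(
    time = (seq_along(voltage) - 1) / fs,
    voltage = voltage,
    valid = TRUE
  )
  new_ecg_tbl(out, fs = fs, lead_mode = lead_mode, subject_id = subject_id,
              notes = notes, start_time = start_time,
              stages_applied = character())
}

new_ecg_tbl <- function(x, fs, lead_mode = "embedded_2",
                        subject_id = NA_character_, notes = NA_character_,
                        start_time = NULL, stages_applied = character()) {
  attr(x, "fs") <- fs
  attr(x, "lead_mode") <- lead_mode
  attr(x, "subject_id") <- subject_id
  attr(x, "notes") <- notes
  attr(x, "start_time") <- start_time
  attr(x, "stages_applied") <- stages_applied
  class(x) <- unique(c("ecg_tbl", class(tibble::tibble())))
  x
}

#' @rdname ecg_record
#' @param x An `ecg_tbl`.
#' @export
ecg_fs <- function(x) {
  fs <- attr(x, "fs", exact = TRUE)
  if (is.null(fs)) stop("object carries no `fs` attribute; is it an `ecg_tbl`?",
                        call. = FALSE)
  fs
}

#' @rdname ecg_record
#' @export
stages_applied <- function(x) attr(x, "stages_applied", exact = TRUE) %||% character()

`%||%` <- function(a, b) if (is.null(a)) b else a

with_stage <- function(x, stage) {
  attr(x, "stages_applied") <- c(stages_applied(x), stage)
  x
}

#' Record an arterial blood-pressure measurement
#'
#' Cuff ABP values are carried through the analysis as metadata only; no
#' waveform processing is attached to them.
#'
#' @param systolic,diastolic Pressures in mmHg; must satisfy
#'   `systolic > diastolic > 0`.
#' @param timestamp Optional measurement time.
#' @return A one-row tibble with columns `systolic`, `diastolic`, `timestamp`.
#' @export
abp_measurement <- function(systolic, diastolic, timestamp = NA) {
  if (!(is.finite(systolic) && is.finite(diastolic) &&
        systolic > diastolic && diastolic > 0)) {
    stop("ABP requires systolic > diastolic > 0 (mmHg)", call. = FALSE)
  }
  tibble::tibble(systolic = systolic, diastolic = diastolic,
                 timestamp = timestamp)
}

#' Read a single-lead ECG from a one-column CSV file
#'
#' The companion-device export format is one voltage sample per row
#' (millivolts), dot decimal separator, with an optional single header row.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz (not stored in the file; must be supplied).
#' @inheritParams ecg_record
#' @return An [ecg_record()] tibble with one row per data row of the file.
#' @seealso [write_ecg_csv()] for the inverse, which round-trips to full
#'   double precision.
#' @export
read_ecg_csv <- function(path, fs,
                         lead_mode = c("embedded_2", "wired_2", "two_by_two"),
                         subject_id = NA_character_,
                         notes = NA_character_) {
  lead_mode <- match.arg(lead_mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines only; blank interior lines are malformed rows
  while (length(lines) > 0 && grepl("^\\s*$", lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0L) stop("empty ECG file: ", path, call. = FALSE)
  first <- suppressWarnings(as.numeric(lines[1L]))
  has_header <- is.na(first)
  data_lines <- if (has_header) lines[-1L] else lines
  row_offset <- if (has_header) 1L else 0L
  if (length(data_lines) == 0L) {
    stop("empty ECG file (header only): ", path, call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(data_lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L] + row_offset
    stop("cannot parse voltage on row ", bad, " of ", path, call. = FALSE)
  }
  ecg_record(vals, fs = fs, lead_mode = lead_mode,
             subject_id = subject_id, notes = notes)
}

#' Write a single-lead ECG to a one-column CSV file
#'
#' Values are written with 17 significant digits so that
#' `read_ecg_csv(write_ecg_csv(x))` reproduces the record exactly.
#'
#' @param record An `ecg_tbl`.
#' @param path Destination path.
#' @param header Write a `voltage` header row? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path, header = TRUE) {
  if (nrow(record) == 0L) stop("nothing to write: record has no samples",
                               call. = FALSE)
  lines <- sprintf("%.17g", record$voltage)
  if (header) lines <- c("voltage", lines)
  tryCatch(writeLines(lines, path),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles every tunable constant of the analysis chain. Defaults follow the
#' platform's published operating points: 75 Hz low-pass, 50 Hz notch
#' (Spanish powerline), 0.5 s large-amplitude-noise blocks judged against the
#' ten previous blocks at mean + 2 sd, a 30% rhythm-alteration threshold, a
#' 3 s pause threshold, 75 s atrial-fibrillation segments, and the 40%/60%
#' beat split with a 10% QRS window gated at 99.5% correlation.
#'
#' Quantities not fixed by the platform description are package choices,
#' exposed here: the spline knot spacing (1 s), zone threshold multiplier
#' (mean + 1 sd of the feature signal), 0.2 s refractory period, 30x30
#' Poincare bins over fixed physiologic ranges, the "full bin" occupancy
#' (>= 1 point) and the AF decision threshold on the disorganization index,
#' derived once from the synthetic-rhythm suite (see the package vignette).
#'
#' @param ... Named overrides of any listed default. Unknown names are an
#'   error.
#' @return A named list of class `ecg_config`.
#' @examples
#' cfg <- analysis_config(af_bins_per_axis = 20)
#' cfg$notch_hz
#' @export
analysis_config <- function(...) {
  defaults <- list(
    lowpass_cutoff_hz = 75,
    notch_hz = 50,
    notch_q = 30,
    spline_knot_s = 1.0,
    lan_block_s = 0.5,
    lan_history_blocks = 10L,
    lan_k_sigma = 2,
    zone_threshold_c = 1.0,
    refractory_s = 0.2,
    alteration_frac = 0.30,
    pause_s = 3.0,
    af_segment_s = 75,
    af_bins_per_axis = 30L,
    af_full_bin_min_count = 1L,
    af_threshold = 0.0406,
    fence_multiplier = 3,
    fence_rule = "corrected",       # "corrected" two-sided or "literal" upper-only
    poincare_rr_range = c(0.24, 2.0),
    poincare_drr_range = c(-0.88, 0.88),
    template_pre_frac = 0.40,
    template_post_frac = 0.60,
    template_window_frac = 0.10,
    template_corr_min = 0.995,
    template_reference = "median",  # or "pairwise_mean"
    triangular_bin_s = 1 / 128
  )
  overrides <- list(...)
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == "")) {
      stop("all configuration overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    defaults[nm] <- overrides
  }
  if (!defaults$fence_rule %in% c("corrected", "literal")) {
    stop("`fence_rule` must be \"corrected\" or \"literal\"", call. = FALSE)
  }
  if (!defaults$template_reference %in% c("median", "pairwise_mean")) {
    stop("`template_reference` must be \"median\" or \"pairwise_mean\"",
         call. = FALSE)
  }
  structure(defaults, class = "ecg_config")
}

#' @export
print.ecg_config <- function(x, ...) {
  cat("<ecg_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
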