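#' Split the filtered ECG into per-beat windows
#'
#' Each detected beat is cut into a window covering one cardiac cycle: 40%
#' of the cycle before the R wave and 60% after (defaults). The cycle length
#' is the global mean RR of the record's valid intervals, so all windows
#' share one length and can be averaged sample-wise. Beats whose window runs
#' past the record bounds or touches masked samples are dropped, never
#' padded.
#'
#' @param signal The filtered `ecg_tbl`.
#' @param beats A `beat_tbl`.
#' @param pre_frac,post_frac Fractions of the cycle before/after the R wave.
#' @return A tibble of class `beat_windows`, long format: `beat`, `pos`
#'   (1..window length), `voltage`; attributes `fs`, `pre_n`, `post_n`,
#'   `cycle_s` (the R wave sits at `pos = pre_n + 1`).
#' @export
segment_beats <- function(signal, beats, pre_frac = 0.40, post_frac = 0.60) {
  if (nrow(beats) < 2L) {
    stop("at least 2 beats are required to define a cycle length",
         call. = FALSE)
  }
  fs <- attr(beats, "fs", exact = TRUE)
  rr <- build_rr(beats, signal)
  cycle <- mean(rr$rr[rr$valid])
  if (!is.finite(cycle)) cycle <- mean(rr$rr)
  pre_n <- as.integer(round(pre_frac * cycle * fs))
  post_n <- as.integer(round(post_frac * cycle * fs))
  n <- nrow(signal)
  wins <- lapply(seq_len(nrow(beats)), function(i) {
    r <- beats$r_index[i]
    lo <- r - pre_n
    hi <- r + post_n - 1L
    if (lo < 1L || hi > n) return(NULL)
    if (!all(signal$valid[lo:hi])) return(NULL)
    tibble::tibble(beat = beats$beat[i], pos = seq_len(pre_n + post_n),
                   voltage = signal$voltage[lo:hi])
  })
  out <- dplyr::bind_rows(wins)
  if (nrow(out) == 0L) stop("no beat window fits inside the record",
                            call. = FALSE)
  attr(out, "fs") <- fs
  attr(out, "pre_n") <- pre_n
  attr(out, "post_n") <- post_n
  attr(out, "cycle_s") <- cycle
  class(out) <- unique(c("beat_windows", class(out)))
  out
}

#' Gate beats by QRS-segment correlation
#'
#' A window of 10% of the cycle duration is centred on each R wave, cutting
#' out the QRS segment; each segment's Pearson correlation coefficient
#' against a reference QRS is computed, and only beats correlating strictly
#' above `corr_min` (99.5% default) are accepted for averaging. The
#' reference is the pointwise *median* QRS segment across beats, which is
#' robust to a minority of ectopic or corrupted beats; `reference =
#' "pairwise_mean"` instead scores each beat by its mean pairwise
#' correlation with every other beat.
#'
#' If fewer than 2 beats pass the gate, the single best-correlated beat is
#' kept with a warning, so a template is still produced.
#'
#' @param windows A `beat_windows` tibble from [segment_beats()].
#' @param window_frac QRS window as a fraction of the cycle.
#' @param corr_min Acceptance threshold on the correlation coefficient.
#' @param reference `"median"` (default) or `"pairwise_mean"`.
#' @return The accepted subset of `windows`; per-beat correlations in
#'   `attr(, "correlations")` (named by beat).
#' @export
qrs_correlation_gate <- function(windows, window_frac = 0.10,
                                 corr_min = 0.995,
                                 reference = c("median", "pairwise_mean")) {
  reference <- match.arg(reference)
  fs <- attr(windows, "fs", exact = TRUE)
  pre_n <- attr(windows, "pre_n", exact = TRUE)
  cycle <- attr(windows, "cycle_s", exact = TRUE)
  beats <- unique(windows$beat)
  if (length(beats) < 2L) {
    stop("at least 2 beat windows are required for correlation gating",
         call. = FALSE)
  }
  half <- max(1L, as.integer(round(window_frac * cycle * fs / 2)))
  qrs_pos <- (pre_n + 1L - half):(pre_n + 1L + half)
  seg_mat <- vapply(beats, function(b) {
    windows$voltage[windows$beat == b][qrs_pos]
  }, numeric(length(qrs_pos)))
  corr <- if (reference == "median") {
    ref <- apply(seg_mat, 1L, median)
    apply(seg_mat, 2L, safe_cor, y = ref)
  } else {
    cm <- suppressWarnings(cor(seg_mat))
    diag(cm) <- NA
    rowMeans(cm, na.rm = TRUE)
  }
  names(corr) <- beats
  accepted <- beats[!is.na(corr) & corr > corr_min]
  if (length(accepted) < 2L) {
    warning("fewer than 2 beats passed the ", corr_min * 100,
            "% correlation gate; keeping the single best beat", call. = FALSE)
    accepted <- beats[which.max(corr)]
  }
  out <- windows[windows$beat %in% accepted, ]
  for (a in c("fs", "pre_n", "post_n", "cycle_s")) {
    attr(out, a) <- attr(windows, a, exact = TRUE)
  }
  attr(out, "correlations") <- corr
  class(out) <- unique(c("beat_windows", class(out)))
  out
}

# Pearson correlation that tolerates zero-variance segments
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(if (isTRUE(all.equal(x, y))) 1 else 0)
  }
  cor(x, y)
}

#' Average accepted beats into a low-noise template
#'
#' The template is the pointwise mean across accepted windows. Averaging N
#' beats carrying independent noise of standard deviation sigma leaves
#' residual noise of about sigma/sqrt(N), giving a clean single-cycle
#' waveform a clinician can inspect for morphology.
#'
#' @param windows Accepted `beat_windows` (from [qrs_correlation_gate()]).
#' @return A tibble of class `beat_template` with columns `pos`, `time`
#'   (seconds relative to the R wave), `voltage`; attributes `fs`,
#'   `n_contributing`, `contributing_beats`, `min_corr` (minimum correlation
#'   among contributors, when known).
#' @export
average_template <- function(windows) {
  if (nrow(windows) == 0L) stop("no accepted windows to average", call. = FALSE)
  fs <- attr(windows, "fs", exact = TRUE)
  pre_n <- attr(windows, "pre_n", exact = TRUE)
  avg <- windows |>
    dplyr::group_by(.data$pos) |>
    dplyr::summarise(voltage = mean(.data$voltage), .groups = "drop")
  beats <- unique(windows$beat)
  corr <- attr(windows, "correlations", exact = TRUE)
  out <- tibble::tibble(
    pos = avg$pos,
    time = (avg$pos - pre_n - 1L) / fs,
    voltage = avg$voltage
  )
  attr(out, "fs") <- fs
  attr(out, "n_contributing") <- length(beats)
  attr(out, "contributing_beats") <- beats
  attr(out, "min_corr") <- if (is.null(corr)) NA_real_ else
    min(corr[as.character(beats)])
  class(out) <- unique(c("beat_template", class(out)))
  out
}

#' Build the averaged beat template for a record
#'
#' Convenience composition of [segment_beats()], [qrs_correlation_gate()]
#' and [average_template()] with parameters from [analysis_config()].
#'
#' @param signal Filtered `ecg_tbl`.
#' @param beats A `beat_tbl`.
#' @param config An [analysis_config()].
#' @return A `beat_template` tibble.
#' @export
beat_template <- function(signal, beats, config = analysis_config()) {
  segment_beats(signal, beats,
                config$template_pre_frac, config$template_post_frac) |>
    qrs_correlation_gate(config$template_window_frac,
                         config$template_corr_min,
                         config$template_reference) |>
    average_template()
}
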