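#' Build the RR-interval series from beat annotations
#'
#' RR[n] is the spacing between consecutive detected R waves, in seconds;
#' dRR[n] = RR[n] - RR[n-1] is its first difference (undefined for the first
#' interval). Intervals that span any masked (large-amplitude-noise) samples
#' are marked invalid and excluded from downstream statistics, since beats
#' inside an excised block may have been missed.
#'
#' @param beats A `beat_tbl` from [detect_beats()].
#' @param signal Optional filtered `ecg_tbl` whose `valid` mask is consulted;
#'   defaults to the record attached to `beats` by [detect_beats()].
#' @return A tibble of class `rr_tbl` with columns `interval`, `onset_time`
#'   (seconds, time of the interval's opening beat), `rr`, `drr`, `valid`,
#'   `outlier` (initialised `FALSE`; see [fence_outliers()]); attribute `fs`.
#' @export
build_rr <- function(beats, signal = attr(beats, "filtered")) {
  if (nrow(beats) < 2L) {
    stop("at least 2 beats are required to form RR intervals", call. = FALSE)
  }
  fs <- attr(beats, "fs", exact = TRUE)
  rr <- diff(beats$r_index) / fs
  valid <- rep(TRUE, length(rr))
  if (!is.null(signal)) {
    for (i in seq_along(rr)) {
      span <- beats$r_index[i]:beats$r_index[i + 1L]
      if (!all(signal$valid[span])) valid[i] <- FALSE
    }
  }
  out <- tibble::tibble(
    interval = seq_along(rr),
    onset_time = beats$time[-length(beats$time)],
    rr = rr,
    drr = c(NA_real_, diff(rr)),
    valid = valid,
    outlier = FALSE
  )
  attr(out, "fs") <- fs
  class(out) <- unique(c("rr_tbl", class(out)))
  out
}

#' Flag rhythm alterations
#'
#' A rhythm alteration is an RR interval differing from its predecessor by
#' strictly more than `alteration_frac` (default 30%) of the predecessor.
#'
#' @param rr An `rr_tbl`.
#' @param alteration_frac Relative-change threshold.
#' @return Tibble with one row per alteration: `interval`, `onset_time`,
#'   `rr`, `rr_prev`, `rel_change`.
#' @export
detect_rhythm_alterations <- function(rr, alteration_frac = 0.30) {
  empty <- tibble::tibble(interval = integer(), onset_time = numeric(),
                          rr = numeric(), rr_prev = numeric(),
                          rel_change = numeric())
  if (nrow(rr) < 2L) return(empty)
  cur <- rr[-1L, ]
  prev_rr <- rr$rr[-nrow(rr)]
  prev_ok <- rr$valid[-nrow(rr)]
  rel <- abs(cur$rr - prev_rr) / prev_rr
  hit <- rel > alteration_frac & cur$valid & prev_ok
  tibble::tibble(
    interval = cur$interval[hit],
    onset_time = cur$onset_time[hit],
    rr = cur$rr[hit],
    rr_prev = prev_rr[hit],
    rel_change = rel[hit]
  )
}

#' Flag pauses
#'
#' A pause is an RR interval strictly longer than `pause_s` seconds
#' (default 3 s).
#'
#' @param rr An `rr_tbl`.
#' @param pause_s Pause threshold, seconds.
#' @return Tibble with one row per pause: `interval`, `onset_time`, `rr`.
#' @export
detect_pauses <- function(rr, pause_s = 3.0) {
  hit <- rr$rr > pause_s & rr$valid
  tibble::tibble(interval = rr$interval[hit],
                 onset_time = rr$onset_time[hit],
                 rr = rr$rr[hit])
}

#' Fence RR outliers by interquartile range
#'
#' Before the Poincare diagram is built, the RR series is denoised by
#' removing outliers. The default ("corrected") rule is the standard
#' two-sided fence on each axis: an interval is an outlier when its RR value
#' lies outside `[P25 - m*IQR, P75 + m*IQR]` of the RR series, or its dRR
#' value lies outside the analogous dRR fence (m = 3 by default). Boundary
#' values are not outliers, which also handles the degenerate IQR = 0 case
#' of an all-identical series.
#'
#' `rule = "literal"` keeps only the upper fence on each axis (the
#' conjunction of two lower-bound/upper-bound ">" conditions collapses to
#' the upper bound); it is provided for fidelity comparisons only.
#'
#' Fewer than 4 valid intervals leave the series unfenced (percentiles are
#' not meaningful), with a message.
#'
#' @param rr An `rr_tbl`.
#' @param multiplier Fence half-width in IQR units.
#' @param rule `"corrected"` (two-sided, default) or `"literal"`.
#' @return The `rr_tbl` with its `outlier` column set; the fences are
#'   attached as `attr(, "fences")` (p25/p75/iqr per axis).
#' @export
fence_outliers <- function(rr, multiplier = 3,
                           rule = c("corrected", "literal")) {
  rule <- match.arg(rule)
  ok <- rr$valid
  if (sum(ok) < 4L) {
    message("fewer than 4 valid intervals; outlier fencing skipped")
    rr$outlier <- FALSE
    attr(rr, "fences") <- NULL
    return(rr)
  }
  q_rr <- quantile(rr$rr[ok], c(0.25, 0.75), names = FALSE)
  drr_ok <- rr$drr[ok & !is.na(rr$drr)]
  q_drr <- quantile(drr_ok, c(0.25, 0.75), names = FALSE)
  iqr_rr <- q_rr[2L] - q_rr[1L]
  iqr_drr <- q_drr[2L] - q_drr[1L]
  lo_rr <- q_rr[1L] - multiplier * iqr_rr
  hi_rr <- q_rr[2L] + multiplier * iqr_rr
  lo_drr <- q_drr[1L] - multiplier * iqr_drr
  hi_drr <- q_drr[2L] + multiplier * iqr_drr
  if (rule == "corrected") {
    o1 <- rr$rr < lo_rr | rr$rr > hi_rr
    o2 <- !is.na(rr$drr) & (rr$drr < lo_drr | rr$drr > hi_drr)
  } else {
    o1 <- rr$rr > lo_rr & rr$rr > hi_rr
    o2 <- !is.na(rr$drr) & rr$drr > lo_drr & rr$drr > hi_drr
  }
  rr$outlier <- (o1 | o2) & rr$valid
  attr(rr, "fences") <- list(
    p25_rr = q_rr[1L], p75_rr = q_rr[2L], iqr_rr = iqr_rr,
    p25_drr = q_drr[1L], p75_drr = q_drr[2L], iqr_drr = iqr_drr
  )
  rr
}

#' Discretized Lorenz-Poincare diagram of the RR series
#'
#' The diagram plots each interval's RR value (abscissa) against its first
#' difference dRR (ordinate), then overlays a grid of equally sized bins and
#' counts the points in each bin. Points come from valid, non-outlier
#' intervals with a defined dRR. Bin edges span *fixed* physiologic ranges —
#' not the data range — so occupancy is comparable across segments and a
#' perfectly regular rhythm occupies exactly one bin rather than spuriously
#' filling an auto-scaled grid; points beyond a range are counted in the
#' nearest edge bin so every plotted point lands in exactly one bin.
#'
#' @param rr An `rr_tbl`, typically after [fence_outliers()].
#' @param bins_per_axis Number of bins per axis.
#' @param rr_range,drr_range Axis ranges, seconds.
#' @return A tibble of class `poincare_grid` with one row per *occupied* bin
#'   (`bin_rr`, `bin_drr`, `count`, bin-centre columns `rr_mid`, `drr_mid`);
#'   attributes `bins_per_axis`, `n_points`, `rr_range`, `drr_range`.
#' @export
poincare_grid <- function(rr, bins_per_axis = 30L,
                          rr_range = c(0.24, 2.0),
                          drr_range = c(-0.88, 0.88)) {
  pts <- rr[rr$valid & !rr$outlier & !is.na(rr$drr), ]
  if (nrow(pts) < 1L) {
    stop("no plottable (valid, non-outlier) RR points", call. = FALSE)
  }
  bin_of <- function(v, range, nb) {
    w <- (range[2L] - range[1L]) / nb
    pmin(nb, pmax(1L, floor((v - range[1L]) / w) + 1L))
  }
  bx <- bin_of(pts$rr, rr_range, bins_per_axis)
  by <- bin_of(pts$drr, drr_range, bins_per_axis)
  counts <- dplyr::count(tibble::tibble(bin_rr = bx, bin_drr = by),
                         .data$bin_rr, .data$bin_drr, name = "count")
  w_rr <- (rr_range[2L] - rr_range[1L]) / bins_per_axis
  w_drr <- (drr_range[2L] - drr_range[1L]) / bins_per_axis
  out <- dplyr::mutate(counts,
                       rr_mid = rr_range[1L] + (.data$bin_rr - 0.5) * w_rr,
                       drr_mid = drr_range[1L] + (.data$bin_drr - 0.5) * w_drr)
  attr(out, "bins_per_axis") <- as.integer(bins_per_axis)
  attr(out, "n_points") <- nrow(pts)
  attr(out, "rr_range") <- rr_range
  attr(out, "drr_range") <- drr_range
  class(out) <- unique(c("poincare_grid", class(out)))
  out
}

#' Poincare disorganization index
#'
#' The fraction of grid bins that are "full" (occupancy at least
#' `full_bin_min_count`, default 1). A metronomic rhythm concentrates all
#' points in one bin (index 1/bins^2); the irregularly irregular RR dynamics
#' of atrial fibrillation scatter points across the plane, raising the
#' index. Always in [0, 1] and non-decreasing in the number of occupied bins.
#'
#' @param grid A `poincare_grid`.
#' @param full_bin_min_count Minimum occupancy for a bin to count as full.
#' @return A single number in `[0, 1]`.
#' @export
disorganization_index <- function(grid, full_bin_min_count = 1L) {
  nb <- attr(grid, "bins_per_axis", exact = TRUE)
  sum(grid$count >= full_bin_min_count) / (nb * nb)
}

#' Screen consecutive segments for atrial fibrillation
#'
#' The RR stream is split into consecutive non-overlapping segments of
#' `af_segment_s` seconds (75 s default — the published operating segment
#' length). Each segment is outlier-fenced, discretized on the Poincare
#' grid, and scored with the disorganization index; a segment is flagged AF
#' when its index strictly exceeds `af_threshold`. A trailing partial
#' segment is analysed only when it is the sole segment (short record), in
#' which case a warning notes the best-effort nature.
#'
#' @param rr An `rr_tbl`.
#' @param config An [analysis_config()].
#' @return Tibble with one row per segment: `segment`, `t_start`, `t_end`,
#'   `n_intervals`, `disorganization`, `af`.
#' @export
classify_af <- function(rr, config = analysis_config()) {
  seg_len <- config$af_segment_s
  t0 <- rr$onset_time
  seg_id <- floor(t0 / seg_len)
  total_t <- max(t0 + rr$rr)
  n_full <- floor(total_t / seg_len)
  empty <- tibble::tibble(segment = integer(), t_start = numeric(),
                          t_end = numeric(), n_intervals = integer(),
                          disorganization = numeric(), af = logical())
  if (n_full < 1L) {
    warning("record shorter than one ", seg_len,
            " s segment; best-effort single segment", call. = FALSE)
    segs <- 0L
  } else {
    segs <- 0L:(n_full - 1L)
  }
  rows <- lapply(segs, function(s) {
    sub <- rr[seg_id == s, ]
    idx <- score_af_segment(sub, config)
    tibble::tibble(segment = s + 1L,
                   t_start = s * seg_len,
                   t_end = if (n_full < 1L) total_t else (s + 1L) * seg_len,
                   n_intervals = nrow(sub),
                   disorganization = idx,
                   af = is.finite(idx) && idx > config$af_threshold)
  })
  dplyr::bind_rows(empty, rows)
}

# disorganization index of one RR sub-series; NA when too sparse to grid
score_af_segment <- function(sub, config) {
  if (nrow(sub) < 2L) return(NA_real_)
  sub$drr[1L] <- NA_real_  # first difference undefined at a segment boundary
  sub <- fence_outliers(sub, config$fence_multiplier, config$fence_rule)
  grid <- tryCatch(
    poincare_grid(sub, config$af_bins_per_axis,
                  config$poincare_rr_range, config$poincare_drr_range),
    error = function(e) NULL
  )
  if (is.null(grid)) return(NA_real_)
  disorganization_index(grid, config$af_full_bin_min_count)
}

#' Time-domain heart-rate-variability indices
#'
#' Classical short-term HRV summaries of the RR series: mean heart rate
#' (60 / mean RR, bpm); SDNN, the standard deviation of the intervals
#' (seconds); the range max(RR) - min(RR) (seconds); and the triangular
#' index, the total number of intervals divided by the height of the modal
#' bin of the RR histogram at the conventional 1/128 s bin width.
#'
#' @param rr An `rr_tbl`.
#' @param triangular_bin_s Histogram bin width for the triangular index.
#' @return One-row tibble: `n_intervals`, `mean_hr_bpm`, `sdnn_s`,
#'   `rr_range_s`, `triangular_index`.
#' @export
hrv_indices <- function(rr, triangular_bin_s = 1 / 128) {
  v <- rr$rr[rr$valid]
  if (length(v) < 2L) {
    stop("at least 2 valid intervals are required for HRV indices",
         call. = FALSE)
  }
  breaks <- seq(0, ceiling(max(v) / triangular_bin_s) + 1L) * triangular_bin_s
  counts <- tabulate(findInterval(v, breaks), nbins = length(breaks))
  tibble::tibble(
    n_intervals = length(v),
    mean_hr_bpm = 60 / mean(v),
    sdnn_s = sd(v),
    rr_range_s = max(v) - min(v),
    triangular_index = length(v) / max(counts)
  )
}
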