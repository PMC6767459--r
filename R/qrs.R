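#' QRS-enhancing feature signal
#'
#' The beat detector works on a squared derivative feature that enhances the
#' steep, high-amplitude QRS complex relative to the P and T waves. The
#' pre-squaring filter is the symmetric five-tap derivative
#' \deqn{y[n] = \frac{-2x[n-2] - x[n-1] + x[n+1] + 2x[n+2]}{10},}
#' i.e. transfer function (1/10)(-2z^-2 - z^-1 + z + 2z^2). The two-sample
#' non-causal advance is implemented as a centred FIR so that the feature is
#' time-aligned with the input (offline analysis permits zero delay). The
#' feature is the square of this output, so it is nonnegative, rejects DC
#' exactly (the coefficients sum to zero) and is invariant to sign inversion
#' of the ECG — inverted (extrasystole-like) complexes produce the same
#' feature as upright ones.
#'
#' The first and last two samples, where the stencil is incomplete, are set
#' to zero.
#'
#' @param x A filtered `ecg_tbl`.
#' @return A tibble of class `feature_tbl` with columns `time`, `feature`
#'   (mV^2), `valid`; attribute `fs`. Records shorter than 5 samples yield an
#'   empty feature tibble.
#' @export
ecg_feature_signal <- function(x) {
  fs <- ecg_fs(x)
  n <- nrow(x)
  if (n < 5L) {
    out <- tibble::tibble(time = numeric(), feature = numeric(),
                          valid = logical())
  } else {
    v <- x$voltage
    pre <- numeric(n)
    idx <- 3L:(n - 2L)
    pre[idx] <- (-2 * v[idx - 2L] - v[idx - 1L] + v[idx + 1L] +
                   2 * v[idx + 2L]) / 10
    out <- tibble::tibble(time = x$time, feature = pre^2, valid = x$valid)
  }
  attr(out, "fs") <- fs
  class(out) <- unique(c("feature_tbl", class(out)))
  out
}

#' Locate QRS candidate zones by amplitude thresholding
#'
#' The detection threshold is `mean + c * sd` of the feature signal over
#' valid samples; QRS location zones are the maximal contiguous runs where
#' the feature strictly exceeds it. Because the squared derivative passes
#' through zero exactly at the R crest, the two flanks of one QRS complex
#' would otherwise split into two runs; runs separated by a gap shorter than
#' `merge_gap_s` (50 ms default, far below any physiological beat spacing)
#' are therefore merged into a single zone. Zones that intersect any masked
#' (large-amplitude-noise) sample are discarded entirely, since amplitude in
#' excised blocks is meaningless.
#'
#' @param feature A `feature_tbl` from [ecg_feature_signal()].
#' @param threshold_c Multiplier `c` on the feature standard deviation.
#' @param merge_gap_s Runs closer than this gap (seconds) form one zone.
#' @return A tibble with columns `zone`, `start`, `end` (sample indices,
#'   inclusive); attribute `threshold` holds the value used.
#' @export
detect_zones <- function(feature, threshold_c = 1.0, merge_gap_s = 0.05) {
  if (nrow(feature) == 0L) {
    out <- tibble::tibble(zone = integer(), start = integer(), end = integer())
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  f <- feature$feature
  ok <- feature$valid
  thr <- mean(f[ok]) + threshold_c * sd(f[ok])
  if (!is.finite(thr)) thr <- Inf
  above <- f > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) > 1L) {
    gap_n <- round(merge_gap_s * (attr(feature, "fs", exact = TRUE) %||% 250))
    merged_s <- starts[1L]; merged_e <- ends[1L]
    for (i in 2L:length(starts)) {
      if (starts[i] - merged_e[length(merged_e)] <= gap_n) {
        merged_e[length(merged_e)] <- ends[i]
      } else {
        merged_s <- c(merged_s, starts[i])
        merged_e <- c(merged_e, ends[i])
      }
    }
    starts <- merged_s; ends <- merged_e
  }
  if (length(starts)) {
    clean <- vapply(seq_along(starts), function(i) {
      all(ok[starts[i]:ends[i]])
    }, logical(1))
    starts <- starts[clean]; ends <- ends[clean]
  }
  out <- tibble::tibble(zone = seq_along(starts), start = starts, end = ends)
  attr(out, "threshold") <- thr
  out
}

#' Refine each zone to the exact R-wave position
#'
#' Within each candidate zone the R position is the sample of maximum
#' absolute amplitude of the filtered ECG. Absolute value — not the signed
#' maximum — is used so that inverted QRS complexes (the ventricular
#' extrasystole case) are localised at their dominant deflection.
#'
#' @param x The filtered `ecg_tbl` the zones refer to.
#' @param zones Zone tibble from [detect_zones()].
#' @param feature Optional `feature_tbl`; when given, each candidate carries
#'   the feature value at its position (used to break refractory conflicts).
#' @return A tibble with columns `r_index`, `weight`.
#' @export
refine_peaks <- function(x, zones, feature = NULL) {
  if (nrow(zones) == 0L) {
    return(tibble::tibble(r_index = integer(), weight = numeric()))
  }
  r_index <- vapply(seq_len(nrow(zones)), function(i) {
    seg <- zones$start[i]:zones$end[i]
    seg[which.max(abs(x$voltage[seg]))]
  }, integer(1))
  weight <- if (is.null(feature)) rep(1, length(r_index)) else
    feature$feature[r_index]
  tibble::tibble(r_index = r_index, weight = weight)
}

#' Enforce a physiological refractory period between detections
#'
#' Candidates closer to the previously accepted beat than the refractory
#' period are artifacts (a heart cannot beat twice within ~0.2 s). The scan
#' is greedy left-to-right; within a conflicting pair, the candidate with the
#' larger feature value — the stronger QRS evidence — is kept.
#'
#' @param candidates Tibble with `r_index` (sorted ascending) and `weight`.
#' @param refractory_s Minimum allowed spacing, in seconds.
#' @param fs Sampling rate (Hz).
#' @return A tibble of class `beat_tbl` with columns `beat`, `r_index`,
#'   `time`; attributes `fs` and `n_removed_refractory`.
#' @export
refractory_filter <- function(candidates, refractory_s = 0.2, fs) {
  gap <- as.integer(round(refractory_s * fs))
  keep_idx <- integer()
  removed <- 0L
  for (i in seq_len(nrow(candidates))) {
    if (length(keep_idx) == 0L) {
      keep_idx <- i
      next
    }
    last <- keep_idx[length(keep_idx)]
    if (candidates$r_index[i] - candidates$r_index[last] >= gap) {
      keep_idx <- c(keep_idx, i)
    } else {
      removed <- removed + 1L
      if (candidates$weight[i] > candidates$weight[last]) {
        # replace, then re-check spacing against the beat before it
        keep_idx <- keep_idx[-length(keep_idx)]
        while (length(keep_idx) > 0L &&
               candidates$r_index[i] -
                 candidates$r_index[keep_idx[length(keep_idx)]] < gap) {
          keep_idx <- keep_idx[-length(keep_idx)]
          removed <- removed + 1L
        }
        keep_idx <- c(keep_idx, i)
      }
    }
  }
  out <- tibble::tibble(
    beat = seq_along(keep_idx),
    r_index = candidates$r_index[keep_idx],
    time = (candidates$r_index[keep_idx] - 1L) / fs
  )
  attr(out, "fs") <- fs
  attr(out, "n_removed_refractory") <- removed
  class(out) <- unique(c("beat_tbl", class(out)))
  out
}

#' Detect QRS complexes in an ECG record
#'
#' Full beat-detection chain: noise-adequation bench (unless the record has
#' already been preprocessed), squared-derivative feature signal, mean + c sd
#' zone thresholding, per-zone absolute-amplitude peak refinement, and
#' refractory filtering. The threshold is computed from the same (scaled)
#' feature it is applied to, so detected positions are invariant to overall
#' amplitude scaling of the record.
#'
#' @param x An `ecg_tbl`, raw or already filtered.
#' @param config An [analysis_config()].
#' @param preprocess Run the filter bench first? Set `FALSE` when `x` already
#'   went through [ecg_preprocess()]. Default: run it unless the record's
#'   `stages_applied()` shows a completed bench.
#' @return A `beat_tbl` (see [refractory_filter()]); the filtered record is
#'   attached as `attr(, "filtered")` for downstream template building.
#' @examples
#' sim <- synth_ecg(synth_spec(duration_s = 30, seed = 7))
#' beats <- detect_beats(sim$record)
#' nrow(beats)
#' @export
detect_beats <- function(x, config = analysis_config(),
                         preprocess = !("notch" %in% stages_applied(x))) {
  filtered <- if (preprocess) ecg_preprocess(x, config) else x
  feature <- ecg_feature_signal(filtered)
  zones <- detect_zones(feature, config$zone_threshold_c)
  cands <- refine_peaks(filtered, zones, feature)
  ann <- refractory_filter(cands, config$refractory_s, ecg_fs(filtered))
  attr(ann, "filtered") <- filtered
  ann
}
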