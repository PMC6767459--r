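#' Specification for a synthetic single-lead ECG
#'
#' Describes a simulated home-device recording: rhythm model, beat
#' morphology scale, and the noise classes such devices exhibit — baseline
#' drift below 0.5 Hz, 50 Hz powerline interference, broadband muscle (EMG)
#' noise above 20 Hz, sporadic large-amplitude body-movement bursts, and the
#' ~16 mV DC offset a dry-electrode front-end can induce.
#'
#' Rhythm models:
#' * `sinus` — RR intervals Gaussian around `60 / mean_hr_bpm` with standard
#'   deviation `hrv_sd_s`, truncated positive.
#' * `af` — RR drawn i.i.d. uniform on `[af_rr_min_s, af_rr_max_s]`. This is
#'   a deliberate simplification that reproduces the irregularly irregular,
#'   serially uncorrelated RR dynamics an atrial-fibrillation screen keys
#'   on; it is *not* a physiological AF model.
#' * `bigeminy_like` — alternating short/long intervals (0.6 s / 1.0 s).
#' * `pause_injected` — sinus with a single 3.5 s interval inserted
#'   mid-record.
#'
#' @param fs Sampling rate, Hz (250 default).
#' @param duration_s Record duration, seconds.
#' @param rhythm One of `"sinus"`, `"af"`, `"bigeminy_like"`,
#'   `"pause_injected"`.
#' @param mean_hr_bpm Mean heart rate for sinus-based rhythms.
#' @param hrv_sd_s Sinus RR jitter standard deviation, seconds.
#' @param af_rr_min_s,af_rr_max_s Uniform RR support for the AF model.
#' @param drift_amp_mV,drift_hz Baseline-drift sinusoid amplitude (mV) and
#'   frequency (must be < 0.5 Hz).
#' @param powerline_amp_mV 50 Hz interference amplitude (mV).
#' @param emg_amp_mV RMS of high-pass (20 Hz) filtered white muscle noise.
#' @param burst_rate_per_min Poisson rate of 0.5 s large-amplitude noise
#'   bursts.
#' @param burst_amp_factor Burst amplitude as a multiple of the R-wave
#'   amplitude.
#' @param dc_offset_mV Constant offset added to the whole record (16 mV
#'   default, the device-like value).
#' @param seed RNG seed; the seed fully determines the generated record.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 250, duration_s = 60,
                       rhythm = c("sinus", "af", "bigeminy_like",
                                  "pause_injected"),
                       mean_hr_bpm = 60, hrv_sd_s = 0.03,
                       af_rr_min_s = 0.4, af_rr_max_s = 1.0,
                       drift_amp_mV = 0, drift_hz = 0.3,
                       powerline_amp_mV = 0, emg_amp_mV = 0,
                       burst_rate_per_min = 0, burst_amp_factor = 10,
                       dc_offset_mV = 16, seed = 1L) {
  rhythm <- match.arg(rhythm)
  spec <- list(fs = fs, duration_s = duration_s, rhythm = rhythm,
               mean_hr_bpm = mean_hr_bpm, hrv_sd_s = hrv_sd_s,
               af_rr_min_s = af_rr_min_s, af_rr_max_s = af_rr_max_s,
               drift_amp_mV = drift_amp_mV, drift_hz = drift_hz,
               powerline_amp_mV = powerline_amp_mV, emg_amp_mV = emg_amp_mV,
               burst_rate_per_min = burst_rate_per_min,
               burst_amp_factor = burst_amp_factor,
               dc_offset_mV = dc_offset_mV, seed = as.integer(seed))
  if (spec$drift_hz >= 0.5) {
    stop("baseline drift is by definition below 0.5 Hz; got drift_hz = ",
         spec$drift_hz, call. = FALSE)
  }
  amps <- c(spec$drift_amp_mV, spec$powerline_amp_mV, spec$emg_amp_mV,
            spec$burst_rate_per_min)
  if (any(amps < 0)) stop("noise amplitudes must be >= 0", call. = FALSE)
  if (spec$fs <= 0 || spec$duration_s <= 0) {
    stop("fs and duration_s must be positive", call. = FALSE)
  }
  if (60 / spec$mean_hr_bpm < 0.25) {
    stop("mean RR below 0.25 s is not physiologically feasible",
         call. = FALSE)
  }
  if (spec$af_rr_min_s >= spec$af_rr_max_s || spec$af_rr_min_s <= 0) {
    stop("AF RR support must satisfy 0 < min < max", call. = FALSE)
  }
  class(spec) <- "synth_spec"
  spec
}

# P-QRS-T morphology as a sum of Gaussians; amplitudes in mV, timing in
# seconds relative to the R wave, widths as Gaussian sigma.
beat_waves <- function() {
  data.frame(
    wave = c("P", "Q", "R", "S", "T"),
    amp = c(0.12, -0.10, 1.00, -0.18, 0.35),
    mu = c(-0.20, -0.030, 0.0, 0.030, 0.25),
    sigma = c(0.025, 0.010, 0.011, 0.012, 0.055)
  )
}

#' Canonical clean beat shape of the synthetic generator
#'
#' Evaluates the generator's isolated P-QRS-T sum-of-Gaussians morphology at
#' the given times (seconds relative to the R wave), free of neighbouring
#' beats and noise. Useful as the reference waveform when judging how well
#' an averaged beat template recovers the underlying morphology.
#'
#' @param times Numeric vector of times relative to the R wave, seconds.
#' @return Voltage vector (mV), 1 mV R peak.
#' @export
synth_beat_waveform <- function(times) {
  waves <- beat_waves()
  out <- numeric(length(times))
  for (w in seq_len(nrow(waves))) {
    out <- out + waves$amp[w] *
      exp(-0.5 * ((times - waves$mu[w]) / waves$sigma[w])^2)
  }
  out
}

# run fn with a private, restored RNG stream seeded from `seed`
with_private_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

draw_rr_sequence <- function(spec) {
  mean_rr <- 60 / spec$mean_hr_bpm
  n_guess <- ceiling(spec$duration_s / min(mean_rr, spec$af_rr_min_s)) + 8L
  rr <- switch(spec$rhythm,
    sinus = ,
    pause_injected = {
      r <- rnorm(n_guess, mean_rr, spec$hrv_sd_s)
      while (any(r <= 0.25)) {   # truncate positive / physiologic
        bad <- r <= 0.25
        r[bad] <- rnorm(sum(bad), mean_rr, spec$hrv_sd_s)
      }
      r
    },
    af = runif(n_guess, spec$af_rr_min_s, spec$af_rr_max_s),
    bigeminy_like = rep(c(1.0, 0.6), length.out = n_guess)
  )
  if (spec$rhythm == "pause_injected") {
    k <- max(2L, floor(spec$duration_s / (2 * mean_rr)))
    rr[k] <- 3.5
  }
  rr
}

#' Generate a synthetic device-like ECG with ground truth
#'
#' Beat positions come from the rhythm model of the spec; each beat is a
#' fixed sum-of-Gaussians P-QRS-T waveform (1 mV R wave) centred on its R
#' sample. Noise components are then added per the spec: sinusoidal baseline
#' drift, a 50 Hz powerline tone, 20 Hz high-passed white EMG noise,
#' uniformly placed 0.5 s large-amplitude bursts (Poisson count), and a
#' constant DC offset. The output is bit-reproducible given the spec's seed.
#'
#' @param spec A [synth_spec()].
#' @return A list with elements
#'   * `record` — the noisy `ecg_tbl`;
#'   * `truth` — list with `r_samples` (true R sample indices), `r_times`,
#'     `rr_true` (seconds), `clean` (noise-free voltage vector),
#'     `burst_blocks` (1-based indices of 0.5 s blocks containing a burst),
#'     `rhythm`.
#' @examples
#' sim <- synth_ecg(synth_spec(duration_s = 10, dc_offset_mV = 0, seed = 42))
#' length(sim$truth$r_samples)
#' @export
synth_ecg <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_private_seed(spec$seed, function() {
    fs <- spec$fs
    n <- as.integer(round(spec$duration_s * fs))
    t <- (seq_len(n) - 1) / fs
    rr <- draw_rr_sequence(spec)
    r_times <- 0.5 + cumsum(c(0, rr))
    r_times <- r_times[r_times <= spec$duration_s - 0.3]
    r_samples <- as.integer(round(r_times * fs)) + 1L
    r_samples <- r_samples[r_samples >= 1L & r_samples <= n]
    r_times <- (r_samples - 1) / fs   # snap truth to the sample grid
    waves <- beat_waves()
    clean <- numeric(n)
    for (rt in r_times) {
      lo <- max(1L, as.integer(floor((rt - 0.45) * fs)))
      hi <- min(n, as.integer(ceiling((rt + 0.55) * fs)))
      seg_t <- t[lo:hi] - rt
      contrib <- numeric(length(seg_t))
      for (w in seq_len(nrow(waves))) {
        contrib <- contrib + waves$amp[w] *
          exp(-0.5 * ((seg_t - waves$mu[w]) / waves$sigma[w])^2)
      }
      clean[lo:hi] <- clean[lo:hi] + contrib
    }
    v <- clean
    if (spec$drift_amp_mV > 0) {
      v <- v + spec$drift_amp_mV *
        sin(2 * pi * spec$drift_hz * t + runif(1, 0, 2 * pi))
    }
    if (spec$powerline_amp_mV > 0) {
      v <- v + spec$powerline_amp_mV *
        sin(2 * pi * 50 * t + runif(1, 0, 2 * pi))
    }
    if (spec$emg_amp_mV > 0) {
      white <- rnorm(n)
      bf <- signal::butter(4, min(0.99, 20 / (fs / 2)), type = "high")
      emg <- signal::filtfilt(bf$b, bf$a, white)
      v <- v + spec$emg_amp_mV * emg / sd(emg)
    }
    burst_blocks <- integer()
    if (spec$burst_rate_per_min > 0) {
      block_n <- as.integer(round(0.5 * fs))
      n_blocks <- n %/% block_n
      k <- rpois(1, spec$burst_rate_per_min * spec$duration_s / 60)
      k <- min(k, n_blocks)
      if (k > 0L) {
        burst_blocks <- sort(sample.int(n_blocks, k))
        for (b in burst_blocks) {
          idx <- ((b - 1L) * block_n + 1L):(b * block_n)
          v[idx] <- v[idx] +
            spec$burst_amp_factor * runif(length(idx), -1, 1)
        }
      }
    }
    v <- v + spec$dc_offset_mV
    record <- ecg_record(v, fs = fs, subject_id = "synthetic",
                         notes = paste0("synthetic ", spec$rhythm,
                                        " rhythm, seed ", spec$seed))
    list(record = record,
         truth = list(r_samples = r_samples, r_times = r_times,
                      rr_true = diff(r_times), clean = clean,
                      burst_blocks = burst_blocks, rhythm = spec$rhythm))
  })
}

#' Sample an AF-like RR series directly
#'
#' Draws `n` serially independent RR intervals uniform on
#' `[min_rr_s, max_rr_s]` — the package's stylised model of the atria
#' "randomly beating". Useful for exercising the Poincare machinery without
#' synthesising a full waveform.
#'
#' @param n Number of intervals.
#' @param min_rr_s,max_rr_s Uniform support, seconds.
#' @param seed Optional seed for a private RNG stream.
#' @return Numeric vector of `n` RR intervals, seconds.
#' @export
rr_af_sample <- function(n, min_rr_s = 0.4, max_rr_s = 1.0, seed = NULL) {
  stopifnot(n >= 1)
  draw <- function() runif(n, min_rr_s, max_rr_s)
  if (is.null(seed)) draw() else with_private_seed(seed, draw)
}

#' Build an `rr_tbl` from a plain vector of RR intervals
#'
#' Convenience for feeding simulated or externally measured interval series
#' into [fence_outliers()], [poincare_grid()], [classify_af()] and
#' [hrv_indices()] without a waveform.
#'
#' @param rr Numeric vector of RR intervals, seconds (all > 0).
#' @param fs Nominal sampling rate to attach (only used for provenance).
#' @return An `rr_tbl` tibble.
#' @export
rr_series <- function(rr, fs = 250) {
  stopifnot(length(rr) >= 1, all(rr > 0))
  out <- tibble::tibble(
    interval = seq_along(rr),
    onset_time = c(0, cumsum(rr)[-length(rr)]),
    rr = as.numeric(rr),
    drr = c(NA_real_, diff(rr)),
    valid = TRUE,
    outlier = FALSE
  )
  attr(out, "fs") <- fs
  class(out) <- unique(c("rr_tbl", class(out)))
  out
}
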