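# Match detected beats against ground-truth R samples within a time
# tolerance; returns sensitivity and positive predictivity.
beat_metrics <- function(beats, truth_samples, fs, tol_s = 0.05) {
  tol <- tol_s * fs
  if (length(truth_samples) == 0L) {
    return(list(sens = NA_real_, ppv = as.numeric(nrow(beats) == 0L)))
  }
  sens <- mean(vapply(truth_samples, function(r) {
    any(abs(beats$r_index - r) <= tol)
  }, logical(1)))
  ppv <- if (nrow(beats) == 0L) 0 else
    mean(vapply(beats$r_index, function(r) {
      any(abs(truth_samples - r) <= tol)
    }, logical(1)))
  list(sens = sens, ppv = ppv)
}

# EMG amplitude giving the requested SNR (dB) against a clean reference
# waveform's AC power.
emg_amp_for_snr <- function(clean, snr_db) {
  sd(clean) * 10^(-snr_db / 20)
}

# steady-state amplitude of a filtered sinusoid (middle 60% of the record)
steady_amp <- function(v) {
  n <- length(v)
  max(abs(v[round(0.2 * n):round(0.8 * n)]))
}
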