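clean_fixture <- function(duration_s = 30, seed = 5, hrv_sd_s = 0,
                          emg_amp_mV = 0) {
  sim <- synth_ecg(synth_spec(duration_s = duration_s, seed = seed,
                              hrv_sd_s = hrv_sd_s, emg_amp_mV = emg_amp_mV,
                              dc_offset_mV = 0))
  beats <- detect_beats(sim$record, preprocess = FALSE)
  list(sim = sim, beats = beats)
}

test_that("beat windows follow the 40%/60% split of the mean cycle", {
  fx <- clean_fixture()
  wins <- segment_beats(fx$sim$record, fx$beats)
  expect_equal(attr(wins, "pre_n"), 100L)   # 0.4 * 1.0 s * 250 Hz
  expect_equal(attr(wins, "post_n"), 150L)
  expect_equal(max(wins$pos), 250L)
  # the R wave sits at pos = pre_n + 1 and carries the 1 mV peak
  first <- wins[wins$beat == wins$beat[1], ]
  expect_equal(which.max(first$voltage), 101L)

  # a beat whose pre-window underruns the record is dropped
  short <- fx$beats
  short$r_index[1] <- 10L
  wins2 <- segment_beats(fx$sim$record, short)
  expect_false(1L %in% unique(wins2$beat))
  expect_error(segment_beats(fx$sim$record, fx$beats[1, ]), "at least 2")
})

test_that("windows touching masked samples are dropped", {
  fx <- clean_fixture()
  sig <- fx$sim$record
  r2 <- fx$beats$r_index[2]
  sig$valid[(r2 - 5):(r2 + 5)] <- FALSE
  wins <- segment_beats(sig, fx$beats)
  expect_false(2L %in% unique(wins$beat))
})

test_that("identical beats all pass the correlation gate; a negated beat fails", {
  fx <- clean_fixture()
  wins <- segment_beats(fx$sim$record, fx$beats)
  acc <- qrs_correlation_gate(wins)
  expect_equal(unique(acc$beat), unique(wins$beat))
  expect_true(all(attr(acc, "correlations") > 0.995))

  # negate one beat's neighbourhood: correlation -1, rejected
  v <- fx$sim$record$voltage
  r3 <- fx$beats$r_index[3]
  v[(r3 - 100):(r3 + 149)] <- -v[(r3 - 100):(r3 + 149)]
  rec2 <- ecg_record(v, 250)
  b2 <- detect_beats(rec2, preprocess = FALSE)
  w2 <- segment_beats(rec2, b2)
  a2 <- qrs_correlation_gate(w2)
  corr <- attr(a2, "correlations")
  expect_equal(sum(corr < 0.995), 1L)
  expect_lt(min(corr), -0.9)
})

test_that("noisy beats at 20 dB SNR are mostly accepted", {
  fx0 <- clean_fixture(duration_s = 60)
  amp <- emg_amp_for_snr(fx0$sim$truth$clean, 20)
  sim <- synth_ecg(synth_spec(duration_s = 60, seed = 5, hrv_sd_s = 0,
                              emg_amp_mV = amp, dc_offset_mV = 0))
  beats <- detect_beats(sim$record, preprocess = FALSE)
  wins <- segment_beats(sim$record, beats)
  acc <- qrs_correlation_gate(wins)
  expect_gte(length(unique(acc$beat)) / length(unique(wins$beat)), 0.90)
})

test_that("averaging: identity on identical windows, sigma/sqrt(N) noise reduction", {
  fx <- clean_fixture()
  wins <- segment_beats(fx$sim$record, fx$beats)
  tpl <- average_template(qrs_correlation_gate(wins))
  one <- wins$voltage[wins$beat == wins$beat[1]]
  expect_equal(tpl$voltage, one, tolerance = 1e-10)
  expect_equal(nrow(tpl), 250L)

  # N windows of pure noise sigma: residual sd ~ sigma / sqrt(N)
  set.seed(55)
  n_rep <- 100L; N <- 16L; L <- 120L; sigma <- 0.1
  ratio <- vapply(seq_len(n_rep), function(i) {
    w <- tibble::tibble(beat = rep(seq_len(N), each = L),
                        pos = rep(seq_len(L), N),
                        voltage = rep(sin(seq_len(L) / 6), N) +
                          rnorm(N * L, 0, sigma))
    attr(w, "fs") <- 250; attr(w, "pre_n") <- 40L
    attr(w, "post_n") <- 80L; attr(w, "cycle_s") <- L / 250
    class(w) <- unique(c("beat_windows", class(w)))
    resid <- average_template(w)$voltage - sin(seq_len(L) / 6)
    sd(resid) / (sigma / sqrt(N))
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.30)

  single <- wins[wins$beat == wins$beat[1], ]
  for (a in c("fs", "pre_n", "post_n", "cycle_s")) {
    attr(single, a) <- attr(wins, a, exact = TRUE)
  }
  expect_equal(average_template(single)$voltage, one)
})

test_that("template stays inside the contributor envelope and tracks the clean beat", {
  amp <- 0  # start clean, then 10 dB noise
  for (snr in c(Inf, 10)) {
    fx0 <- clean_fixture(duration_s = 60)
    amp <- if (is.finite(snr)) emg_amp_for_snr(fx0$sim$truth$clean, snr) else 0
    sim <- synth_ecg(synth_spec(duration_s = 60, seed = 12, hrv_sd_s = 0.02,
                                emg_amp_mV = amp, dc_offset_mV = 0))
    beats <- detect_beats(sim$record, preprocess = FALSE)
    wins <- segment_beats(sim$record, beats)
    acc <- qrs_correlation_gate(wins)
    tpl <- average_template(acc)
    lo <- tapply(acc$voltage, acc$pos, min)
    hi <- tapply(acc$voltage, acc$pos, max)
    expect_true(all(tpl$voltage >= lo - 1e-12 & tpl$voltage <= hi + 1e-12))
    # correlation with the generator's isolated clean beat shape
    expect_gt(cor(tpl$voltage, synth_beat_waveform(tpl$time)), 0.99)
  }
})

test_that("raising the correlation threshold never adds contributors", {
  sim <- synth_ecg(synth_spec(duration_s = 60, seed = 13, hrv_sd_s = 0.02,
                              emg_amp_mV = 0.05, dc_offset_mV = 0))
  beats <- detect_beats(sim$record, preprocess = FALSE)
  wins <- segment_beats(sim$record, beats)
  n_at <- vapply(c(0.90, 0.95, 0.995, 0.999), function(cm) {
    acc <- suppressWarnings(qrs_correlation_gate(wins, corr_min = cm))
    length(unique(acc$beat))
  }, numeric(1))
  expect_true(all(diff(n_at) <= 0))
})
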