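fake_beats <- function(r_indices, fs = 250) {
  out <- tibble::tibble(beat = seq_along(r_indices),
                        r_index = as.integer(r_indices),
                        time = (r_indices - 1) / fs)
  attr(out, "fs") <- fs
  class(out) <- unique(c("beat_tbl", class(out)))
  out
}

test_that("RR and dRR are plain interval arithmetic", {
  rr <- build_rr(fake_beats(c(1, 251, 501)))
  expect_equal(rr$rr, c(1.0, 1.0))
  expect_equal(rr$drr, c(NA, 0))
  rr2 <- build_rr(fake_beats(c(1, 201, 501)))
  expect_equal(rr2$rr, c(0.8, 1.2))
  expect_equal(rr2$drr[2], 0.4)
  expect_error(build_rr(fake_beats(100)), "at least 2 beats")
})

test_that("intervals spanning masked samples are excluded from statistics", {
  sig <- ecg_record(rep(0, 1000), fs = 250)
  sig$valid[300:350] <- FALSE
  rr <- build_rr(fake_beats(c(1, 251, 501, 751)), signal = sig)
  expect_equal(rr$valid, c(TRUE, FALSE, TRUE))
})

test_that("alteration warnings follow the strict 30% rule", {
  expect_equal(detect_rhythm_alterations(rr_series(c(0.8, 0.8, 1.2)))$interval, 3L)
  expect_equal(nrow(detect_rhythm_alterations(rr_series(c(0.8, 1.0)))), 0L)
  expect_equal(nrow(detect_rhythm_alterations(rr_series(rep(0.9, 20)))), 0L)
  # exhaustive small-case enumeration against the literal rule
  set.seed(31)
  for (i in 1:50) {
    rr <- runif(8, 0.4, 2.0)
    got <- detect_rhythm_alterations(rr_series(rr))$interval
    want <- which(c(FALSE, abs(diff(rr)) / rr[-length(rr)] > 0.30))
    expect_equal(got, as.integer(want))
  }
})

test_that("pause warnings are strictly RR > 3 s", {
  expect_equal(detect_pauses(rr_series(c(0.9, 3.1)))$interval, 2L)
  expect_equal(nrow(detect_pauses(rr_series(c(0.9, 3.0)))), 0L)
  expect_equal(nrow(detect_pauses(rr_series(rep(1.0, 10)))), 0L)
  set.seed(32)
  for (i in 1:50) {
    rr <- runif(10, 0.5, 4)
    expect_equal(detect_pauses(rr_series(rr))$interval,
                 as.integer(which(rr > 3)))
  }
})

test_that("outlier fencing equals a brute-force percentile oracle", {
  set.seed(33)
  for (i in 1:300) {
    n <- sample(5:60, 1)
    rr <- exp(rnorm(n, log(0.8), 0.4))
    fenced <- fence_outliers(rr_series(rr))
    drr <- diff(rr)
    q <- quantile(rr, c(0.25, 0.75), names = FALSE)
    qd <- quantile(drr, c(0.25, 0.75), names = FALSE)
    o1 <- rr < q[1] - 3 * (q[2] - q[1]) | rr > q[2] + 3 * (q[2] - q[1])
    o2 <- c(FALSE, drr < qd[1] - 3 * (qd[2] - qd[1]) |
                   drr > qd[2] + 3 * (qd[2] - qd[1]))
    expect_identical(fenced$outlier, o1 | o2)
  }
})

test_that("fencing handles narrow, degenerate and spiked series", {
  set.seed(34)
  rr <- runif(100, 0.7, 0.9)
  expect_equal(sum(fence_outliers(rr_series(rr))$outlier), 0L)
  rr2 <- c(rep(0.8, 30) + rnorm(30, 0, 0.02), 5.0)
  fenced <- fence_outliers(rr_series(rr2))
  expect_true(fenced$outlier[31])
  expect_equal(sum(fence_outliers(rr_series(rep(0.8, 20)))$outlier), 0L)
  expect_message(fence_outliers(rr_series(c(0.8, 0.9))), "skipped")
})

test_that("fencing is time-reversal invariant on the RR axis and monotone in the multiplier", {
  set.seed(35)
  rr <- exp(rnorm(40, log(0.8), 0.5))
  fwd <- fence_outliers(rr_series(rr))
  # RR-axis flags only (dRR is direction-sensitive)
  rr_axis_flags <- function(x) {
    f <- attr(x, "fences")
    x$rr < f$p25_rr - 3 * f$iqr_rr | x$rr > f$p75_rr + 3 * f$iqr_rr
  }
  rev_f <- fence_outliers(rr_series(rev(rr)))
  expect_identical(rev(rr_axis_flags(rev_f)), rr_axis_flags(fwd))
  wide <- fence_outliers(rr_series(rr), multiplier = 3)
  narrow <- fence_outliers(rr_series(rr), multiplier = 1)
  expect_true(all(which(wide$outlier) %in% which(narrow$outlier)))
})

test_that("the literal fence rule reduces to the upper fence only", {
  rr <- c(rep(0.8, 20), 0.2, 5.0)
  lit <- fence_outliers(rr_series(rr), rule = "literal")
  cor_ <- fence_outliers(rr_series(rr), rule = "corrected")
  expect_true(cor_$outlier[21] && cor_$outlier[22])   # both extremes
  expect_false(lit$outlier[21])                       # low spike not caught
  expect_true(lit$outlier[22])
})

test_that("Poincare grid conserves points and enumerates known patterns", {
  rr <- rr_series(rep(1.0, 20))
  g <- poincare_grid(rr)
  expect_equal(nrow(g), 1L)
  expect_equal(sum(g$count), attr(g, "n_points"))

  big <- rr_series(rep(c(0.6, 1.0), 30))
  g2 <- poincare_grid(big)
  expect_equal(nrow(g2), 2L)  # (1.0, +0.4) and (0.6, -0.4)
  expect_equal(sum(g2$count), 59L)  # n - 1 points have a defined dRR

  set.seed(36)
  for (i in 1:20) {
    rr3 <- rr_series(rr_af_sample(sample(10:200, 1)))
    g3 <- poincare_grid(rr3)
    expect_equal(sum(g3$count), attr(g3, "n_points"))
  }
  expect_error(poincare_grid(rr_series(0.8)), "no plottable")
})

test_that("disorganization index is a bounded occupancy fraction", {
  g <- poincare_grid(rr_series(rep(1.0, 20)), bins_per_axis = 30)
  expect_equal(disorganization_index(g), 1 / 900)
  # synthetic full grid
  full <- tibble::tibble(bin_rr = rep(1:5, each = 5),
                         bin_drr = rep(1:5, 5), count = 1L)
  attr(full, "bins_per_axis") <- 5L
  expect_equal(disorganization_index(full), 1.0)
  # monotone in occupied bins, bounded in [0, 1]
  set.seed(37)
  prev <- 0
  for (n in c(5, 20, 80, 200)) {
    gi <- disorganization_index(poincare_grid(rr_series(rr_af_sample(n))))
    expect_gte(gi, 0); expect_lte(gi, 1)
    expect_gte(gi, prev)
    prev <- gi
  }
})

test_that("AF-like segments score higher disorganization than sinus in paired simulation", {
  set.seed(38)
  n_pairs <- 200L
  wins <- vapply(seq_len(n_pairs), function(i) {
    af <- rr_af_sample(110)
    af <- af[cumsum(af) <= 75]
    sin_rr <- pmax(0.3, rnorm(100, 0.75, 0.03))
    sin_rr <- sin_rr[cumsum(sin_rr) <= 75]
    idx <- function(v) disorganization_index(
      poincare_grid(fence_outliers(rr_series(v))))
    idx(af) > idx(sin_rr)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("segmental AF classification separates the rhythm generators", {
  cfg <- analysis_config()
  sinus <- synth_ecg(synth_spec(duration_s = 160, seed = 40))
  rr_s <- build_rr(detect_beats(sinus$record, cfg))
  seg_s <- classify_af(rr_s, cfg)
  expect_equal(nrow(seg_s), 2L)
  expect_false(any(seg_s$af))

  af <- synth_ecg(synth_spec(duration_s = 160, seed = 41, rhythm = "af"))
  rr_a <- build_rr(detect_beats(af$record, cfg))
  seg_a <- classify_af(rr_a, cfg)
  expect_equal(nrow(seg_a), 2L)
  expect_true(all(seg_a$af))

  # index never exceeds 1, so a threshold of 1 flags nothing
  cfg1 <- analysis_config(af_threshold = 1.0)
  expect_false(any(classify_af(rr_a, cfg1)$af))

  expect_warning(classify_af(rr_series(rep(0.8, 10)), cfg), "best-effort")
})

test_that("HRV indices match their definitions and a brute-force oracle", {
  h <- hrv_indices(rr_series(rep(1.0, 30)))
  expect_equal(h$mean_hr_bpm, 60)
  expect_equal(h$sdnn_s, 0)
  expect_equal(h$rr_range_s, 0)
  expect_equal(h$triangular_index, 1.0)

  h2 <- hrv_indices(rr_series(c(0.5, 1.0)))
  expect_equal(h2$mean_hr_bpm, 80)
  expect_equal(h2$rr_range_s, 0.5)

  set.seed(39)
  for (i in 1:20) {
    rr <- runif(sample(10:300, 1), 0.4, 1.4)
    h3 <- hrv_indices(rr_series(rr))
    expect_equal(h3$sdnn_s, sd(rr))
    expect_equal(h3$mean_hr_bpm, 60 / mean(rr))
    # triangular index vs direct histogram at 1/128 s bins
    counts <- table(floor(rr / (1 / 128)))
    expect_equal(h3$triangular_index, length(rr) / max(counts))
  }
})
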