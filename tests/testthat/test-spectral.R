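sine_series <- function(f, fps = 200, n = 4000, amp = 0.3, mean0 = 0,
                        kind = "flagellar", noise = 0) {
  t <- (0:(n - 1)) / fps
  th <- wrap_to_pi(mean0 + amp * sin(2 * pi * f * t) + rnorm(n, sd = noise))
  make_series(th, kind = kind, fps = fps)
}

ramp_series <- function(f_rot, fps = 200, n = 4000) {
  t <- (0:(n - 1)) / fps
  make_series(wrap_to_pi(2 * pi * f_rot * t), kind = "body", fps = fps)
}

test_that("longest valid segment picks the earliest longest contiguous run", {
  s <- make_series(seq(0, 0.5, length.out = 6),
                   valid = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  seg <- longest_valid_segment(s)
  expect_equal(seg$frame, 3:5)
  expect_true(all(seg$valid))

  all_ok <- make_series(seq(0, 0.5, length.out = 8))
  expect_equal(longest_valid_segment(all_ok)$frame, 0:7)

  alt <- make_series(rep(0.1, 8), valid = c(TRUE, FALSE))
  expect_equal(longest_valid_segment(alt)$frame, 0)

  # frame-index gaps break runs even when every row is valid
  gap <- make_series(rep(0.1, 6), frame = c(0, 1, 2, 10, 11, 12))
  expect_equal(longest_valid_segment(gap)$frame, 0:2)

  expect_flagrot_error(
    longest_valid_segment(make_series(rep(0, 4), valid = c(TRUE, FALSE,
                                                           FALSE, FALSE))),
    "flagrot_insufficient_data_error")
})

test_that("mean-removed spectrum localizes a sinusoid to one bin", {
  s <- sine_series(46.5)
  spec <- power_spectrum(s, "mean_removed")
  expect_equal(spec$df, 200 / 4000)
  expect_lte(abs(spec$freq[which.max(spec$power)] - 46.5), spec$df)

  const <- make_series(rep(0.7, 64))
  expect_true(all(power_spectrum(const, "mean_removed")$power == 0))

  expect_flagrot_error(power_spectrum(make_series(rnorm(64),
                                                  valid = c(TRUE, TRUE, FALSE, TRUE))),
                       "flagrot_validation_error")
  expect_flagrot_error(power_spectrum(make_series(rnorm(8))),
                       "flagrot_insufficient_data_error")
})

test_that("unit-complex spectrum localizes a wrapped rotation ramp", {
  for (f_rot in c(1.7, 4.3, -2.5)) {
    spec <- power_spectrum(ramp_series(f_rot), "unit_complex")
    expect_lte(abs(spec$freq[which.max(spec$power)] - abs(f_rot)), spec$df)
  }
})

test_that("total mean-removed power equals the signal variance (Parseval)", {
  set.seed(21)
  for (n in c(64, 1001, 4096)) {
    s <- make_series(wrap_to_pi(rnorm(n, sd = 0.8)), fps = 200)
    spec <- power_spectrum(s, "mean_removed")
    v <- mean((s$theta - mean(s$theta))^2)
    expect_equal(sum(spec$power), v, tolerance = 1e-6)
  }
})

test_that("peak picking matches a brute-force in-band argmax", {
  set.seed(22)
  for (i in 1:20) {
    f1 <- runif(1, 15, 48)
    f2 <- runif(1, 55, 95)
    t <- (0:3999) / 200
    th <- wrap_to_pi(1.0 * sin(2 * pi * f1 * t) + 0.4 * sin(2 * pi * f2 * t) +
                       rnorm(4000, sd = 0.02))
    spec <- power_spectrum(make_series(th), "mean_removed")
    est <- pick_peak(spec, 10, 100)
    in_band <- spec$freq >= 10 & spec$freq <= 100
    brute <- spec$freq[in_band][which.max(spec$power[in_band])]
    expect_equal(est$peak_hz, brute)
    # the larger sinusoid wins
    expect_lte(abs(est$peak_hz - f1), spec$df)
  }
})

test_that("flat and empty spectra yield a no-peak condition", {
  flat <- structure(list(freq = seq(0, 100, by = 0.5),
                         power = c(0, rep(1, 200)), df = 0.5,
                         n_samples = 400, source_kind = "flagellar",
                         fps = 200),
                    class = "spectrum_fr")
  expect_flagrot_error(pick_peak(flat, 10, 100), "flagrot_no_peak_error")
  expect_flagrot_error(pick_peak(flat, 10, 120), "flagrot_validation_error")

  const <- make_series(rep(0.7, 64))
  expect_flagrot_error(
    pick_peak(power_spectrum(const, "mean_removed"), 10, 100),
    "flagrot_no_peak_error")
})

test_that("tied peaks resolve to the lowest frequency", {
  p <- rep(0, 41)
  p[c(11, 31)] <- 5  # two identical peaks
  tied <- structure(list(freq = seq(0, 100, by = 2.5), power = p, df = 2.5,
                         n_samples = 80, source_kind = "flagellar",
                         fps = 200),
                    class = "spectrum_fr")
  est <- pick_peak(tied, 10, 100)
  expect_equal(est$peak_hz, tied$freq[11])
  expect_true(est$ambiguous)
})

test_that("beat and rotation estimators recover generator frequencies", {
  cfg <- simulation_config(f_rot = 4.3, f_beat = 67.1, noise_sigma = 0,
                           dropout_prob = 0, seed = 2)
  sim <- simulate_track(cfg)
  fl <- flagellar_angle(sim$track)
  be <- estimate_beat_frequency(fl)
  expect_lte(abs(be$peak_hz - 67.1), be$df)
  expect_equal(be$df, 200 / 12607, tolerance = 1e-12)

  body <- body_axis_angle(sim$track)
  re <- estimate_rotation_frequency(body)
  expect_lte(abs(re$peak_hz - 4.3), re$df)

  # with moderate angle noise the estimate stays within one bin
  set.seed(23)
  noisy <- sine_series(67.1, n = 12607, amp = 0.6, noise = 0.05)
  bn <- estimate_beat_frequency(noisy)
  expect_lte(abs(bn$peak_hz - 67.1), bn$df)

  # 1.7 Hz ramp
  re2 <- estimate_rotation_frequency(ramp_series(1.7, n = 12607))
  expect_lte(abs(re2$peak_hz - 1.7), re2$df)

  # constant angle: no peak; zero rotation with small noise: no peak
  expect_flagrot_error(estimate_beat_frequency(make_series(rep(0.2, 100))),
                       "flagrot_no_peak_error")
  set.seed(24)
  still <- make_series(wrap_to_pi(0.3 + rnorm(4000, sd = 0.02)),
                       kind = "body")
  expect_flagrot_error(estimate_rotation_frequency(still),
                       "flagrot_no_peak_error")
})

test_that("spectral estimates are blind to the sign of the angle", {
  set.seed(25)
  th <- wrap_to_pi(0.5 * sin(2 * pi * 31 * (0:2999) / 200) +
                     rnorm(3000, sd = 0.03))
  a <- estimate_beat_frequency(make_series(th, kind = "flagellar"))
  b <- estimate_beat_frequency(make_series(wrap_to_pi(-th),
                                           kind = "flagellar"))
  expect_equal(a$peak_hz, b$peak_hz)

  ra <- estimate_rotation_frequency(ramp_series(2.9, n = 3000))
  rb <- estimate_rotation_frequency(ramp_series(-2.9, n = 3000))
  expect_equal(ra$peak_hz, rb$peak_hz)
})

test_that("halving the record doubles df and pure tones stay within one bin", {
  set.seed(26)
  for (i in 1:10) {
    f <- runif(1, 12, 90)
    s_full <- sine_series(f, n = 4096)
    s_half <- sine_series(f, n = 2048)
    sp_full <- power_spectrum(s_full, "mean_removed")
    sp_half <- power_spectrum(s_half, "mean_removed")
    expect_equal(sp_half$df, 2 * sp_full$df)
    e_full <- pick_peak(sp_full, 10, 100)
    e_half <- pick_peak(sp_half, 10, 100)
    expect_lte(abs(e_full$peak_hz - f), sp_full$df)
    expect_lte(abs(e_half$peak_hz - f), sp_half$df)
  }
})

test_that("noise-free spectral and slope rotation rates agree within df", {
  cfg <- simulation_config(f_rot = -3.3, f_beat = 52, noise_sigma = 0,
                           dropout_prob = 0, seed = 3, n_frames = 6000)
  sim <- simulate_track(cfg)
  body <- body_axis_angle(sim$track)
  rot <- fit_rotation(unwrap_cumulative(body), "c")
  est <- estimate_rotation_frequency(body)
  expect_lte(abs(est$peak_hz - abs(rot$omega) / (2 * pi)), est$df)
  expect_identical(rot$direction, "CW")
})
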