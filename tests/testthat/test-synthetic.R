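test_that("noise-free tracks are self-consistent with every pipeline stage", {
  cfg <- simulation_config(f_rot = 2.6, f_beat = 55, noise_sigma = 0,
                           dropout_prob = 0, wobble_amplitude = 0,
                           n_frames = 6000, seed = 10)
  sim <- simulate_track(cfg)
  t <- (0:5999) / 200
  fl <- flagellar_angle(sim$track)
  expect_equal(fl$theta, wrap_to_pi(0.6 * sin(2 * pi * 55 * t)),
               tolerance = 1e-12)
  expect_equal(fl$theta, wrap_to_pi(sim$truth$theta_flag), tolerance = 1e-12)

  body <- body_axis_angle(sim$track)
  cum <- unwrap_cumulative(body)
  expect_equal(cum$theta, sim$truth$theta_body - sim$truth$theta_body[1],
               tolerance = 1e-9)
  rot <- fit_rotation(cum, "c")
  expect_equal(rot$omega, 2 * pi * 2.6, tolerance = 1e-9)

  be <- estimate_beat_frequency(fl)
  expect_lte(abs(be$peak_hz - 55), be$df)
  re <- estimate_rotation_frequency(body)
  expect_lte(abs(re$peak_hz - 2.6), re$df)
})

test_that("the same seed reproduces a track bitwise, on disk too", {
  cfg <- simulation_config(f_rot = 4.3, f_beat = 67.1, n_frames = 500,
                           seed = 77)
  a <- simulate_track(cfg)
  b <- simulate_track(cfg)
  expect_identical(a$track$frames, b$track$frames)
  expect_identical(a$truth, b$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_dlc_csv(a$track, f1)
  write_dlc_csv(b$track, f2)
  expect_identical(readLines(f1), readLines(f2))

  c2 <- simulate_track(simulation_config(f_rot = 4.3, f_beat = 67.1,
                                         n_frames = 500, seed = 78))
  expect_false(identical(a$track$frames, c2$track$frames))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(simulate_track(simulation_config(f_rot = 1, f_beat = 30,
                                             n_frames = 100, seed = 5)))
  expect_identical(runif(3), before)
})

test_that("dropout frames occur at the configured rate and are sub-threshold", {
  cfg <- simulation_config(f_rot = 4.3, f_beat = 67.1, n_frames = 50000,
                           dropout_prob = 0.1, seed = 8)
  sim <- simulate_track(cfg)
  frac <- mean(sim$track$frames$tip_l < 0.95)
  sd3 <- 3 * sqrt(0.1 * 0.9 / 50000)
  expect_lt(abs(frac - 0.1), sd3)
  # dropout flags and sub-threshold likelihoods coincide exactly
  expect_identical(sim$track$frames$frame[sim$track$frames$tip_l < 0.95],
                   sim$truth$dropout_frames)
})

test_that("negating the rotation rate flips direction, not magnitudes", {
  mk <- function(f_rot) {
    simulate_track(simulation_config(f_rot = f_rot, f_beat = 48,
                                     n_frames = 4000, noise_sigma = 0.5,
                                     dropout_prob = 0, seed = 12))
  }
  pos <- mk(3.1)
  neg <- mk(-3.1)
  rp <- fit_rotation(unwrap_cumulative(body_axis_angle(pos$track)), "p")
  rn <- fit_rotation(unwrap_cumulative(body_axis_angle(neg$track)), "n")
  expect_identical(rp$direction, "CCW")
  expect_identical(rn$direction, "CW")
  # localization noise is not mirrored with the signal, so the refined
  # estimates agree only up to the noise scale, far below one bin
  ep <- estimate_rotation_frequency(body_axis_angle(pos$track))
  en <- estimate_rotation_frequency(body_axis_angle(neg$track))
  expect_lt(abs(ep$peak_hz - en$peak_hz), ep$df / 10)
  bp <- estimate_beat_frequency(flagellar_angle(pos$track))
  bn <- estimate_beat_frequency(flagellar_angle(neg$track))
  expect_lt(abs(bp$peak_hz - bn$peak_hz), bp$df / 10)
})

test_that("degenerate jitter returns the preset frequencies exactly", {
  p <- draw_cohort_params(1, "live", base_seed = 4, jitter = 0)
  expect_equal(p$f_beat, 67.1, tolerance = 1e-12)
  expect_equal(abs(p$f_rot), 4.3, tolerance = 1e-12)
  pd <- draw_cohort_params(1, "demembranated", base_seed = 4, jitter = 0)
  expect_equal(pd$f_beat, 46.5, tolerance = 1e-12)
  expect_equal(abs(pd$f_rot), 1.7, tolerance = 1e-12)
})

test_that("cohort mixing and medians match their presets at scale", {
  p <- draw_cohort_params(10000, "live", base_seed = 6)
  cw_frac <- mean(p$direction == "CW")
  p_cw <- 2 / 46
  expect_lt(abs(cw_frac - p_cw), 3 * sqrt(p_cw * (1 - p_cw) / 10000))
  expect_lt(abs(median(abs(p$f_rot)) - 4.3) / 4.3, 0.02)
  expect_lt(abs(median(p$f_beat) - 67.1) / 67.1, 0.02)
  expect_true(all(p$f_beat < 100))

  pd <- draw_cohort_params(10000, "demembranated", base_seed = 6)
  p_cw_d <- 10 / 56
  expect_lt(abs(mean(pd$direction == "CW") - p_cw_d),
            3 * sqrt(p_cw_d * (1 - p_cw_d) / 10000))
  expect_lt(abs(median(abs(pd$f_rot)) - 1.7) / 1.7, 0.02)
})

test_that("invalid configurations are rejected", {
  expect_flagrot_error(simulation_config(f_rot = 4.3, f_beat = 150),
                       "flagrot_validation_error")
  expect_flagrot_error(simulation_config(f_rot = 120, f_beat = 50),
                       "flagrot_validation_error")
  expect_flagrot_error(simulation_config(f_rot = 1, f_beat = 50,
                                         dropout_prob = 1),
                       "flagrot_validation_error")
  expect_flagrot_error(simulation_config(f_rot = 1, f_beat = 50,
                                         beat_amplitude = 4),
                       "flagrot_validation_error")
  expect_error(simulate_cohort(3, "frozen"))
})

test_that("cohorts export as pipeline-ready files with truth sidecars", {
  dir <- tempfile()
  co <- simulate_cohort(3, "live", base_seed = 2, n_frames = 300)
  write_cohort(co, dir)
  files <- list.files(file.path(dir, "live"))
  expect_setequal(files, c("cell_000.csv", "cell_001.csv", "cell_002.csv",
                           "cell_000_truth.json", "cell_001_truth.json",
                           "cell_002_truth.json"))
  tr <- read_dlc_csv(file.path(dir, "live", "cell_001.csv"), fps = 200,
                     condition = "live")
  expect_equal(tr$frames, co[[2]]$track$frames, ignore_attr = TRUE)
  truth <- jsonlite::read_json(file.path(dir, "live", "cell_001_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$f_rot_hz, co[[2]]$truth$f_rot)
  expect_equal(truth$f_beat_hz, co[[2]]$truth$f_beat)
})
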