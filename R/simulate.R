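# Ground-truthed synthetic landmark trajectories.
#
# Kinematic model (per frame time t):
#   body angle   Theta_b(t) = theta0 + 2 pi f_rot t + wobble * sin(2 pi f_beat t)
#   body axis    u(t) = (cos Theta_b, sin Theta_b)
#   posterior    = center - body_len * u(t)
#   base         = center
#   flag angle   theta_f(t) = beat_mean + beat_amplitude * sin(2 pi f_beat t)
#   tip          = base + flag_len * R(theta_f) u(t)
# so the kinematics stage recovers theta_f and Theta_b exactly in the
# noise-free case. Independent Gaussian localization noise is added per
# coordinate; each frame is independently a dropout with probability
# dropout_prob, in which case the tip receives an additional large
# displacement (uniform in a disc of radius 5 * flag_len) and all three
# likelihoods are drawn from the dropout range instead of the good range.

#' Build a validated simulation configuration
#'
#' Defaults emulate the recording conditions the pipeline targets: 200
#' frames per second for about a minute (12,607 frames), a cell body of
#' ~10 um (40 px at 4.14 px/um) rotating at a constant rate while the
#' flagellar angle oscillates sinusoidally, 1 px localization noise and 5%
#' likelihood-dropout frames.
#'
#' @param f_rot signed body rotation rate in Hz (positive = CCW); magnitude
#'   must be below fps/2.
#' @param f_beat flagellar beat frequency in Hz, in (0, fps/2).
#' @param fps frame rate (default 200).
#' @param n_frames number of frames (default 12607).
#' @param beat_amplitude flagellar angle oscillation amplitude in radians
#'   (default 0.6).
#' @param beat_mean mean flagellar angle in radians (default 0).
#' @param body_len posterior-to-base distance in pixels (default 40).
#' @param flag_len base-to-tip distance in pixels (default 45).
#' @param center fixed base position, math-convention pixels (default
#'   `c(150, -150)` so the exported image-convention file resembles a
#'   300 x 300 px crop).
#' @param wobble_amplitude body-angle modulation at the beat frequency, in
#'   radians (default 0.05); puts a realistic beat-frequency satellite into
#'   the rotation spectrum.
#' @param noise_sigma Gaussian localization noise per coordinate, pixels
#'   (default 1).
#' @param dropout_prob per-frame probability of a low-likelihood dropout
#'   frame (default 0.05).
#' @param dropout_likelihood_range,good_likelihood_range likelihood draw
#'   ranges for dropout and normal frames.
#' @param theta0 initial body angle in radians (default 0).
#' @param seed integer RNG seed making the track reproducible.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(f_rot, f_beat, fps = 200, n_frames = 12607,
                              beat_amplitude = 0.6, beat_mean = 0,
                              body_len = 40, flag_len = 45,
                              center = c(150, -150),
                              wobble_amplitude = 0.05, noise_sigma = 1,
                              dropout_prob = 0.05,
                              dropout_likelihood_range = c(0, 0.95),
                              good_likelihood_range = c(0.95, 1),
                              theta0 = 0, seed = 1) {
  if (fps <= 0) abort_validation("fps must be > 0")
  if (n_frames < 1) abort_validation("n_frames must be >= 1")
  if (f_rot != 0 && abs(f_rot) >= fps / 2) {
    abort_validation("|f_rot| must be below the Nyquist frequency fps/2")
  }
  if (!(f_beat > 0 && f_beat < fps / 2)) {
    abort_validation("f_beat must lie in (0, fps/2)")
  }
  if (!(dropout_prob >= 0 && dropout_prob < 1)) {
    abort_validation("dropout_prob must lie in [0, 1)")
  }
  if (!(beat_amplitude > 0 && beat_amplitude < pi)) {
    abort_validation("beat_amplitude must lie in (0, pi)")
  }
  if (noise_sigma < 0) abort_validation("noise_sigma must be >= 0")
  if (body_len <= 0 || flag_len <= 0) {
    abort_validation("body_len and flag_len must be > 0")
  }
  structure(
    list(f_rot = f_rot, f_beat = f_beat, fps = fps, n_frames = n_frames,
         beat_amplitude = beat_amplitude, beat_mean = beat_mean,
         body_len = body_len, flag_len = flag_len, center = center,
         wobble_amplitude = wobble_amplitude, noise_sigma = noise_sigma,
         dropout_prob = dropout_prob,
         dropout_likelihood_range = dropout_likelihood_range,
         good_likelihood_range = good_likelihood_range,
         theta0 = theta0, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate one landmark track with ground truth
#'
#' Generates a synthetic cell track under the model described in
#' [simulation_config()]. Deterministic given the seed: the random draws are
#' made in a fixed order (dropout flags, coordinate noise, tip dropout
#' displacement, likelihoods) under a locally seeded RNG, leaving the
#' caller's RNG state untouched.
#'
#' @param config a `sim_config` from [simulation_config()].
#' @param cell_id identifier (default `"sim"`).
#' @param condition `"live"` or `"demembranated"` (metadata only; default
#'   `"live"`).
#' @return list with `track` (a [cell_track()]) and `truth` (class
#'   `ground_truth`: exact `theta_body` unwrapped, `theta_flag`, `f_rot`,
#'   `f_beat`, `direction`, `dropout_frames`, `seed`).
#' @export
simulate_track <- function(config, cell_id = "sim", condition = "live") {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  n <- cf$n_frames
  t <- (0:(n - 1)) / cf$fps
  theta_body <- cf$theta0 + 2 * pi * cf$f_rot * t +
    cf$wobble_amplitude * sin(2 * pi * cf$f_beat * t)
  theta_flag <- cf$beat_mean + cf$beat_amplitude * sin(2 * pi * cf$f_beat * t)
  ux <- cos(theta_body)
  uy <- sin(theta_body)
  base_x <- rep(cf$center[1], n)
  base_y <- rep(cf$center[2], n)
  post_x <- base_x - cf$body_len * ux
  post_y <- base_y - cf$body_len * uy
  tip_x <- base_x + cf$flag_len * cos(theta_body + theta_flag)
  tip_y <- base_y + cf$flag_len * sin(theta_body + theta_flag)

  draws <- with_seed(cf$seed, {
    dropout <- stats::runif(n) < cf$dropout_prob
    noise <- matrix(stats::rnorm(6 * n, sd = cf$noise_sigma), nrow = n)
    disc_r <- 5 * cf$flag_len * sqrt(stats::runif(n))
    disc_a <- 2 * pi * stats::runif(n)
    lik <- matrix(stats::runif(3 * n), nrow = n)
    list(dropout = dropout, noise = noise, disc_r = disc_r, disc_a = disc_a,
         lik = lik)
  })
  dropout <- draws$dropout
  tip_x <- tip_x + draws$noise[, 1]
  tip_y <- tip_y + draws$noise[, 2]
  base_x <- base_x + draws$noise[, 3]
  base_y <- base_y + draws$noise[, 4]
  post_x <- post_x + draws$noise[, 5]
  post_y <- post_y + draws$noise[, 6]
  tip_x[dropout] <- tip_x[dropout] +
    draws$disc_r[dropout] * cos(draws$disc_a[dropout])
  tip_y[dropout] <- tip_y[dropout] +
    draws$disc_r[dropout] * sin(draws$disc_a[dropout])
  lo <- ifelse(dropout, cf$dropout_likelihood_range[1],
               cf$good_likelihood_range[1])
  hi <- ifelse(dropout, cf$dropout_likelihood_range[2],
               cf$good_likelihood_range[2])
  lik <- lo + draws$lik * (hi - lo)

  frames <- data.frame(
    frame = 0:(n - 1),
    tip_x = tip_x, tip_y = tip_y, tip_l = lik[, 1],
    base_x = base_x, base_y = base_y, base_l = lik[, 2],
    post_x = post_x, post_y = post_y, post_l = lik[, 3]
  )
  track <- cell_track(frames, cell_id = cell_id, condition = condition,
                      fps = cf$fps, scorer = "synthetic")
  truth <- structure(
    list(theta_body = theta_body, theta_flag = theta_flag,
         f_rot = cf$f_rot, f_beat = cf$f_beat,
         direction = if (cf$f_rot > 0) "CCW" else if (cf$f_rot < 0) "CW"
                     else "indeterminate",
         dropout_frames = frames$frame[dropout], seed = cf$seed),
    class = "ground_truth"
  )
  list(track = track, truth = truth)
}

#' Cohort presets
#'
#' Median frequencies and clockwise mixing probabilities for the two
#' conditions: live cells (beat 67.1 Hz, rotation 4.3 Hz, CW probability
#' 2/46) and demembranated, ATP-reactivated cell models (46.5 Hz, 1.7 Hz,
#' CW probability 10/56).
#'
#' @param preset `"live"` or `"demembranated"`.
#' @return list with `f_beat_median`, `f_rot_median`, `p_cw`.
#' @export
cohort_preset <- function(preset = c("live", "demembranated")) {
  preset <- match.arg(preset)
  if (preset == "live") {
    list(f_beat_median = 67.1, f_rot_median = 4.3, p_cw = 2 / 46)
  } else {
    list(f_beat_median = 46.5, f_rot_median = 1.7, p_cw = 10 / 56)
  }
}

#' Draw per-cell cohort parameters
#'
#' Per-cell beat and rotation frequencies are drawn log-normally around the
#' preset medians (log-normal jitter has positive support and preserves the
#' median, the cohort summary statistic). `jitter` is the relative standard
#' deviation of the per-cell frequencies; `jitter = 0` returns the preset
#' medians exactly. Beat draws at or above the Nyquist frequency fps/2 are
#' redrawn so every cell satisfies the simulator's validity invariant (at
#' default settings this affects well under 1% of draws). Each cell is
#' independently clockwise with the preset mixing probability.
#'
#' @param n_cells number of cells.
#' @param preset `"live"` or `"demembranated"`.
#' @param base_seed integer seed for the parameter draws.
#' @param jitter relative s.d. of per-cell frequencies (default 0.15).
#' @param fps frame rate, used for the Nyquist bound (default 200).
#' @return data frame with columns `cell_id`, `f_beat`, `f_rot` (signed),
#'   `direction`, `seed` (per-cell track seed, `base_seed + index`).
#' @export
draw_cohort_params <- function(n_cells, preset = c("live", "demembranated"),
                               base_seed = 1, jitter = 0.15, fps = 200) {
  preset <- match.arg(preset)
  if (n_cells < 1) abort_validation("n_cells must be >= 1")
  ps <- cohort_preset(preset)
  sdlog <- sqrt(log1p(jitter^2))
  with_seed(base_seed, {
    f_beat <- stats::rlnorm(n_cells, meanlog = log(ps$f_beat_median),
                            sdlog = sdlog)
    while (any(bad <- f_beat >= fps / 2)) {
      f_beat[bad] <- stats::rlnorm(sum(bad),
                                   meanlog = log(ps$f_beat_median),
                                   sdlog = sdlog)
    }
    f_rot_mag <- stats::rlnorm(n_cells, meanlog = log(ps$f_rot_median),
                               sdlog = sdlog)
    cw <- stats::runif(n_cells) < ps$p_cw
    data.frame(
      cell_id = sprintf("cell_%03d", seq_len(n_cells) - 1),
      f_beat = f_beat,
      f_rot = ifelse(cw, -f_rot_mag, f_rot_mag),
      direction = ifelse(cw, "CW", "CCW"),
      seed = base_seed + seq_len(n_cells)
    )
  })
}

#' Simulate a cohort of cells under a condition preset
#'
#' Draws per-cell frequencies and directions with [draw_cohort_params()] and
#' simulates one track per cell. Per-cell track seeds are derived
#' deterministically from `base_seed + cell index`.
#'
#' @inheritParams draw_cohort_params
#' @param ... further [simulation_config()] settings applied to every cell
#'   (e.g. `n_frames`, `noise_sigma`, `dropout_prob`).
#' @return list of `list(track, truth)` pairs, one per cell.
#' @export
simulate_cohort <- function(n_cells, preset = c("live", "demembranated"),
                            base_seed = 1, jitter = 0.15, ...) {
  preset <- match.arg(preset)
  extra <- list(...)
  fps <- extra$fps %||% 200
  params <- draw_cohort_params(n_cells, preset, base_seed, jitter, fps = fps)
  lapply(seq_len(n_cells), function(i) {
    cfg <- do.call(simulation_config,
                   c(list(f_rot = params$f_rot[i], f_beat = params$f_beat[i],
                          seed = params$seed[i]), extra))
    simulate_track(cfg, cell_id = params$cell_id[i], condition = preset)
  })
}

#' Write a simulated cohort to disk in pipeline-ready form
#'
#' Emits one DeepLabCut-dialect CSV per cell under
#' `dir/<condition>/<cell_id>.csv` plus a ground-truth JSON sidecar
#' `<cell_id>_truth.json` (keys: `f_rot_hz`, `f_beat_hz`, `direction`,
#' `seed`, `dropout_frames`).
#'
#' @param cohort list of `list(track, truth)` pairs from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the condition subdirectory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(length(cohort) >= 1)
  condition <- cohort[[1]]$track$condition
  sub <- file.path(dir, condition)
  dir.create(sub, recursive = TRUE, showWarnings = FALSE)
  for (cell in cohort) {
    id <- cell$track$cell_id
    write_dlc_csv(cell$track, file.path(sub, paste0(id, ".csv")))
    truth <- cell$truth
    jsonlite::write_json(
      list(f_rot_hz = truth$f_rot, f_beat_hz = truth$f_beat,
           direction = truth$direction, seed = truth$seed,
           dropout_frames = as.integer(truth$dropout_frames)),
      file.path(sub, paste0(id, "_truth.json")),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(sub)
}
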