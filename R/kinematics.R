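# Angle time series from landmark coordinates.
#
# Body angle: planar angle of the posterior->base vector (the body axis).
# Flagellar angle: signed angle from the posterior->base vector to the
# base->tip vector, positive counterclockwise. A frame is valid for an angle
# only if every landmark that angle consumes passes the likelihood threshold
# and the vectors involved are non-degenerate.

#' Construct an angle series
#'
#' A time-indexed angle signal with a per-frame validity mask. Carries the
#' body angle, the flagellar angle, or the unwrapped cumulative angle.
#'
#' @param frame integer frame indices (strictly increasing).
#' @param t time in seconds per sample (strictly increasing).
#' @param theta angle in radians per sample; `NA` where invalid. For kinds
#'   other than `"cumulative"` valid values must lie in (-pi, pi].
#' @param valid logical validity mask.
#' @param kind `"body"`, `"flagellar"` or `"cumulative"`.
#' @param fps frame rate the series was sampled at.
#' @return object of class `angle_series`.
#' @export
angle_series <- function(frame, t, theta, valid,
                         kind = c("body", "flagellar", "cumulative"), fps) {
  kind <- match.arg(kind)
  n <- length(theta)
  if (length(t) != n || length(valid) != n || length(frame) != n) {
    abort_validation("frame, t, theta and valid must have equal length")
  }
  if (n > 1 && any(diff(t) <= 0)) {
    abort_validation("t must be strictly increasing")
  }
  if (kind != "cumulative") {
    th <- theta[valid]
    if (any(!is.finite(th)) || any(th <= -pi | th > pi)) {
      abort_validation("valid wrapped angles must lie in (-pi, pi]")
    }
  }
  structure(list(frame = frame, t = t, theta = theta,
                 valid = as.logical(valid), kind = kind, fps = fps),
            class = "angle_series")
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series:%s> %d samples (%d valid) @ %g fps\n",
              x$kind, length(x$theta), sum(x$valid), x$fps))
  invisible(x)
}

#' @export
as.data.frame.angle_series <- function(x, ...) {
  data.frame(frame = x$frame, t_s = x$t, theta_rad = x$theta, valid = x$valid)
}

#' Export an angle series as tidy CSV
#'
#' Columns: `frame`, `t_s`, `theta_rad`, `valid`.
#' @param series an [angle_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_angle_series <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Wrap angles to the interval (-pi, pi]
#'
#' The boundary maps to +pi: `wrap_to_pi(pi)` and `wrap_to_pi(-pi)` are both
#' `pi`. The result equals the input modulo 2*pi.
#'
#' @param angle numeric vector of finite angles in radians.
#' @return angles in (-pi, pi].
#' @export
wrap_to_pi <- function(angle) {
  if (any(!is.finite(angle))) abort_validation("angle must be finite")
  r <- angle %% (2 * pi)
  r[r > pi] <- r[r > pi] - 2 * pi
  # %% can return 2*pi for tiny negative inputs through rounding
  r[r > pi] <- pi
  r
}

angle_mask <- function(lik_list, len_list, likelihood_threshold,
                       degenerate_eps) {
  valid <- Reduce(`&`, lapply(lik_list, function(l) l >= likelihood_threshold))
  for (len in len_list) valid <- valid & (len > degenerate_eps)
  valid
}

#' Body-axis angle time series
#'
#' The body angle at each frame is the planar angle of the vector from the
#' cell posterior to the flagellar base, in (-pi, pi]. A frame is valid when
#' both landmarks meet the likelihood threshold and the axis vector is longer
#' than `degenerate_eps`.
#'
#' @param track a [cell_track()].
#' @param likelihood_threshold minimum landmark likelihood (default 0.95,
#'   the conventional pose-confidence cutoff).
#' @param degenerate_eps minimum vector length in pixels below which a frame
#'   is marked invalid rather than producing an undefined angle.
#' @return an [angle_series()] of kind `"body"`.
#' @export
body_axis_angle <- function(track, likelihood_threshold = 0.95,
                            degenerate_eps = 1e-9) {
  stopifnot(inherits(track, "cell_track"))
  fr <- track$frames
  if (nrow(fr) == 0) abort_insufficient("track has no frames")
  dx <- fr$base_x - fr$post_x
  dy <- fr$base_y - fr$post_y
  len <- sqrt(dx^2 + dy^2)
  valid <- angle_mask(list(fr$base_l, fr$post_l), list(len),
                      likelihood_threshold, degenerate_eps)
  theta <- rep(NA_real_, nrow(fr))
  theta[valid] <- wrap_to_pi(atan2(dy[valid], dx[valid]))
  angle_series(fr$frame, fr$frame / track$fps, theta, valid,
               kind = "body", fps = track$fps)
}

#' Flagellar angle time series
#'
#' The flagellar angle at each frame is the signed angle from the body-axis
#' vector (posterior to base) to the flagellar vector (base to tip), in
#' (-pi, pi], positive counterclockwise. Validity requires all three
#' landmarks to meet the likelihood threshold and both vectors to be
#' non-degenerate.
#'
#' @inheritParams body_axis_angle
#' @return an [angle_series()] of kind `"flagellar"`.
#' @export
flagellar_angle <- function(track, likelihood_threshold = 0.95,
                            degenerate_eps = 1e-9) {
  stopifnot(inherits(track, "cell_track"))
  fr <- track$frames
  if (nrow(fr) == 0) abort_insufficient("track has no frames")
  ax <- fr$base_x - fr$post_x
  ay <- fr$base_y - fr$post_y
  fx <- fr$tip_x - fr$base_x
  fy <- fr$tip_y - fr$base_y
  alen <- sqrt(ax^2 + ay^2)
  flen <- sqrt(fx^2 + fy^2)
  valid <- angle_mask(list(fr$tip_l, fr$base_l, fr$post_l),
                      list(alen, flen), likelihood_threshold, degenerate_eps)
  theta <- rep(NA_real_, nrow(fr))
  theta[valid] <- wrap_to_pi(atan2(fy[valid], fx[valid]) -
                               atan2(ay[valid], ax[valid]))
  angle_series(fr$frame, fr$frame / track$fps, theta, valid,
               kind = "flagellar", fps = track$fps)
}

#' Unwrap a wrapped angle series to a cumulative angle
#'
#' Accumulates wrapped angle increments over valid samples so that full
#' turns add up instead of wrapping at +/-pi. The cumulative angle starts at
#' zero at the first valid sample. Consecutive valid samples further apart
#' than `max_gap_frames` contribute a zero increment: rotation is never
#' extrapolated across long tracking gaps, which biases the total
#' conservatively rather than inventing turns. Unwrapping assumes less than
#' half a turn between consecutive valid samples, amply satisfied at
#' hundreds of frames per second and a few turns per second.
#'
#' @param series an [angle_series()] of kind `"body"` or `"flagellar"`.
#' @param max_gap_frames largest frame gap (in frames) across which angle
#'   increments are still accumulated (default 5).
#' @return an [angle_series()] of kind `"cumulative"` with the same mask.
#' @export
unwrap_cumulative <- function(series, max_gap_frames = 5) {
  stopifnot(inherits(series, "angle_series"))
  if (series$kind == "cumulative") {
    abort_validation("series is already cumulative")
  }
  if (max_gap_frames < 1) abort_validation("max_gap_frames must be >= 1")
  v <- which(series$valid)
  if (length(v) < 2) {
    abort_insufficient("need at least 2 valid samples to unwrap")
  }
  inc <- wrap_to_pi(diff(series$theta[v]))
  gap <- diff(series$frame[v])
  inc[gap > max_gap_frames] <- 0
  cum <- c(0, cumsum(inc))
  theta <- rep(NA_real_, length(series$theta))
  theta[v] <- cum
  angle_series(series$frame, series$t, theta, series$valid,
               kind = "cumulative", fps = series$fps)
}
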