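# Rotational velocity and direction from the cumulative body angle, plus
# cohort-level direction and box statistics.

#' Fit rotational velocity from a cumulative angle series
#'
#' The signed angular velocity omega is the ordinary-least-squares slope of
#' the cumulative angle against time over valid samples (closed form
#' cov(t, theta) / var(t)). Direction is assigned from the sign of omega
#' with a dead band: `CCW` for omega > omega_min, `CW` for
#' omega < -omega_min, otherwise `indeterminate`. Tracks whose valid
#' fraction falls below `min_valid_fraction` are labelled indeterminate
#' regardless of the slope. Set `omega_min = 0` to force a CW/CCW call for
#' every track with any nonzero slope.
#'
#' @param cumulative an [angle_series()] of kind `"cumulative"`.
#' @param cell_id identifier carried into the result.
#' @param min_valid_fraction minimum fraction of valid frames required for a
#'   direction call (default 0.5).
#' @param omega_min dead band in rad/s around zero slope (default 0.05).
#' @return object of class `rotation_result` with fields `cell_id`, `omega`
#'   (rad/s, positive = CCW), `rotation_hz` (omega / 2 pi), `direction`,
#'   `n_valid`, `valid_fraction`, `residual_rms` (radians), `overridden`.
#' @export
fit_rotation <- function(cumulative, cell_id = "cell",
                         min_valid_fraction = 0.5, omega_min = 0.05) {
  stopifnot(inherits(cumulative, "angle_series"))
  if (cumulative$kind != "cumulative") {
    abort_validation("fit_rotation requires a cumulative angle series")
  }
  v <- cumulative$valid
  n_valid <- sum(v)
  if (n_valid < 2) abort_insufficient("need at least 2 valid samples")
  tt <- cumulative$t[v]
  th <- cumulative$theta[v]
  tc <- tt - mean(tt)
  omega <- sum(tc * th) / sum(tc^2)
  intercept <- mean(th) - omega * mean(tt)
  residual_rms <- sqrt(mean((th - (intercept + omega * tt))^2))
  valid_fraction <- n_valid / length(v)
  direction <- if (valid_fraction < min_valid_fraction) {
    "indeterminate"
  } else if (omega > omega_min) {
    "CCW"
  } else if (omega < -omega_min) {
    "CW"
  } else {
    "indeterminate"
  }
  structure(
    list(cell_id = as.character(cell_id), omega = omega,
         rotation_hz = omega / (2 * pi), direction = direction,
         n_valid = n_valid, valid_fraction = valid_fraction,
         residual_rms = residual_rms, overridden = FALSE),
    class = "rotation_result"
  )
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf("<rotation_result> %s: omega = %.4g rad/s (%.3g Hz), %s%s\n",
              x$cell_id, x$omega, x$rotation_hz, x$direction,
              if (x$overridden) " [overridden]" else ""))
  invisible(x)
}

#' Apply visual-inspection direction overrides
#'
#' Slope-based direction calls can be wrong for noisy tracks; where the
#' rotation direction has been verified by eye, the override table replaces
#' the fitted label. The fitted omega is left untouched and the result is
#' flagged `overridden`. Overrides for unknown cell ids are ignored with a
#' warning. Applying the same table twice is idempotent.
#'
#' @param results list of `rotation_result` objects.
#' @param overrides named character vector from [read_overrides()] (names =
#'   cell ids, values = `"CCW"`/`"CW"`), or `NULL` for no-op.
#' @return the list with overridden entries replaced.
#' @export
apply_overrides <- function(results, overrides) {
  if (is.null(overrides) || length(overrides) == 0) return(results)
  ids <- vapply(results, function(r) r$cell_id, character(1))
  unknown <- setdiff(names(overrides), ids)
  if (length(unknown) > 0) {
    warning("override(s) for unknown cell_id ignored: ",
            paste(unknown, collapse = ", "))
  }
  for (i in seq_along(results)) {
    id <- results[[i]]$cell_id
    if (id %in% names(overrides)) {
      results[[i]]$direction <- unname(overrides[[id]])
      results[[i]]$overridden <- TRUE
    }
  }
  results
}

direction_labels <- function(results) {
  if (is.data.frame(results)) {
    as.character(results$direction)
  } else if (is.character(results)) {
    results
  } else {
    vapply(results, function(r) r$direction, character(1))
  }
}

#' Summarize rotation directions for one condition
#'
#' Counts CCW, CW and indeterminate calls and reports the clockwise
#' percentage among directed cells, `100 * n_cw / (n_ccw + n_cw)`, rounded
#' to one decimal place.
#'
#' @param results list of `rotation_result`s, a data frame with a
#'   `direction` column, or a character vector of direction labels.
#' @param condition condition label carried into the summary.
#' @return one-row data frame with columns `condition`, `n_total`, `n_ccw`,
#'   `n_cw`, `n_indeterminate`, `pct_cw`.
#' @export
summarize_directions <- function(results, condition = "all") {
  dirs <- direction_labels(results)
  if (length(dirs) == 0) abort_insufficient("no results to summarize")
  n_ccw <- sum(dirs == "CCW")
  n_cw <- sum(dirs == "CW")
  n_ind <- sum(dirs == "indeterminate")
  pct_cw <- if (n_ccw + n_cw > 0) round(100 * n_cw / (n_ccw + n_cw), 1) else NA_real_
  data.frame(condition = condition, n_total = length(dirs), n_ccw = n_ccw,
             n_cw = n_cw, n_indeterminate = n_ind, pct_cw = pct_cw)
}

#' Select the top-k counterclockwise rotators
#'
#' Returns the CCW-labelled results with the largest angular velocities,
#' mirroring the convention of characterizing frequencies on the fastest
#' counterclockwise cells. Ties at the cut are broken by cell_id ascending
#' so the selection is deterministic.
#'
#' @param results list of `rotation_result`s.
#' @param k number of cells to keep (default 10). If fewer CCW cells exist,
#'   all are returned with a message.
#' @return list of `rotation_result`s, omega descending.
#' @export
top_k_ccw <- function(results, k = 10) {
  ccw <- Filter(function(r) r$direction == "CCW", results)
  if (length(ccw) == 0) return(list())
  om <- vapply(ccw, function(r) r$omega, numeric(1))
  ids <- vapply(ccw, function(r) r$cell_id, character(1))
  ord <- order(-om, ids)
  if (length(ccw) < k) {
    message(sprintf("only %d CCW cells available (k = %d); returning all",
                    length(ccw), k))
  }
  ccw[ord][seq_len(min(k, length(ccw)))]
}

#' Box-plot statistics with 1.5 IQR whiskers
#'
#' Median and quartiles (linear-interpolation quantile rule, R type 7) with
#' whiskers at the extreme data values lying within 1.5 times the
#' interquartile range from the first and third quartiles.
#'
#' @param values numeric vector, length >= 1.
#' @return one-row data frame: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `n`.
#' @export
box_stats <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort_insufficient("box_stats needs >= 1 value")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  data.frame(median = q[2], q1 = q[1], q3 = q[3],
             whisker_low = min(values[values >= lo_fence]),
             whisker_high = max(values[values <= hi_fence]),
             n = length(values))
}

#' Percent reduction of a comparison value relative to a reference
#'
#' `100 * (reference - comparison) / reference`. Used to express how much a
#' median frequency drops between conditions.
#'
#' @param reference positive reference value.
#' @param comparison comparison value.
#' @return percent reduction (positive when comparison < reference).
#' @export
percent_reduction <- function(reference, comparison) {
  if (!is.numeric(reference) || any(reference <= 0)) {
    abort_domain("reference must be > 0")
  }
  100 * (reference - comparison) / reference
}

#' Per-cell rotation results as a data frame
#' @param results list of `rotation_result`s.
#' @return data frame, one row per cell.
#' @export
rotation_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(cell_id = r$cell_id, omega_rad_s = r$omega,
               rotation_hz = r$rotation_hz, direction = r$direction,
               n_valid = r$n_valid, valid_fraction = r$valid_fraction,
               residual_rms = r$residual_rms, overridden = r$overridden)
  }))
}
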