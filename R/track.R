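#' Construct a cell track
#'
#' A `cell_track` holds the per-frame landmark observations for one cell:
#' the flagellar tip, the flagellar base, and the posterior end of the cell
#' body, each with an x/y position (internal mathematical convention,
#' y increasing upwards) and a tracking-confidence score ("likelihood") in
#' \[0, 1\] as emitted by marker-less pose estimators.
#'
#' @param frames data frame with columns `frame` (integer, strictly
#'   increasing), and for each of `tip`, `base`, `post`: `<part>_x`,
#'   `<part>_y` (pixels, math convention) and `<part>_l` (likelihood).
#' @param cell_id character scalar identifying the cell.
#' @param condition `"live"` or `"demembranated"`.
#' @param fps acquisition frame rate in frames per second (> 0).
#' @param px_per_um optional pixel scale (pixels per micron).
#' @param scorer name recorded in the CSV scorer header row.
#' @param bodyparts named character vector mapping roles
#'   `c(tip=, base=, posterior=)` to the body-part names used in the CSV
#'   header.
#'
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(frames, cell_id, condition = c("live", "demembranated"),
                       fps, px_per_um = NULL, scorer = "flagrot",
                       bodyparts = c(tip = "tip", base = "base",
                                     posterior = "posterior")) {
  condition <- match.arg(condition)
  needed <- c("frame",
              "tip_x", "tip_y", "tip_l",
              "base_x", "base_y", "base_l",
              "post_x", "post_y", "post_l")
  missing_cols <- setdiff(needed, names(frames))
  if (length(missing_cols) > 0) {
    abort_validation(paste0("frames is missing column(s): ",
                            paste(missing_cols, collapse = ", ")))
  }
  frames <- as.data.frame(frames)[, needed]
  if (!is.numeric(fps) || length(fps) != 1 || !is.finite(fps) || fps <= 0) {
    abort_validation("fps must be a single positive number")
  }
  n <- nrow(frames)
  if (n > 0) {
    if (any(diff(frames$frame) <= 0)) {
      abort_validation("frame indices must be strictly increasing")
    }
    coords <- as.matrix(frames[, c("tip_x", "tip_y", "base_x", "base_y",
                                   "post_x", "post_y")])
    if (any(!is.finite(coords))) {
      abort_validation("landmark coordinates must be finite")
    }
    lik <- as.matrix(frames[, c("tip_l", "base_l", "post_l")])
    if (any(!is.finite(lik)) || any(lik < 0) || any(lik > 1)) {
      abort_validation("likelihoods must lie in [0, 1]")
    }
  }
  structure(
    list(cell_id = as.character(cell_id), condition = condition, fps = fps,
         px_per_um = px_per_um, scorer = scorer, bodyparts = bodyparts,
         frames = frames),
    class = "cell_track"
  )
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> %s (%s): %d frames @ %g fps\n",
              x$cell_id, x$condition, nrow(x$frames), x$fps))
  invisible(x)
}

#' Number of frames in a track
#' @param track a `cell_track`.
#' @return integer frame count.
#' @export
n_frames <- function(track) {
  stopifnot(inherits(track, "cell_track"))
  nrow(track$frames)
}
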