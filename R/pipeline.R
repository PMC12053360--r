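# Per-cell analysis and cohort aggregation.

#' Build a run configuration
#'
#' Bundles every tunable of the per-cell analysis: frame rate, likelihood
#' threshold, pixel scale, spectral search bands, top-k subset size and the
#' slope-fit dead band.
#'
#' @param fps frame rate in Hz (default 200).
#' @param likelihood_threshold pose-confidence cutoff below which a frame is
#'   masked (default 0.95).
#' @param px_per_um pixel scale (default 4.14 px per micron).
#' @param beat_band flagellar beat search band in Hz (default 10-100).
#' @param rotation_band body rotation search band in Hz (default 0.2-20).
#' @param top_k size of the fastest-CCW subset used for frequency summaries
#'   (default 10).
#' @param min_valid_fraction minimum valid-frame fraction for a direction
#'   call (default 0.5).
#' @param omega_min direction dead band in rad/s (default 0.05; set 0 to
#'   force a CW/CCW call on every cell).
#' @param max_gap_frames largest frame gap unwrapped across (default 5).
#' @param min_prominence_fraction spectral peak prominence threshold
#'   (default 0.1).
#' @param window FFT window, `"rectangular"` or `"hann"`.
#' @param degenerate_eps minimum landmark vector length in pixels.
#' @return list of class `run_config`.
#' @export
run_config <- function(fps = 200, likelihood_threshold = 0.95,
                       px_per_um = 4.14, beat_band = c(10, 100),
                       rotation_band = c(0.2, 20), top_k = 10,
                       min_valid_fraction = 0.5, omega_min = 0.05,
                       max_gap_frames = 5, min_prominence_fraction = 0.1,
                       window = "rectangular", degenerate_eps = 1e-9) {
  if (!(likelihood_threshold >= 0 && likelihood_threshold <= 1)) {
    abort_validation("likelihood_threshold must lie in [0, 1]")
  }
  structure(
    list(fps = fps, likelihood_threshold = likelihood_threshold,
         px_per_um = px_per_um, beat_band = beat_band,
         rotation_band = rotation_band, top_k = top_k,
         min_valid_fraction = min_valid_fraction, omega_min = omega_min,
         max_gap_frames = max_gap_frames,
         min_prominence_fraction = min_prominence_fraction,
         window = window, degenerate_eps = degenerate_eps),
    class = "run_config"
  )
}

flag_of <- function(err) {
  if (inherits(err, "flagrot_no_peak_error")) "no_peak"
  else if (inherits(err, "flagrot_insufficient_data_error")) "insufficient_data"
  else "error"
}

#' Analyze a single cell track
#'
#' Runs the full per-cell pipeline: body and flagellar angle extraction with
#' likelihood masking, cumulative-angle unwrapping, least-squares rotation
#' fit, optional direction override, and FFT frequency estimation for both
#' signals. Insufficient-data and no-peak conditions are recorded as flags
#' in the output record rather than raised, so a cohort run never aborts on
#' one bad cell.
#'
#' @param track a [cell_track()].
#' @param config a [run_config()].
#' @param overrides named direction override vector from [read_overrides()],
#'   or `NULL`.
#' @param keep_series if `TRUE`, attach the three angle series and both
#'   spectra to the result for plotting.
#' @return list of class `cell_record`: `record` (one-row data frame),
#'   `rotation` (the `rotation_result` or `NULL`), and optionally `series`
#'   and `spectra`.
#' @export
analyze_cell <- function(track, config = run_config(), overrides = NULL,
                         keep_series = FALSE) {
  stopifnot(inherits(track, "cell_track"), inherits(config, "run_config"))
  thr <- config$likelihood_threshold
  eps <- config$degenerate_eps
  body <- body_axis_angle(track, thr, eps)
  flag <- flagellar_angle(track, thr, eps)

  rot <- NULL
  rot_flag <- NA_character_
  cum <- NULL
  res <- tryCatch({
    cum <- unwrap_cumulative(body, config$max_gap_frames)
    fit_rotation(cum, cell_id = track$cell_id,
                 min_valid_fraction = config$min_valid_fraction,
                 omega_min = config$omega_min)
  }, flagrot_insufficient_data_error = function(e) e)
  if (inherits(res, "rotation_result")) {
    rot <- res
    if (!is.null(overrides)) rot <- apply_overrides(list(rot), overrides)[[1]]
  } else {
    rot_flag <- flag_of(res)
  }

  est <- function(fun, series, band) {
    tryCatch(fun(series, band = band,
                 min_prominence_fraction = config$min_prominence_fraction,
                 window = config$window),
             flagrot_error = function(e) flag_of(e))
  }
  beat <- est(estimate_beat_frequency, flag, config$beat_band)
  rotf <- est(estimate_rotation_frequency, body, config$rotation_band)

  record <- data.frame(
    cell_id = track$cell_id,
    condition = track$condition,
    omega_rad_s = if (is.null(rot)) NA_real_ else rot$omega,
    rotation_hz = if (is.null(rot)) NA_real_ else rot$rotation_hz,
    direction = if (is.null(rot)) "indeterminate" else rot$direction,
    n_valid = if (is.null(rot)) sum(body$valid) else rot$n_valid,
    valid_fraction = if (is.null(rot)) mean(body$valid) else rot$valid_fraction,
    residual_rms = if (is.null(rot)) NA_real_ else rot$residual_rms,
    overridden = if (is.null(rot)) FALSE else rot$overridden,
    rotation_flag = rot_flag,
    beat_hz = if (inherits(beat, "spectral_estimate")) beat$peak_hz else NA_real_,
    beat_df = if (inherits(beat, "spectral_estimate")) beat$df else NA_real_,
    beat_ambiguous = if (inherits(beat, "spectral_estimate")) beat$ambiguous else NA,
    beat_flag = if (is.character(beat)) beat else NA_character_,
    rotfreq_hz = if (inherits(rotf, "spectral_estimate")) rotf$peak_hz else NA_real_,
    rotfreq_df = if (inherits(rotf, "spectral_estimate")) rotf$df else NA_real_,
    rotfreq_ambiguous = if (inherits(rotf, "spectral_estimate")) rotf$ambiguous else NA,
    rotfreq_flag = if (is.character(rotf)) rotf else NA_character_
  )
  out <- list(record = record, rotation = rot)
  if (keep_series) {
    out$series <- list(body = body, flagellar = flag, cumulative = cum)
    out$spectra <- list(
      beat = if (inherits(beat, "spectral_estimate")) beat else NULL,
      rotation = if (inherits(rotf, "spectral_estimate")) rotf else NULL
    )
  }
  class(out) <- "cell_record"
  out
}

#' Analyze a list of in-memory tracks
#'
#' @param tracks list of [cell_track()]s.
#' @param config a [run_config()].
#' @param overrides optional override vector.
#' @return data frame with one record row per cell.
#' @export
analyze_tracks <- function(tracks, config = run_config(), overrides = NULL) {
  do.call(rbind, lapply(tracks, function(tr) {
    analyze_cell(tr, config, overrides)$record
  }))
}

#' Aggregate per-cell records into a cohort summary
#'
#' Per condition: direction counts and clockwise percentage; the top-k
#' fastest CCW subset; box statistics and medians of the beat and rotation
#' frequencies over that subset (or over all CCW cells with
#' `all_cells = TRUE`). When both a reference and a comparison condition are
#' present, percent reductions of the median frequencies are computed from
#' the same medians reported in the summary.
#'
#' @param per_cell data frame from [analyze_tracks()] / [analyze_cohort()].
#' @param config a [run_config()] (supplies `top_k`).
#' @param reference,comparison condition labels compared in the reduction
#'   section (defaults `"live"` vs `"demembranated"`).
#' @param all_cells if `TRUE`, summarize frequencies over all CCW cells
#'   instead of the top-k subset.
#' @return list of class `cohort_summary`: `directions` (data frame),
#'   `frequencies` (per condition: medians + box stats), `reductions`
#'   (percent, or `NULL` when a condition is missing), `top_k`, `n_skipped`.
#' @export
summarize_cohort <- function(per_cell, config = run_config(),
                             reference = "live",
                             comparison = "demembranated",
                             all_cells = FALSE) {
  stopifnot(is.data.frame(per_cell), nrow(per_cell) >= 1)
  conditions <- unique(per_cell$condition)
  directions <- do.call(rbind, lapply(conditions, function(cc) {
    summarize_directions(per_cell[per_cell$condition == cc, ], cc)
  }))

  freq_one <- function(cc) {
    sub <- per_cell[per_cell$condition == cc & per_cell$direction == "CCW", ]
    if (nrow(sub) == 0) return(NULL)
    sub <- sub[order(-sub$omega_rad_s, sub$cell_id), ]
    if (!all_cells) sub <- sub[seq_len(min(config$top_k, nrow(sub))), ]
    beat <- sub$beat_hz[!is.na(sub$beat_hz)]
    rotf <- sub$rotfreq_hz[!is.na(sub$rotfreq_hz)]
    list(
      condition = cc,
      cell_ids = sub$cell_id,
      beat_median = if (length(beat)) stats::median(beat) else NA_real_,
      rotation_median = if (length(rotf)) stats::median(rotf) else NA_real_,
      beat_box = if (length(beat)) box_stats(beat) else NULL,
      rotation_box = if (length(rotf)) box_stats(rotf) else NULL
    )
  }
  frequencies <- Filter(Negate(is.null), lapply(conditions, freq_one))
  names(frequencies) <- vapply(frequencies, `[[`, character(1), "condition")

  reductions <- NULL
  if (reference %in% names(frequencies) && comparison %in% names(frequencies)) {
    ref <- frequencies[[reference]]
    cmp <- frequencies[[comparison]]
    if (!is.na(ref$beat_median) && !is.na(cmp$beat_median) &&
        !is.na(ref$rotation_median) && !is.na(cmp$rotation_median)) {
      reductions <- list(
        reference = reference, comparison = comparison,
        beat_reduction_pct = percent_reduction(ref$beat_median,
                                               cmp$beat_median),
        rotation_reduction_pct = percent_reduction(ref$rotation_median,
                                                   cmp$rotation_median)
      )
    }
  }
  structure(list(directions = directions, frequencies = frequencies,
                 reductions = reductions, top_k = config$top_k,
                 n_skipped = attr(per_cell, "n_skipped") %||% 0L),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$directions)
  for (f in x$frequencies) {
    cat(sprintf("  %s: median beat %.3g Hz, median rotation %.3g Hz (n = %d)\n",
                f$condition, f$beat_median, f$rotation_median,
                length(f$cell_ids)))
  }
  if (!is.null(x$reductions)) {
    cat(sprintf("  reduction %s -> %s: beat %.1f%%, rotation %.1f%%\n",
                x$reductions$reference, x$reductions$comparison,
                x$reductions$beat_reduction_pct,
                x$reductions$rotation_reduction_pct))
  }
  invisible(x)
}

#' Analyze a directory of tracks and summarize the cohort
#'
#' Walks `input_dir` for condition subdirectories (`live/`,
#' `demembranated/`) containing DeepLabCut CSVs, analyzes every cell, and
#' aggregates. Unparseable files are skipped with a warning and counted in
#' the summary; a single corrupt file never aborts the run. When
#' `output_dir` is given, writes `per_cell.csv`, `direction_summary.csv`,
#' `topk_frequencies.csv` and `cohort_summary.json`.
#'
#' @param input_dir directory with `live/` and/or `demembranated/`
#'   subdirectories of `*.csv` tracks (ground-truth `*_truth.json` sidecars
#'   are ignored).
#' @param config a [run_config()].
#' @param overrides_path optional override CSV path (see
#'   [read_overrides()]).
#' @param output_dir optional directory for result tables.
#' @param all_cells see [summarize_cohort()].
#' @return a `cohort_summary` with the per-cell table attached as
#'   `$per_cell`.
#' @export
analyze_cohort <- function(input_dir, config = run_config(),
                           overrides_path = NULL, output_dir = NULL,
                           all_cells = FALSE) {
  conditions <- c("live", "demembranated")
  subdirs <- file.path(input_dir, conditions)
  present <- conditions[dir.exists(subdirs)]
  if (length(present) == 0) {
    abort_io(paste0("no live/ or demembranated/ subdirectory under ",
                    input_dir))
  }
  overrides <- if (!is.null(overrides_path)) read_overrides(overrides_path)
  records <- list()
  n_skipped <- 0L
  for (cc in present) {
    files <- list.files(file.path(input_dir, cc), pattern = "\\.csv$",
                        full.names = TRUE)
    if (length(files) == 0) next
    for (f in files) {
      rec <- tryCatch({
        tr <- read_dlc_csv(f, fps = config$fps, condition = cc,
                           px_per_um = config$px_per_um)
        analyze_cell(tr, config, overrides)$record
      }, error = function(e) {
        warning(sprintf("skipping %s: %s", basename(f), conditionMessage(e)))
        NULL
      })
      if (is.null(rec)) n_skipped <- n_skipped + 1L else {
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  if (length(records) == 0) abort_io("no parseable track files found")
  per_cell <- do.call(rbind, records)
  attr(per_cell, "n_skipped") <- n_skipped
  summary <- summarize_cohort(per_cell, config, all_cells = all_cells)
  summary$per_cell <- per_cell
  if (!is.null(output_dir)) write_cohort_outputs(summary, output_dir)
  summary
}

cohort_summary_json <- function(summary) {
  freq <- lapply(summary$frequencies, function(f) {
    list(n = length(f$cell_ids), cell_ids = f$cell_ids,
         beat_median_hz = f$beat_median,
         rotation_median_hz = f$rotation_median,
         beat_box = f$beat_box, rotation_box = f$rotation_box)
  })
  list(directions = summary$directions, top_k = summary$top_k,
       frequencies = freq, reductions = summary$reductions,
       n_skipped = summary$n_skipped)
}

#' Write cohort summary tables to a directory
#'
#' @param summary a `cohort_summary` with `$per_cell` attached.
#' @param output_dir destination directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_cohort_outputs <- function(summary, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary$per_cell, file.path(output_dir, "per_cell.csv"),
                   row.names = FALSE)
  utils::write.csv(summary$directions,
                   file.path(output_dir, "direction_summary.csv"),
                   row.names = FALSE)
  topk <- do.call(rbind, lapply(summary$frequencies, function(f) {
    sub <- summary$per_cell[summary$per_cell$cell_id %in% f$cell_ids &
                              summary$per_cell$condition == f$condition, ]
    sub[, c("cell_id", "condition", "rotation_hz", "beat_hz", "rotfreq_hz")]
  }))
  utils::write.csv(topk, file.path(output_dir, "topk_frequencies.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort_summary_json(summary),
                       file.path(output_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(output_dir)
}
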