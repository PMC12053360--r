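# Reading and writing the DeepLabCut single-animal CSV dialect.
#
# Layout: three header rows ("scorer", "bodyparts", "coords") followed by
# integer-indexed data rows; per body part the columns are x, y, likelihood.
# Image coordinates have y increasing downwards; on import y is negated so
# internal angles follow the mathematical convention and on-screen
# counterclockwise motion gives a positive cumulative angle slope.

#' Read a DeepLabCut single-animal CSV track
#'
#' Parses the three-row-header CSV dialect written by DeepLabCut in
#' single-animal mode and returns a [cell_track()]. The image-convention y
#' coordinates (origin top-left, y down) are negated at import, so that all
#' downstream angles follow the mathematical convention and counterclockwise
#' rotation on screen corresponds to increasing angle.
#'
#' @param path path to the CSV file.
#' @param fps acquisition frame rate (frames per second).
#' @param condition `"live"` or `"demembranated"`.
#' @param cell_id identifier; defaults to the file name without extension.
#' @param bodypart_map named character vector mapping the roles
#'   `tip`, `base`, `posterior` to body-part names in the file header.
#' @param px_per_um optional pixel scale (pixels per micron).
#'
#' @return A [cell_track()]. Row count and order are preserved exactly;
#'   likelihoods are passed through unmodified. Filtering happens downstream.
#' @export
read_dlc_csv <- function(path, fps, condition = c("live", "demembranated"),
                         cell_id = NULL,
                         bodypart_map = c(tip = "tip", base = "base",
                                          posterior = "posterior"),
                         px_per_um = NULL) {
  condition <- match.arg(condition)
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    abort_format("not a DeepLabCut CSV: fewer than 3 header rows")
  }
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  labels <- vapply(hdr, `[`, character(1), 1)
  if (!identical(tolower(labels), c("scorer", "bodyparts", "coords"))) {
    abort_format(paste0("expected header rows scorer/bodyparts/coords, got: ",
                        paste(labels, collapse = "/")))
  }
  scorer <- hdr[[1]][2]
  bodyparts_row <- hdr[[2]][-1]
  coords_row <- hdr[[3]][-1]

  roles <- c("tip", "base", "posterior")
  if (!all(roles %in% names(bodypart_map))) {
    abort_validation("bodypart_map must name tip, base and posterior")
  }
  col_idx <- list()
  for (role in roles) {
    part <- bodypart_map[[role]]
    idx <- which(bodyparts_row == part)
    if (length(idx) == 0) {
      abort_format(paste0("body part '", part, "' (role ", role,
                          ") not found in bodyparts header"))
    }
    found <- coords_row[idx]
    for (coord in c("x", "y", "likelihood")) {
      j <- idx[found == coord]
      if (length(j) != 1) {
        abort_format(paste0("body part '", part, "' lacks a unique '", coord,
                            "' column"))
      }
      col_idx[[paste(role, coord, sep = ".")]] <- j + 1  # +1: frame-index col
    }
  }

  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[nzchar(data_lines)]
  n <- length(data_lines)
  ncol_expected <- length(hdr[[2]])
  parse_rows <- function() {
    if (n == 0) {
      return(matrix(numeric(0), nrow = 0, ncol = ncol_expected))
    }
    cells <- strsplit(data_lines, ",", fixed = TRUE)
    bad_len <- which(lengths(cells) != ncol_expected)
    if (length(bad_len) > 0) {
      abort_parse(sprintf("data row %d has %d fields, expected %d",
                          bad_len[1], lengths(cells)[bad_len[1]],
                          ncol_expected))
    }
    m <- matrix(unlist(cells), nrow = n, byrow = TRUE)
    num <- suppressWarnings(matrix(as.numeric(m), nrow = n))
    bad <- which(is.na(num) & nzchar(m), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      abort_parse(sprintf("non-numeric value '%s' at data row %d, column %d",
                          m[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))
    }
    num
  }
  num <- parse_rows()

  pick <- function(key) if (n == 0) numeric(0) else num[, col_idx[[key]]]
  frames <- data.frame(
    frame  = if (n == 0) integer(0) else num[, 1],
    tip_x  = pick("tip.x"),
    tip_y  = -pick("tip.y"),
    tip_l  = pick("tip.likelihood"),
    base_x = pick("base.x"),
    base_y = -pick("base.y"),
    base_l = pick("base.likelihood"),
    post_x = pick("posterior.x"),
    post_y = -pick("posterior.y"),
    post_l = pick("posterior.likelihood")
  )
  lik <- c(frames$tip_l, frames$base_l, frames$post_l)
  if (any(lik < 0 | lik > 1)) {
    abort_validation("likelihood outside [0, 1] in input file")
  }
  if (is.null(cell_id)) {
    cell_id <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  }
  cell_track(frames, cell_id = cell_id, condition = condition, fps = fps,
             px_per_um = px_per_um, scorer = scorer,
             bodyparts = bodypart_map[roles])
}

#' Write a cell track as a DeepLabCut single-animal CSV
#'
#' Emits the three-row-header dialect with columns in canonical role order
#' (tip, base, posterior; x, y, likelihood each). Internal math-convention y
#' is negated back to image convention, so `read_dlc_csv(write_dlc_csv(x))`
#' is the identity on the data model. Numbers are written with the shortest
#' decimal representation that parses back to the identical double, making
#' the round trip bitwise exact.
#'
#' @param track a [cell_track()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(track, path) {
  stopifnot(inherits(track, "cell_track"))
  parts <- track$bodyparts
  header <- c(
    paste(c("scorer", rep(track$scorer %||% "flagrot", 9)), collapse = ","),
    paste(c("bodyparts", rep(unname(parts[c("tip", "base", "posterior")]),
                             each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), 3)), collapse = ",")
  )
  fr <- track$frames
  body <- character(0)
  if (nrow(fr) > 0) {
    cols <- cbind(
      format_roundtrip(fr$tip_x),  format_roundtrip(-fr$tip_y),
      format_roundtrip(fr$tip_l),
      format_roundtrip(fr$base_x), format_roundtrip(-fr$base_y),
      format_roundtrip(fr$base_l),
      format_roundtrip(fr$post_x), format_roundtrip(-fr$post_y),
      format_roundtrip(fr$post_l)
    )
    body <- paste(format_roundtrip(fr$frame),
                  apply(cols, 1, paste, collapse = ","), sep = ",")
  }
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(paste0("cannot write to ", path))
  invisible(path)
}

#' Read a per-cell direction override table
#'
#' Rotation direction calls from the cumulative-angle slope can be corrected
#' by visual inspection of the original videos; this reads a headerless
#' two-column CSV `cell_id,direction` with direction labels `CCW` or `CW`.
#'
#' @param path path to the override CSV. An empty file yields an empty table.
#' @return named character vector mapping cell_id to direction label.
#' @export
read_overrides <- function(path) {
  if (!file.exists(path)) abort_io(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  if (any(lengths(fields) != 2)) {
    abort_format("override file must have exactly two columns: cell_id,direction")
  }
  ids <- trimws(vapply(fields, `[`, character(1), 1))
  dirs <- trimws(vapply(fields, `[`, character(1), 2))
  bad <- setdiff(unique(dirs), c("CCW", "CW"))
  if (length(bad) > 0) {
    abort_validation(paste0("unknown direction label(s): ",
                            paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(ids)) {
    abort_validation(paste0("duplicate cell_id in override table: ",
                            ids[duplicated(ids)][1]))
  }
  stats::setNames(dirs, ids)
}
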