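# Fixture builders used across the suite. All fixtures are generated in code.

`%||%` <- function(a, b) if (is.null(a)) b else a

# A minimal frames data frame from landmark coordinate lists (math
# convention). Likelihoods default to fully confident.
make_frames <- function(tip, base, post, lik = 0.99, frame = NULL) {
  n <- length(tip) / 2
  tip <- matrix(tip, ncol = 2, byrow = TRUE)
  base <- matrix(base, ncol = 2, byrow = TRUE)
  post <- matrix(post, ncol = 2, byrow = TRUE)
  lik <- matrix(rep_len(lik, 3 * nrow(tip)), ncol = 3, byrow = TRUE)
  data.frame(
    frame = frame %||% (seq_len(nrow(tip)) - 1),
    tip_x = tip[, 1], tip_y = tip[, 2], tip_l = lik[, 1],
    base_x = base[, 1], base_y = base[, 2], base_l = lik[, 2],
    post_x = post[, 1], post_y = post[, 2], post_l = lik[, 3]
  )
}

make_track <- function(tip, base, post, lik = 0.99, fps = 200,
                       cell_id = "fix", condition = "live", frame = NULL) {
  cell_track(make_frames(tip, base, post, lik, frame), cell_id = cell_id,
             condition = condition, fps = fps)
}

# Random valid track for round-trip property tests.
random_track <- function(n = 20, cell_id = "rand") {
  frames <- data.frame(
    frame = sort(sample.int(5 * n, n)) - 1,
    tip_x = rnorm(n, 100, 30), tip_y = rnorm(n, -100, 30),
    tip_l = runif(n),
    base_x = rnorm(n, 100, 30), base_y = rnorm(n, -100, 30),
    base_l = runif(n),
    post_x = rnorm(n, 100, 30), post_y = rnorm(n, -100, 30),
    post_l = runif(n)
  )
  cell_track(frames, cell_id = cell_id, condition = "live", fps = 200)
}

# A raw DLC-dialect CSV written directly (image convention), for testing the
# reader against hand-specified bytes.
write_raw_dlc <- function(path, rows,
                          parts = c("tip", "base", "posterior"),
                          coords = c("x", "y", "likelihood"),
                          scorer = "DLC_model") {
  header <- c(
    paste(c("scorer", rep(scorer, length(parts) * length(coords))),
          collapse = ","),
    paste(c("bodyparts", rep(parts, each = length(coords))), collapse = ","),
    paste(c("coords", rep(coords, length(parts))), collapse = ",")
  )
  writeLines(c(header, rows), path)
  path
}

# An angle_series built directly from values, for unit tests.
make_series <- function(theta, valid = TRUE, kind = "body", fps = 200,
                        frame = NULL) {
  n <- length(theta)
  frame <- frame %||% (seq_len(n) - 1)
  valid <- rep_len(valid, n)
  th <- theta
  th[!valid] <- NA_real_
  angle_series(frame, frame / fps, th, valid, kind = kind, fps = fps)
}

expect_flagrot_error <- function(expr, class) {
  expect_error(expr, class = class)
}
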