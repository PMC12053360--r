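test_that("wrap_to_pi maps into (-pi, pi] with the +pi boundary convention", {
  expect_equal(wrap_to_pi(3 * pi / 2), -pi / 2)
  expect_equal(wrap_to_pi(pi), pi)
  expect_equal(wrap_to_pi(-pi), pi)
  expect_equal(wrap_to_pi(0), 0)
  # equals the input modulo 2 pi, over many random angles
  set.seed(1)
  x <- runif(500, -50, 50)
  w <- wrap_to_pi(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(sin(w), sin(x), tolerance = 1e-12)
  expect_equal(cos(w), cos(x), tolerance = 1e-12)
  expect_flagrot_error(wrap_to_pi(NaN), "flagrot_validation_error")
  expect_flagrot_error(wrap_to_pi(c(0, Inf)), "flagrot_validation_error")
})

test_that("body angle is the planar angle of posterior->base", {
  tr <- make_track(
    tip  = c(2, 0,   0, 2,  -1, 1),
    base = c(1, 0,   0, 1,   0, 1),
    post = c(0, 0,   0, 0,   1, 1)
  )
  b <- body_axis_angle(tr)
  expect_equal(b$theta, c(0, pi / 2, pi))
  expect_true(all(b$valid))
  expect_equal(b$t, (0:2) / 200)
})

test_that("flagellar angle is signed from body axis to base->tip", {
  tr <- make_track(
    tip  = c(2, 0,   1, 1,   0, 0),
    base = c(1, 0,   1, 0,   1, 0),
    post = c(0, 0,   0, 0,   0, 0)
  )
  fl <- flagellar_angle(tr)
  expect_equal(fl$theta, c(0, pi / 2, pi))
})

test_that("likelihood masking uses exactly the landmarks each angle consumes", {
  # tip unreliable: body angle unaffected, flagellar angle masked
  tr <- make_track(
    tip  = c(2, 0, 2, 0),
    base = c(1, 0, 1, 0),
    post = c(0, 0, 0, 0),
    lik  = c(0.5, 0.99, 0.99,   # frame 1: bad tip
             0.99, 0.5, 0.99)   # frame 2: bad base
  )
  expect_identical(body_axis_angle(tr)$valid, c(TRUE, FALSE))
  expect_identical(flagellar_angle(tr)$valid, c(FALSE, FALSE))
})

test_that("degenerate zero-length vectors invalidate the frame, not the track", {
  tr <- make_track(
    tip  = c(1, 0,  1, 0),
    base = c(1, 0,  1, 0),   # base == tip: flagellar vector degenerate
    post = c(1, 0,  0, 0)    # frame 1: posterior == base too
  )
  b <- body_axis_angle(tr)
  expect_identical(b$valid, c(FALSE, TRUE))
  fl <- flagellar_angle(tr)
  expect_identical(fl$valid, c(FALSE, FALSE))
  # all-degenerate track: all-invalid series, no exception
  tr2 <- make_track(tip = c(0, 0), base = c(0, 0), post = c(0, 0))
  expect_identical(body_axis_angle(tr2)$valid, FALSE)
})

test_that("unwrapping accumulates quarter turns across the wrap boundary", {
  s <- make_series(c(0, pi / 2, pi, -pi / 2, 0))
  u <- unwrap_cumulative(s)
  expect_equal(u$theta, c(0, pi / 2, pi, 3 * pi / 2, 2 * pi))
  expect_equal(u$kind, "cumulative")

  const <- make_series(rep(0.3, 10))
  expect_equal(unwrap_cumulative(const)$theta, rep(0, 10))

  expect_flagrot_error(unwrap_cumulative(make_series(c(0, 1, 2),
                                                     valid = c(TRUE, FALSE, FALSE))),
                       "flagrot_insufficient_data_error")
})

test_that("gaps longer than max_gap_frames contribute zero rotation", {
  # valid at frames 0,1 then 10,11: the 9-frame gap must not add rotation
  s <- make_series(c(0.0, 0.5, 2.0, 2.5), frame = c(0, 1, 10, 11))
  u <- unwrap_cumulative(s, max_gap_frames = 5)
  expect_equal(u$theta, c(0, 0.5, 0.5, 1.0))
  # with a permissive gap the increment is accumulated
  u2 <- unwrap_cumulative(s, max_gap_frames = 20)
  expect_equal(u2$theta, c(0, 0.5, 2.0, 2.5))
})

test_that("unwrap matches brute-force accumulation of generator increments", {
  set.seed(11)
  for (rep in 1:50) {
    inc <- runif(200, -pi / 4, pi / 4)
    true_cum <- c(0, cumsum(inc))
    wrapped <- wrap_to_pi(true_cum)
    u <- unwrap_cumulative(make_series(wrapped))
    expect_equal(u$theta, true_cum, tolerance = 1e-12)
  }
})

test_that("kinematics obeys translation, rotation and mirror symmetries", {
  set.seed(5)
  n <- 60
  frames <- make_frames(
    tip = as.vector(t(cbind(rnorm(n, 2), rnorm(n)))),
    base = as.vector(t(cbind(rnorm(n, 1), rnorm(n)))),
    post = as.vector(t(cbind(rnorm(n), rnorm(n))))
  )
  tr <- cell_track(frames, "sym", "live", fps = 200)
  b0 <- body_axis_angle(tr)
  f0 <- flagellar_angle(tr)

  shift <- function(fr, dx, dy) {
    for (p in c("tip", "base", "post")) {
      fr[[paste0(p, "_x")]] <- fr[[paste0(p, "_x")]] + dx
      fr[[paste0(p, "_y")]] <- fr[[paste0(p, "_y")]] + dy
    }
    fr
  }
  tr_t <- cell_track(shift(frames, 17.3, -42.1), "sym", "live", fps = 200)
  expect_equal(body_axis_angle(tr_t)$theta, b0$theta, tolerance = 1e-12)
  expect_equal(flagellar_angle(tr_t)$theta, f0$theta, tolerance = 1e-12)

  phi <- 0.7
  rot <- function(fr) {
    for (p in c("tip", "base", "post")) {
      x <- fr[[paste0(p, "_x")]]; y <- fr[[paste0(p, "_y")]]
      fr[[paste0(p, "_x")]] <- cos(phi) * x - sin(phi) * y
      fr[[paste0(p, "_y")]] <- sin(phi) * x + cos(phi) * y
    }
    fr
  }
  tr_r <- cell_track(rot(frames), "sym", "live", fps = 200)
  expect_equal(wrap_to_pi(body_axis_angle(tr_r)$theta - b0$theta - phi),
               rep(0, n), tolerance = 1e-12)
  expect_equal(flagellar_angle(tr_r)$theta, f0$theta, tolerance = 1e-12)

  mir <- frames
  for (p in c("tip", "base", "post")) {
    mir[[paste0(p, "_y")]] <- -mir[[paste0(p, "_y")]]
  }
  tr_m <- cell_track(mir, "sym", "live", fps = 200)
  expect_equal(wrap_to_pi(body_axis_angle(tr_m)$theta + b0$theta),
               rep(0, n), tolerance = 1e-12)
  expect_equal(wrap_to_pi(flagellar_angle(tr_m)$theta + f0$theta),
               rep(0, n), tolerance = 1e-12)
})

test_that("raising the likelihood threshold never gains valid samples", {
  set.seed(9)
  tr <- random_track(200)
  prev <- Inf
  for (thr in c(0, 0.25, 0.5, 0.75, 0.9, 0.99, 1)) {
    nv <- sum(body_axis_angle(tr, likelihood_threshold = thr)$valid)
    expect_lte(nv, prev)
    prev <- nv
  }
})

test_that("wrapped cumulative differences agree with wrapped raw differences", {
  set.seed(13)
  inc <- runif(300, -1, 1)
  wrapped <- wrap_to_pi(cumsum(inc))
  u <- unwrap_cumulative(make_series(wrapped))
  expect_equal(wrap_to_pi(u$theta - u$theta[1]),
               wrap_to_pi(wrapped - wrapped[1]), tolerance = 1e-12)
})
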