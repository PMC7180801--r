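test_that("thorax and upper-arm frames match hand-computed constructions", {
  f <- thorax_frame_kinect(SS = c(0, 400, 0), SM = c(0, 0, 0),
                           SL = c(-200, 380, 0), SR = c(200, 380, 0))
  expect_equal(f$axes[, "y"], c(0, 1, 0), tolerance = 1e-12)
  expect_equal(f$axes[, "z"], c(0, 0, -1), tolerance = 1e-12)
  expect_equal(f$axes[, "x"], c(-1, 0, 0), tolerance = 1e-12)
  expect_equal(f$origin, c(0, 400, 0))

  u <- upper_arm_frame_kinect(SR = c(0, 0, 0), ER = c(0, -300, 0),
                              WR = c(250, -300, 0))
  expect_equal(u$axes[, "y"], c(0, 1, 0), tolerance = 1e-12)
  expect_equal(u$axes[, "z"], c(0, 0, 1), tolerance = 1e-12)
  expect_equal(u$axes[, "x"], c(1, 0, 0), tolerance = 1e-12)

  expect_error(thorax_frame_kinect(c(0, 0, 0), c(0, 0, 0),
                                   c(-1, 0, 0), c(1, 0, 0)), "singular")
  expect_error(upper_arm_frame_kinect(c(0, 0, 0), c(0, -300, 0),
                                      c(0, -560, 0)), "extended")
})

test_that("random non-degenerate landmarks yield right-handed orthonormal frames", {
  set.seed(42)
  worst <- 0
  for (k in 1:500) {
    P <- matrix(stats::rnorm(12, sd = 200), 4, 3)
    f <- tryCatch(thorax_frame_kinect(P[1, ], P[2, ], P[3, ], P[4, ]),
                  error = function(e) NULL)
    if (is.null(f)) next
    worst <- max(worst, max(abs(crossprod(f$axes) - diag(3))),
                 abs(det(f$axes) - 1))
    u <- tryCatch(upper_arm_frame_kinect(P[1, ], P[2, ], P[3, ]),
                  error = function(e) NULL)
    if (!is.null(u)) {
      worst <- max(worst, max(abs(crossprod(u$axes) - diag(3))),
                   abs(det(u$axes) - 1))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("z-x-y decomposition inverts composition away from gimbal lock", {
  # identity rotation -> all zero, no flag
  id <- shoulder_angles(segment_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                        segment_frame(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  expect_equal(c(id$fe, id$aa, id$ie), c(0, 0, 0))
  expect_false(id$gimbal)

  d <- euler_zxy_decompose(euler_zxy_compose(30, 20, 10))
  expect_equal(c(d$fe, d$aa, d$ie), c(30, 20, 10), tolerance = 1e-9)

  set.seed(5)
  worst <- 0
  for (k in 1:400) {
    fe <- stats::runif(1, -150, 150)
    aa <- stats::runif(1, -85, 85)
    ie <- stats::runif(1, -150, 150)
    d <- euler_zxy_decompose(euler_zxy_compose(fe, aa, ie))
    worst <- max(worst, abs(d$fe - fe), abs(d$aa - aa), abs(d$ie - ie))
    R <- euler_zxy_compose(d$fe, d$aa, d$ie)
    worst <- max(worst, max(abs(R - euler_zxy_compose(fe, aa, ie))))
  }
  expect_lt(worst, 1e-9)
})

test_that("gimbal lock zeroes axial rotation and preserves the outer sum", {
  R <- euler_zxy_compose(40, 90, 25)
  d <- euler_zxy_decompose(R)
  expect_true(d$gimbal)
  expect_equal(d$ie, 0)
  expect_equal(d$fe, 40 + 25, tolerance = 1e-9)
})

test_that("elbow angle conventions agree with limit geometry", {
  SR <- c(0, 0, 0); ER <- c(0, -300, 0)
  expect_equal(elbow_angle(SR, ER, c(0, -560, 0), "raw-acos"), 180)
  expect_equal(elbow_angle(SR, ER, c(0, -560, 0), "flexion"), 0)
  expect_equal(elbow_angle(SR, ER, c(260, -300, 0)), 90)
  # folded arm: wrist back toward the shoulder
  expect_equal(elbow_angle(SR, ER, c(0, -40, 0)), 180)
  expect_error(elbow_angle(SR, ER, ER), "zero")
})

test_that("trajectory kinematics recover generating angles and stay constant on static poses", {
  trial <- make_clean_trial(offset = 0.2)
  wf <- kinematics_kinect(trial$kinect_stream)
  truth <- attr(trial$kinect_stream, "truth_values")
  expect_lt(max(abs(wf$values - truth)), 1e-6)

  # constant mid-movement pose replicated over 50 frames
  pose <- pose_frame <- trial$kinect_stream$positions[40, , ]
  arr <- array(rep(pose_frame, each = 50), dim = c(50, 3, 6),
               dimnames = list(NULL, c("x", "y", "z"), trial$kinect_stream$names))
  const <- landmark_series(arr, times = seq(0, 49) / 30, rate_hz = 30,
                           source = "kinect")
  cw <- kinematics_kinect(const)
  expect_lt(max(apply(cw$values, 2, function(v) diff(range(v)))), 1e-9)
  expect_equal(unname(cw$values[1, ]), unname(truth[40, ]), tolerance = 1e-6)
})

test_that("fully extended arm frames are carried or rejected by the singular-frame budget", {
  # all-collinear trial errors at the default budget
  Tn <- 30
  arr <- array(NA_real_, dim = c(Tn, 3, 6),
               dimnames = list(NULL, c("x", "y", "z"), KINECT_LANDMARKS <- c("SS", "SM", "SL", "SR", "ER", "WR")))
  for (t in seq_len(Tn)) {
    arr[t, , "SS"] <- c(0, 400, 0); arr[t, , "SM"] <- c(0, 0, 0)
    arr[t, , "SL"] <- c(200, 380, 0); arr[t, , "SR"] <- c(-200, 380, 0)
    arr[t, , "ER"] <- c(-200, 80, 0); arr[t, , "WR"] <- c(-200, -180, 0)
  }
  s <- landmark_series(arr, times = seq_len(Tn) / 30, rate_hz = 30,
                       source = "kinect")
  expect_error(kinematics_kinect(s), "unusable")
  # with a relaxed budget the neutral fallback gives the anatomical zeros
  wf <- kinematics_kinect(s, max_singular_frac = 1)
  expect_lt(max(abs(wf$values)), 1e-9)
})

test_that("angles are invariant under global rigid transforms of the landmarks", {
  set.seed(9)
  trial <- make_clean_trial(offset = 0.1)
  wf0 <- kinematics_kinect(trial$kinect_stream)
  for (k in 1:3) {
    moved <- apply_rigid_series(trial$kinect_stream, random_rigid())
    wf1 <- kinematics_kinect(moved)
    expect_lt(max(abs(wf1$values - wf0$values)), 1e-6)
  }
})

test_that("channel unwrapping removes full-revolution jumps", {
  x <- c(170, 175, 179, -178, -172)
  u <- unwrap_degrees(x)
  expect_equal(u, c(170, 175, 179, 182, 188))
  expect_lt(max(abs(diff(u))), 180)
})
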