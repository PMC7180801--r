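# Synthetic corpus generator: task-specific minimum-jerk joint trajectories,
# forward kinematics to marker and skeleton streams (each placed so its
# model's frame construction inverts exactly), rate mismatch and start
# offset between the streams, and a parametric, learnable sensor-error model
# for the depth stream.

#' Default body model
#'
#' Segment lengths and the landmark/marker offsets used by the forward
#' kinematics, in mm. Offsets are expressed in the thorax frame (fixed
#' markers), the humerus frame or the forearm frame. The skeleton shoulder
#' line is placed so the skeleton model's thorax construction recovers the
#' generating frame exactly (schematic, not anthropometric, placement).
#'
#' @param upper_arm,forearm,shoulder_halfwidth,thorax_height lengths (mm).
#' @return object of class `body_model`.
#' @export
body_model <- function(upper_arm = 300, forearm = 260,
                       shoulder_halfwidth = 200, thorax_height = 400) {
  stopifnot(upper_arm > 0, forearm > 0, shoulder_halfwidth > 0,
            thorax_height > 0)
  structure(list(
    upper_arm = upper_arm, forearm = forearm,
    shoulder_halfwidth = shoulder_halfwidth, thorax_height = thorax_height,
    # shoulder joint center, in the thorax frame (to the subject's right = +z)
    shoulder_center = c(0, 0.95 * thorax_height, shoulder_halfwidth),
    elbow_marker_halfwidth = 30, styloid_halfwidth = 25,
    # marker cluster offsets: PUA in the humerus frame (relative to the
    # shoulder center), DUA in the forearm frame (relative to the elbow)
    pua = list(c(40, -120, 0), c(45, -180, 5), c(-10, -150, 35)),
    dua = list(c(30, -100, 0), c(35, -160, 5), c(-5, -130, 30))
  ), class = "body_model")
}

scale_body <- function(body, factor) {
  b <- body
  for (f in c("upper_arm", "forearm", "shoulder_halfwidth", "thorax_height")) {
    b[[f]] <- body[[f]] * factor
  }
  b$shoulder_center <- c(0, 0.95 * b$thorax_height, b$shoulder_halfwidth)
  b
}

#' Task profiles for the four functional tasks
#'
#' Start and end angles (degrees) per channel with between-subject SDs of the
#' end angle, and movement durations (s). End-angle means and SDs follow the
#' gold-standard columns of the study's parameter tables; start angles are
#' end minus the signed range of motion (the trajectories are monotone
#' minimum-jerk curves).
#'
#' @return named list of task profiles.
#' @export
task_profiles <- function() {
  prof <- function(task, start, end, end_sd, duration) {
    list(task = task,
         start = stats::setNames(start, ANGLE_CHANNELS),
         end = stats::setNames(end, ANGLE_CHANNELS),
         end_sd = stats::setNames(end_sd, ANGLE_CHANNELS),
         start_sd = stats::setNames(rep(3, 4), ANGLE_CHANNELS),
         duration = duration,
         hold_in = 1.05, hold_out = 0.45)
  }
  list(
    t1_contralateral_shoulder = prof("t1_contralateral_shoulder",
      start = c(FE = -3.15, AA = 12.80, IE = 4.63, EFE = 30.03),
      end = c(FE = 39.35, AA = -1.28, IE = 69.22, EFE = 125.06),
      end_sd = c(FE = 7.95, AA = 6.15, IE = 5.30, EFE = 3.42),
      duration = 1.8),
    t2_hand_to_mouth = prof("t2_hand_to_mouth",
      start = c(FE = -2.46, AA = -9.07, IE = 1.75, EFE = 29.76),
      end = c(FE = 56.37, AA = -22.78, IE = 31.82, EFE = 130.05),
      end_sd = c(FE = 8.83, AA = 12.03, IE = 6.86, EFE = 5.07),
      duration = 1.6),
    t3_comb_hair = prof("t3_comb_hair",
      start = c(FE = 0.04, AA = -11.13, IE = -22.16, EFE = 31.59),
      end = c(FE = 105.89, AA = -58.49, IE = 23.53, EFE = 144.56),
      end_sd = c(FE = 15.02, AA = 8.30, IE = 13.20, EFE = 3.49),
      duration = 2.2),
    t4_back_pocket = prof("t4_back_pocket",
      start = c(FE = -7.91, AA = -10.75, IE = 14.97, EFE = 30.84),
      end = c(FE = -42.06, AA = -23.72, IE = 37.89, EFE = 78.66),
      end_sd = c(FE = 5.56, AA = 6.01, IE = 6.16, EFE = 11.85),
      duration = 1.8)
  )
}

#' Minimum-jerk position profile
#'
#' `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5`, the standard smooth reaching
#' profile with zero boundary velocity and acceleration.
#'
#' @param tau normalized time, clipped to \[0, 1\].
#' @return profile value in \[0, 1\].
#' @export
minimum_jerk <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Generate a true joint-angle trajectory for a task
#'
#' Each channel follows a minimum-jerk curve from its start to its end angle
#' over the task's movement duration, flanked by stationary holds (the
#' lead-in hold also absorbs the random inter-system start offset downstream).
#'
#' @param profile one entry of [task_profiles()].
#' @param subject optional list overriding `start`, `end` and `duration`
#'   (a subject/trial draw from [generate_corpus()]).
#' @param rate_hz sampling rate of the truth waveform (default 300).
#' @return an [angle_waveform()] (`source = "truth"`), with the movement
#'   window `[t0, t1]` in `attr(, "movement")`.
#' @export
generate_truth <- function(profile, subject = NULL, rate_hz = 300) {
  start <- profile$start; end <- profile$end; duration <- profile$duration
  if (!is.null(subject)) {
    if (!is.null(subject$start)) start <- subject$start
    if (!is.null(subject$end)) end <- subject$end
    if (!is.null(subject$duration)) duration <- subject$duration
  }
  stopifnot(duration > 0)
  total <- profile$hold_in + duration + profile$hold_out
  times <- seq(0, total, by = 1 / rate_hz)
  tau <- (times - profile$hold_in) / duration
  s <- minimum_jerk(tau)
  vals <- vapply(ANGLE_CHANNELS, function(ch) {
    start[[ch]] + (end[[ch]] - start[[ch]]) * s
  }, numeric(length(times)))
  wf <- angle_waveform(vals, rate_hz = rate_hz, times = times,
                       task = profile$task, source = "truth")
  attr(wf, "movement") <- c(profile$hold_in, profile$hold_in + duration)
  wf
}

# Humerus frame axes (columns of Rz(FE) Rx(AA) Ry(IE)) for vectors of angles
# (degrees); returns list of T x 3 matrices x, y, z.
humerus_axes <- function(fe, aa, ie) {
  f <- fe * pi / 180; a <- aa * pi / 180; i <- ie * pi / 180
  cf <- cos(f); sf <- sin(f); ca <- cos(a); sa <- sin(a)
  ci <- cos(i); si <- sin(i)
  list(x = cbind(cf * ci - sf * sa * si, sf * ci + cf * sa * si, -ca * si),
       y = cbind(-sf * ca, cf * ca, sa),
       z = cbind(cf * si + sf * sa * ci, sf * si - cf * sa * ci, ca * ci))
}

# Skeleton landmark positions from angle trajectories. Returns T x 3 x 6 array.
pose_kinect_landmarks <- function(values, body) {
  Tn <- nrow(values)
  H <- humerus_axes(values[, "FE"], values[, "AA"], values[, "IE"])
  phi <- values[, "EFE"] * pi / 180
  Gy <- -sin(phi) * H$x + cos(phi) * H$y
  th <- body$thorax_height; hw <- body$shoulder_halfwidth
  SM <- c(0, 0, 0); SS <- c(0, th, 0)
  SL <- c(hw, 0.95 * th, 0); SR <- c(-hw, 0.95 * th, 0)
  const_row <- function(v) matrix(v, Tn, 3, byrow = TRUE)
  ER <- const_row(SR) - body$upper_arm * H$y
  WR <- ER - body$forearm * Gy
  arr <- array(NA_real_, dim = c(Tn, 3, 6),
               dimnames = list(NULL, c("x", "y", "z"), KINECT_LANDMARKS))
  arr[, , "SS"] <- const_row(SS); arr[, , "SM"] <- const_row(SM)
  arr[, , "SL"] <- const_row(SL); arr[, , "SR"] <- const_row(SR)
  arr[, , "ER"] <- ER; arr[, , "WR"] <- WR
  arr
}

# Marker positions from angle trajectories. include_anatomical toggles the
# elbow/wrist landmarks that are removed during dynamic trials.
pose_mocap_markers <- function(values, body, include_anatomical = FALSE) {
  Tn <- nrow(values)
  H <- humerus_axes(values[, "FE"], values[, "AA"], values[, "IE"])
  phi <- values[, "EFE"] * pi / 180
  Gx <- cos(phi) * H$x + sin(phi) * H$y
  Gy <- -sin(phi) * H$x + cos(phi) * H$y
  Gz <- H$z
  th <- body$thorax_height
  S0 <- body$shoulder_center
  const_row <- function(v) matrix(v, Tn, 3, byrow = TRUE)
  in_frame <- function(origin, ax, off) {
    origin + off[1] * ax$x + off[2] * ax$y + off[3] * ax$z
  }
  S <- const_row(S0)
  E <- S - body$upper_arm * H$y
  W <- E - body$forearm * Gy
  G <- list(x = Gx, y = Gy, z = Gz)
  mk <- list(
    C7 = const_row(c(-60, th, 0)), CLAV = const_row(c(60, th, 0)),
    T10 = const_row(c(-60, 0, 0)), STRN = const_row(c(60, 0, 0)),
    PSH = const_row(S0 + c(-40, 0, 0)), ASH = const_row(S0 + c(40, 0, 0)),
    PUA1 = S + in_frame(0, H, body$pua[[1]]),
    PUA2 = S + in_frame(0, H, body$pua[[2]]),
    PUA3 = S + in_frame(0, H, body$pua[[3]]),
    DUA1 = E + in_frame(0, G, body$dua[[1]]),
    DUA2 = E + in_frame(0, G, body$dua[[2]]),
    DUA3 = E + in_frame(0, G, body$dua[[3]]),
    CAR = W - 60 * Gy
  )
  if (include_anatomical) {
    mk$EL <- E + body$elbow_marker_halfwidth * H$z
    mk$EM <- E - body$elbow_marker_halfwidth * H$z
    mk$RS <- W + body$styloid_halfwidth * Gz
    mk$US <- W - body$styloid_halfwidth * Gz
  }
  arr <- array(NA_real_, dim = c(Tn, 3, length(mk)),
               dimnames = list(NULL, c("x", "y", "z"), names(mk)))
  for (nm in names(mk)) arr[, , nm] <- mk[[nm]]
  arr
}

#' Forward kinematics: truth angles to marker and skeleton streams
#'
#' Places the thorax at the origin and drives the humerus and forearm by
#' `Rz(FE) Rx(AA) Ry(IE)` and elbow flexion. Emits the full UWA marker set at
#' 100 Hz (elbow/wrist anatomical markers withheld, as during dynamic
#' recordings), the six skeleton landmarks at 30 Hz starting at a random
#' offset (uniform 0-1 s unless given) into the motion, and a static
#' anatomical-pose marker trial for CAST calibration. Landmark placement is
#' chosen so both kinematic models recover the generating angles exactly on
#' noise-free data.
#'
#' @param truth a [generate_truth()] waveform.
#' @param body a [body_model()].
#' @param offset start offset (s) of the skeleton stream; `NULL` draws it
#'   uniformly from \[0, 1\] (keep it below the profile's lead-in hold).
#' @param mocap_hz,kinect_hz stream rates (default 100 / 30).
#' @return list with `mocap`, `kinect_truth` and `static`
#'   [landmark_series()]; the streams carry their per-stream truth angles in
#'   `attr(, "truth_values")` and the body in `attr(, "body")`.
#' @export
forward_kinematics <- function(truth, body = body_model(), offset = NULL,
                               mocap_hz = 100, kinect_hz = 30) {
  validate_angle_waveform(truth)
  if (max(abs(truth$values)) > 180) {
    stop("truth angles must stay within +/-180 degrees", call. = FALSE)
  }
  if (is.null(offset)) offset <- stats::runif(1, 0, 1)
  times <- truth$times
  total <- times[length(times)]
  sample_truth <- function(ts) {
    vapply(seq_len(4), function(j) {
      stats::spline(times, truth$values[, j], xout = ts, method = "fmm")$y
    }, numeric(length(ts)))
  }
  t_mocap <- seq(0, total, by = 1 / mocap_hz)
  t_kin <- seq(offset, total, by = 1 / kinect_hz)
  vm <- sample_truth(t_mocap); colnames(vm) <- ANGLE_CHANNELS
  vk <- sample_truth(t_kin); colnames(vk) <- ANGLE_CHANNELS

  mocap <- landmark_series(pose_mocap_markers(vm, body), times = t_mocap,
                           rate_hz = mocap_hz, source = "mocap")
  kin <- landmark_series(pose_kinect_landmarks(vk, body), times = t_kin,
                         rate_hz = kinect_hz, source = "kinect")
  static_vals <- matrix(0, nrow = round(mocap_hz) + 1, ncol = 4,
                        dimnames = list(NULL, ANGLE_CHANNELS))
  t_static <- seq(0, 1, by = 1 / mocap_hz)
  static <- landmark_series(pose_mocap_markers(static_vals, body,
                                               include_anatomical = TRUE),
                            times = t_static, rate_hz = mocap_hz,
                            source = "mocap")
  attr(mocap, "truth_values") <- vm
  attr(kin, "truth_values") <- vk
  attr(kin, "body") <- body
  attr(kin, "offset") <- offset
  list(mocap = mocap, kinect_truth = kin, static = static)
}

#' Sensor error model for the depth stream
#'
#' Parametric stand-in for the systematic error of skeleton tracking from a
#' single depth sensor. Per channel, a smooth bias (quadratic polynomial in
#' the true angle plus one sinusoidal cycle over the trial) is applied by
#' re-posing the skeleton from the biased angles; each landmark is then
#' displaced along the camera depth axis (elevation-modulated), and Gaussian
#' jitter and occasional occlusion spikes (smoothed over 3 frames to mimic
#' tracker inertia) are added. With `gain = 0` the output equals the input
#' exactly. The systematic part is a deterministic, smooth function of the
#' true kinematics, so a sequence model can learn to remove it; default
#' magnitudes are largest on the axial-rotation (IE) channel, reflecting the
#' transverse-plane weakness of depth-sensor skeletons.
#'
#' @param gain global error gain (0 disables everything).
#' @param channel_gain named per-channel multipliers of the systematic bias.
#' @param poly named list of `c(b0, b1, b2)` coefficients (degrees;
#'   bias = b0 + b1 a + b2 a^2 at true angle a).
#' @param sin_amp,sin_phase named amplitude (degrees) / phase (rad) of the
#'   sinusoidal bias cycle.
#' @param depth_axis camera depth direction (unit-normalized internally).
#' @param depth_scale named per-landmark depth displacement scales (mm).
#' @param jitter_sd Gaussian landmark jitter SD (mm).
#' @param spike_prob,spike_mag occlusion spike probability per frame/landmark
#'   and magnitude scale (mm).
#' @return object of class `sensor_error_model`.
#' @export
sensor_error_model <- function(gain = 1,
                               channel_gain = c(FE = 1, AA = 1, IE = 1, EFE = 1),
                               poly = list(FE = c(3, 0.27, 0.0007),
                                           AA = c(1.5, 0.10, 0),
                                           IE = c(8, 0.28, 0.0015),
                                           EFE = c(12, -0.52, 0)),
                               sin_amp = c(FE = 6, AA = 5, IE = 12, EFE = 14),
                               sin_phase = c(FE = 0.6, AA = 2.0, IE = 4.0,
                                             EFE = 1.2),
                               depth_axis = c(0.25, 0.1, 1),
                               depth_scale = c(SS = 2, SM = 2, SL = 3, SR = 3,
                                               ER = 6, WR = 9),
                               jitter_sd = 2,
                               spike_prob = 0.01, spike_mag = 15) {
  stopifnot(gain >= 0, jitter_sd >= 0, spike_prob >= 0, spike_prob <= 1)
  structure(list(gain = gain, channel_gain = channel_gain, poly = poly,
                 sin_amp = sin_amp, sin_phase = sin_phase,
                 depth_axis = depth_axis / sqrt(sum(depth_axis^2)),
                 depth_scale = depth_scale, jitter_sd = jitter_sd,
                 spike_prob = spike_prob, spike_mag = spike_mag),
            class = "sensor_error_model")
}

# Systematic per-channel bias (degrees) at true angles `values` (T x 4).
# The sinusoidal component rides on the movement phase (the channel's
# normalized excursion), so it is constant during the stationary holds and
# remains a smooth deterministic function of the true kinematics.
systematic_bias <- function(err, values, tau) {
  vapply(ANGLE_CHANNELS, function(ch) {
    a <- values[, ch]
    p <- err$poly[[ch]]
    g <- err$gain * err$channel_gain[[ch]]
    a1 <- a[1]; aT <- a[length(a)]
    phase <- if (abs(aT - a1) > 5) pmin(1, pmax(0, (a - a1) / (aT - a1))) else tau
    g * (p[1] + p[2] * a + p[3] * a^2 +
           err$sin_amp[[ch]] * sin(2 * pi * phase + err$sin_phase[[ch]]))
  }, numeric(nrow(values)))
}

#' Corrupt a skeleton stream with the sensor-error model
#'
#' @param kinect_truth noise-free skeleton stream from [forward_kinematics()]
#'   (carries its truth angles and body model as attributes).
#' @param err a [sensor_error_model()].
#' @param seed integer seed for jitter and spikes.
#' @return corrupted kinect [landmark_series()]; the clean truth angles stay
#'   attached for oracle evaluation.
#' @export
corrupt_kinect <- function(kinect_truth, err = sensor_error_model(), seed = 1) {
  stopifnot(inherits(err, "sensor_error_model"))
  truth_vals <- attr(kinect_truth, "truth_values")
  body <- attr(kinect_truth, "body")
  if (is.null(truth_vals) || is.null(body)) {
    stop("corrupt_kinect needs a stream generated by forward_kinematics ",
         "(with truth angles attached)", call. = FALSE)
  }
  if (err$gain == 0) return(kinect_truth)
  times <- kinect_truth$times
  tau <- (times - times[1]) / (times[length(times)] - times[1])

  biased <- truth_vals + systematic_bias(err, truth_vals, tau)
  arr <- pose_kinect_landmarks(biased, body)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  Tn <- length(times)
  elev <- 0.5 + 0.5 * sin(truth_vals[, "FE"] * pi / 180)
  for (lm in KINECT_LANDMARKS) {
    depth <- err$gain * err$depth_scale[[lm]] * elev
    arr[, , lm] <- arr[, , lm] + outer(depth, err$depth_axis)
    if (err$jitter_sd > 0) {
      arr[, , lm] <- arr[, , lm] + matrix(stats::rnorm(Tn * 3, 0, err$jitter_sd),
                                          Tn, 3)
    }
    if (err$spike_prob > 0 && err$spike_mag > 0) {
      hit <- stats::runif(Tn) < err$spike_prob
      spike <- numeric(Tn)
      spike[hit] <- stats::rnorm(sum(hit), 0, err$spike_mag)
      spike <- stats::filter(spike, rep(1 / 3, 3), sides = 2)
      spike[is.na(spike)] <- 0
      arr[, , lm] <- arr[, , lm] + outer(as.numeric(spike), err$depth_axis)
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  out <- landmark_series(arr, times = times, rate_hz = kinect_truth$rate_hz,
                         source = "kinect")
  attr(out, "truth_values") <- truth_vals
  attr(out, "body") <- body
  attr(out, "offset") <- attr(kinect_truth, "offset")
  out
}

#' Generate a synthetic paired corpus
#'
#' Draws per-subject body models (+/-5% segment lengths) and task endpoints,
#' then per trial: truth trajectory, forward kinematics to both streams, and
#' sensor-error corruption of the skeleton stream. Fully reproducible from
#' `master_seed`.
#'
#' @param n_subjects number of subjects (default 13, the study cohort size).
#' @param tasks task codes (default all four).
#' @param trials_per_task trials per subject and task (default 3).
#' @param err a [sensor_error_model()].
#' @param master_seed integer seed.
#' @return list of [trial_record()]s (truth angles attached per trial).
#' @export
generate_corpus <- function(n_subjects = 13, tasks = TASKS,
                            trials_per_task = 3,
                            err = sensor_error_model(), master_seed = 42) {
  stopifnot(n_subjects >= 3)
  tasks <- match.arg(tasks, TASKS, several.ok = TRUE)
  profiles <- task_profiles()
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(master_seed)
  corpus <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    body <- scale_body(body_model(), 1 + stats::runif(1, -0.05, 0.05))
    for (task in tasks) {
      pr <- profiles[[task]]
      subj_end <- pr$end + stats::rnorm(4, 0, 1) * pr$end_sd
      subj_start <- pr$start + stats::rnorm(4, 0, 1) * pr$start_sd
      subj_dur <- max(0.8, pr$duration + stats::rnorm(1, 0, 0.15))
      for (tr in seq_len(trials_per_task)) {
        draw <- list(start = subj_start + stats::rnorm(4, 0, 1),
                     end = subj_end + stats::rnorm(4, 0, 1.5),
                     duration = max(0.8, subj_dur + stats::rnorm(1, 0, 0.05)))
        truth <- generate_truth(pr, subject = draw)
        offset <- stats::runif(1, 0, 1)
        noise_seed <- sample.int(2^30, 1)
        fk <- forward_kinematics(truth, body, offset = offset)
        kin <- corrupt_kinect(fk$kinect_truth, err, seed = noise_seed)
        corpus[[length(corpus) + 1]] <-
          trial_record(subject_id = sid, task = task,
                       trial_id = sprintf("%s_%s_r%d", sid, task, tr),
                       kinect_stream = kin, mocap_stream = fk$mocap,
                       static_trial = fk$static, truth_angles = truth)
      }
    }
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  corpus
}

#' Corpus-level uncorrected RMSE per channel
#'
#' Mean (within subject, then across subjects) of the per-trial RMSE between
#' the preprocessed skeleton and gold-standard waveforms -- the quantity the
#' error injector is calibrated against.
#'
#' @param corpus list of [trial_record()]s (one task) or prepared pairs.
#' @param task optional task filter.
#' @return named per-channel RMSE vector (degrees).
#' @export
corpus_uncorrected_rmse <- function(corpus, task = NULL) {
  pairs <- if (length(corpus) > 0 && inherits(corpus[[1]], "trial_record")) {
    prepare_corpus_pairs(corpus, task = task)
  } else corpus
  subj <- vapply(pairs, `[[`, "", "subject_id")
  per_trial <- t(vapply(pairs, function(p) {
    vapply(ANGLE_CHANNELS, function(ch) {
      rmse(p$input$values[, ch], p$target$values[, ch])
    }, numeric(1))
  }, numeric(4)))
  apply(per_trial, 2, function(v) subject_mean_sd(v, subj)["mean"])
}

#' Calibrate the systematic error gain to target uncorrected RMSEs
#'
#' Scales the per-channel systematic-error gains until the corpus-level
#' uncorrected RMSE of each targeted channel matches its target. The search
#' exploits that the squared RMSE is, to good approximation, a noise floor
#' plus a term quadratic in the gain, and polishes with bisection.
#'
#' @param targets named per-channel target RMSEs (degrees), e.g.
#'   `c(FE = 41.73, EFE = 25.83)`.
#' @param task task whose corpus is calibrated.
#' @param err starting [sensor_error_model()].
#' @param n_subjects,trials_per_task,master_seed corpus parameters (fixed
#'   during calibration so the search is deterministic).
#' @param tol admissible |achieved - target| (degrees, default 1).
#' @param max_gain upper bound of the per-channel gain search.
#' @param max_iter bisection polish iterations.
#' @return calibrated [sensor_error_model()]; achieved RMSEs in
#'   `attr(, "achieved")`.
#' @export
calibrate_error_gain <- function(targets, task, err = sensor_error_model(),
                                 n_subjects = 13, trials_per_task = 3,
                                 master_seed = 42, tol = 1, max_gain = 12,
                                 max_iter = 8) {
  stopifnot(all(names(targets) %in% ANGLE_CHANNELS), all(targets > 0))
  measure <- function(e) {
    corpus_uncorrected_rmse(generate_corpus(n_subjects = n_subjects,
                                            tasks = task,
                                            trials_per_task = trials_per_task,
                                            err = e,
                                            master_seed = master_seed))
  }
  # noise floor: systematic gains off, stochastic terms unchanged
  e0 <- err
  e0$channel_gain[] <- 0
  e0$depth_scale[] <- 0
  floor_rmse <- measure(e0)
  base <- measure(err)
  for (ch in names(targets)) {
    tg <- targets[[ch]]
    if (tg < floor_rmse[[ch]]) {
      stop(sprintf(paste0("target %.2f deg for channel %s is below the ",
                          "stochastic noise floor (%.2f deg)"),
                   tg, ch, floor_rmse[[ch]]), call. = FALSE)
    }
    s2 <- max(base[[ch]]^2 - floor_rmse[[ch]]^2, 1e-6)
    g <- err$channel_gain[[ch]] *
      sqrt(max(tg^2 - floor_rmse[[ch]]^2, 0) / s2)
    g <- min(g, max_gain)
    err$channel_gain[[ch]] <- g
  }
  achieved <- measure(err)
  # bisection polish per channel
  for (ch in names(targets)) {
    tg <- targets[[ch]]
    if (abs(achieved[[ch]] - tg) <= tol) next
    lo <- 0; hi <- max_gain
    if (achieved[[ch]] > tg) hi <- err$channel_gain[[ch]] else lo <- err$channel_gain[[ch]]
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      err$channel_gain[[ch]] <- mid
      achieved <- measure(err)
      if (abs(achieved[[ch]] - tg) <= tol) break
      if (achieved[[ch]] > tg) hi <- mid else lo <- mid
    }
    if (abs(achieved[[ch]] - tg) > tol) {
      if (hi >= max_gain - 1e-9 && achieved[[ch]] < tg) {
        stop(sprintf(paste0("target %.2f deg for channel %s unreachable ",
                            "within gain bounds (achieved %.2f deg)"),
                     tg, ch, achieved[[ch]]), call. = FALSE)
      }
    }
  }
  attr(err, "achieved") <- achieved
  err
}
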