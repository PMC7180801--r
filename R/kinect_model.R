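# Model Phi: shoulder FE/AA/IE and elbow FE from the six skeleton landmarks.
#
# Thorax: y = unit(SS - SM); z = unit(y x (SR - SL)); x = y x z; origin SS.
# Upper arm: origin ER; y = unit(SR - ER); z = unit(y x (ER - WR)); x = y x z.
# Shoulder angles from R = t(thorax axes) %*% upper-arm axes via the z-x-y
# (flexion, adduction, rotation) decomposition; elbow flexion from the angle
# between the upper-arm long axis and the forearm vector.

#' Thorax segment frame from skeleton landmarks
#'
#' @param SS,SM,SL,SR length-3 positions (mm) of SpineShoulder, SpineMid,
#'   ShoulderLeft, ShoulderRight.
#' @return a [segment_frame()] with origin at SS.
#' @export
thorax_frame_kinect <- function(SS, SM, SL, SR) {
  y <- vec3_unit(SS - SM, "thorax y-axis (SS - SM)")
  z <- vec3_unit(vec3_cross(y, SR - SL), "thorax z-axis (y x (SR - SL))")
  x <- vec3_unit(vec3_cross(y, z), "thorax x-axis")
  segment_frame(SS, x, y, z)
}

#' Upper-arm segment frame from skeleton landmarks
#'
#' Singular when the arm is fully extended (elbow-wrist vector parallel to the
#' upper-arm long axis); single-frame use then errors, trajectory processing
#' in [kinematics_kinect()] carries the last valid z-axis forward.
#'
#' @param SR,ER,WR length-3 positions (mm) of ShoulderRight, ElbowRight,
#'   WristRight.
#' @return a [segment_frame()] with origin at ER.
#' @export
upper_arm_frame_kinect <- function(SR, ER, WR) {
  y <- vec3_unit(SR - ER, "upper-arm y-axis (SR - ER)")
  z <- vec3_unit(vec3_cross(y, ER - WR),
                 "upper-arm z-axis (arm fully extended)")
  x <- vec3_unit(vec3_cross(y, z), "upper-arm x-axis")
  segment_frame(ER, x, y, z)
}

#' Shoulder angles from thorax and upper-arm frames
#'
#' Decomposes `R = t(thorax$axes) %*% upper_arm$axes` with the z-x-y sequence:
#' flexion(+)/extension(-), adduction(+)/abduction(-),
#' internal(+)/external(-) rotation.
#'
#' @param thorax,upper_arm [segment_frame()] objects.
#' @return list with `fe`, `aa`, `ie` (degrees) and `gimbal` flag.
#' @export
shoulder_angles <- function(thorax, upper_arm) {
  validate_segment_frame(thorax, tol = 1e-7)
  validate_segment_frame(upper_arm, tol = 1e-7)
  R <- crossprod(thorax$axes, upper_arm$axes)
  euler_zxy_decompose(R, check = FALSE)
}

#' Elbow flexion angle from skeleton landmarks
#'
#' The raw angle is `acos(y_upper_arm . unit(WR - ER)) * 180/pi`, which is 180
#' degrees at full extension. The default `"flexion"` convention reports
#' `180 - raw` so that full extension maps to 0 and a fully folded arm to 180.
#'
#' @param SR,ER,WR length-3 positions (mm).
#' @param convention `"flexion"` (default) or `"raw-acos"`.
#' @return elbow angle in degrees.
#' @export
elbow_angle <- function(SR, ER, WR, convention = c("flexion", "raw-acos")) {
  convention <- match.arg(convention)
  y <- vec3_unit(SR - ER, "upper-arm y-axis (SR - ER)")
  v <- vec3_unit(WR - ER, "forearm vector (WR - ER)")
  raw <- acos(min(1, max(-1, sum(y * v)))) * 180 / pi
  if (convention == "flexion") 180 - raw else raw
}

#' Upper-limb angle waveforms from a skeleton stream (model Phi)
#'
#' Applies the thorax/upper-arm frame constructions and the z-x-y shoulder
#' decomposition plus the elbow flexion angle to every frame of a
#' kinect-source [landmark_series()], unwraps each channel over time, and
#' returns the 4-channel waveform `[FE, AA, IE, EFE]`.
#'
#' Frames in which the arm is (near-)fully extended leave the upper-arm
#' z-axis undefined; such frames reuse the last valid z direction (or, if
#' none exists yet, the thorax z-axis of the same frame) and are flagged in
#' `attr(, "singular_frames")`. A trial with more than `max_singular_frac` of
#' its frames singular is rejected as unusable.
#'
#' @param series kinect-source [landmark_series()].
#' @param elbow_convention `"flexion"` or `"raw-acos"` (see [elbow_angle()]).
#' @param max_singular_frac maximum tolerated fraction of singular frames
#'   (default 0.2).
#' @return an [angle_waveform()] at the stream's rate; attributes
#'   `singular_frames` (logical T-vector) and `gimbal_frames`.
#' @export
kinematics_kinect <- function(series, elbow_convention = c("flexion", "raw-acos"),
                              max_singular_frac = 0.2) {
  elbow_convention <- match.arg(elbow_convention)
  validate_landmark_series(series)
  if (series$source != "kinect") {
    stop("kinematics_kinect needs a kinect-source series", call. = FALSE)
  }
  SS <- landmark_get(series, "SS"); SM <- landmark_get(series, "SM")
  SL <- landmark_get(series, "SL"); SR <- landmark_get(series, "SR")
  ER <- landmark_get(series, "ER"); WR <- landmark_get(series, "WR")
  Tn <- n_frames(series)

  # thorax axes per frame
  ty_raw <- SS - SM
  ty <- rows_unit(ty_raw)
  tz_raw <- rows_cross(ty, SR - SL)
  if (any(rows_norm(ty_raw) <= EPS_GEOM) || any(rows_norm(tz_raw) <= EPS_GEOM)) {
    stop("singular thorax geometry in at least one frame", call. = FALSE)
  }
  tz <- rows_unit(tz_raw)
  tx <- rows_unit(rows_cross(ty, tz))
  thorax <- list(x = tx, y = ty, z = tz)

  # upper-arm axes per frame with carry-forward z on full extension
  uy_raw <- SR - ER
  if (any(rows_norm(uy_raw) <= EPS_GEOM)) {
    stop("degenerate upper-arm segment (SR == ER) in at least one frame",
         call. = FALSE)
  }
  uy <- rows_unit(uy_raw)
  fore <- ER - WR
  if (any(rows_norm(fore) <= EPS_GEOM)) {
    stop("degenerate forearm vector (ER == WR) in at least one frame",
         call. = FALSE)
  }
  uz_raw <- rows_cross(uy, fore)
  sing <- rows_norm(uz_raw) <= EPS_GEOM * rows_norm(fore)
  frac <- mean(sing)
  if (frac > max_singular_frac) {
    stop(sprintf(paste0("unusable trial: %.1f%% of frames have a fully ",
                        "extended (collinear) arm"), 100 * frac), call. = FALSE)
  }
  uz <- matrix(NA_real_, Tn, 3)
  last <- NULL
  for (t in seq_len(Tn)) {
    if (!sing[t]) {
      last <- uz_raw[t, ] / sqrt(sum(uz_raw[t, ]^2))
    }
    uz[t, ] <- if (is.null(last)) tz[t, ] else last
  }
  # backfill leading singular frames from the first valid z when available
  first_valid <- which(!sing)[1]
  if (!is.na(first_valid) && first_valid > 1) {
    for (t in seq_len(first_valid - 1)) {
      uz[t, ] <- uz_raw[first_valid, ] / sqrt(sum(uz_raw[first_valid, ]^2))
    }
  }
  # re-orthogonalize z against y (carry-forward z need not be exactly normal)
  uz <- uz - uy * rowSums(uz * uy)
  uz <- rows_unit(uz)
  ux <- rows_unit(rows_cross(uy, uz))
  upper <- list(x = ux, y = uy, z = uz)

  Rflat <- relative_rotation_traj(thorax, upper)
  dec <- euler_zxy_decompose_traj(Rflat)

  wv <- rows_unit(WR - ER)
  raw <- acos(pmin(1, pmax(-1, rowSums(uy * wv)))) * 180 / pi
  efe <- if (elbow_convention == "flexion") 180 - raw else raw

  values <- cbind(dec$angles[, "fe"], dec$angles[, "aa"],
                  dec$angles[, "ie"], efe)
  values <- apply(values, 2, unwrap_degrees)
  wf <- angle_waveform(values, rate_hz = series$rate_hz, times = series$times,
                       source = "kinect")
  attr(wf, "singular_frames") <- sing
  attr(wf, "gimbal_frames") <- dec$gimbal
  wf
}
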