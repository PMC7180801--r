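# Model Gamma: gold-standard upper-limb kinematics from the UWA marker set.
#
# Thorax: origin mid(C7, CLAV); y from mid(T10, STRN) to mid(C7, CLAV);
# z = sagittal-plane normal (C7, T10, CLAV), signed toward the subject's
# right; x completes the right-handed set. Upper arm and forearm frames are
# built on the joint centers S (shoulder-marker centroid), E (mid EL/EM) and
# W (mid RS/US); EM/EL/RS/US are CAST-reconstructed from the PUA/DUA clusters
# during dynamic trials.

#' Thorax segment frame from the UWA trunk markers
#'
#' @param C7,T10,CLAV,STRN length-3 marker positions (mm).
#' @param right_hint optional direction with a positive component toward the
#'   subject's right, used to sign the lateral z-axis; defaults to +x of the
#'   lab when no hint is available.
#' @return a [segment_frame()] with origin at mid(C7, CLAV).
#' @export
thorax_frame_uwa <- function(C7, T10, CLAV, STRN, right_hint = c(1, 0, 0)) {
  o_thorax <- (C7 + CLAV) / 2
  o_torso <- (T10 + STRN) / 2
  y <- vec3_unit(o_thorax - o_torso, "thorax y-axis")
  n <- vec3_cross(C7 - T10, CLAV - T10)
  if (sqrt(sum(n^2)) <= EPS_GEOM) {
    stop("singular thorax plane: C7, T10, CLAV are collinear", call. = FALSE)
  }
  z <- n / sqrt(sum(n^2))
  if (sum(z * right_hint) < 0) z <- -z
  x <- vec3_unit(vec3_cross(y, z), "thorax x-axis")
  z <- vec3_cross(x, y)   # re-orthogonalized lateral axis
  segment_frame(o_thorax, x, y, z)
}

#' Upper-limb joint centers from the UWA markers
#'
#' @param PSH,ASH,ACR shoulder markers; `ACR` optional (at least two needed).
#' @param EL,EM elbow epicondyle markers; `RS,US` styloid markers.
#' @return list with `S`, `E`, `W` (length-3, mm).
#' @export
joint_centers_uwa <- function(PSH = NULL, ASH = NULL, ACR = NULL, EL, EM, RS, US) {
  sh <- Filter(Negate(is.null), list(PSH, ASH, ACR))
  if (length(sh) < 2) {
    stop("at least two shoulder markers (of PSH, ASH, ACR) are required",
         call. = FALSE)
  }
  S <- Reduce(`+`, sh) / length(sh)
  list(S = S, E = (EL + EM) / 2, W = (RS + US) / 2)
}

#' Upper-arm segment frame from joint centers
#'
#' Identical construction to [upper_arm_frame_kinect()] with the joint
#' centers S, E, W in place of the skeleton joints; origin at E.
#'
#' @param S,E,W shoulder, elbow and wrist joint centers (mm).
#' @return a [segment_frame()].
#' @export
upper_arm_frame_uwa <- function(S, E, W) {
  y <- vec3_unit(S - E, "upper-arm y-axis (S - E)")
  z <- vec3_unit(vec3_cross(y, E - W), "upper-arm z-axis (arm fully extended)")
  x <- vec3_unit(vec3_cross(y, z), "upper-arm x-axis")
  segment_frame(E, x, y, z)
}

#' Forearm segment frame from the UWA markers
#'
#' y runs from the wrist joint center up to the elbow joint center; x is
#' perpendicular to y and the styloid axis (RS - US), signed anteriorly
#' (positive projection on `anterior_hint`); z completes the set.
#'
#' @param E,W elbow and wrist joint centers (mm).
#' @param RS,US styloid markers (mm).
#' @param anterior_hint direction with positive anterior component used to
#'   sign x; `NULL` keeps the raw `y x (RS - US)` direction.
#' @return a [segment_frame()] with origin at W.
#' @export
forearm_frame_uwa <- function(E, W, RS, US, anterior_hint = NULL) {
  y <- vec3_unit(E - W, "forearm y-axis (E - W)")
  sty <- RS - US
  if (sqrt(sum(sty^2)) <= EPS_GEOM) {
    stop("degenerate styloid geometry (RS == US)", call. = FALSE)
  }
  x_raw <- vec3_cross(y, sty)
  if (sqrt(sum(x_raw^2)) <= EPS_GEOM * sqrt(sum(sty^2))) {
    stop("degenerate styloid geometry: RS - US parallel to the forearm axis",
         call. = FALSE)
  }
  x <- x_raw / sqrt(sum(x_raw^2))
  if (!is.null(anterior_hint) && sum(x * anterior_hint) < 0) x <- -x
  z <- vec3_unit(vec3_cross(x, y), "forearm z-axis")
  segment_frame(W, x, y, z)
}

# ---------------------------------------------------------------------------
# CAST: calibrated anatomical systems technique

# Technical frame of a 3-marker cluster: marker1 = origin, x toward marker2,
# z = unit(x x (marker3 - marker1)), y = z x x. Any consistent convention
# yields identical reconstructed landmarks.
cluster_frame <- function(m1, m2, m3) {
  x <- vec3_unit(m2 - m1, "cluster x-axis (collinear cluster markers)")
  z_raw <- vec3_cross(x, m3 - m1)
  if (sqrt(sum(z_raw^2)) <= EPS_GEOM) {
    stop("collinear cluster markers", call. = FALSE)
  }
  z <- z_raw / sqrt(sum(z_raw^2))
  y <- vec3_cross(z, x)
  segment_frame(m1, x, y, z)
}

CAST_ASSIGNMENT <- list(EM = "PUA", EL = "PUA", RS = "DUA", US = "DUA")

#' Calibrate anatomical landmarks against their marker clusters
#'
#' From a static (anatomical pose) trial, expresses EM, EL (upper-arm cluster
#' PUA) and RS, US (forearm cluster DUA) in their cluster technical frames and
#' averages the local coordinates over all static frames.
#'
#' @param static mocap-source [landmark_series()] containing PUA1-3, DUA1-3
#'   and EM, EL, RS, US.
#' @return object of class `cast_calibration`: per landmark, the cluster id
#'   and constant local coordinates (mm).
#' @export
cast_calibrate <- function(static) {
  validate_landmark_series(static)
  need <- c(paste0("PUA", 1:3), paste0("DUA", 1:3), names(CAST_ASSIGNMENT))
  missing <- setdiff(need, static$names)
  if (length(missing) > 0) {
    stop("static trial is missing landmark(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Tn <- n_frames(static)
  local <- lapply(names(CAST_ASSIGNMENT), function(lm) {
    cl <- CAST_ASSIGNMENT[[lm]]
    m1 <- landmark_get(static, paste0(cl, "1"))
    m2 <- landmark_get(static, paste0(cl, "2"))
    m3 <- landmark_get(static, paste0(cl, "3"))
    p <- landmark_get(static, lm)
    loc <- matrix(NA_real_, Tn, 3)
    for (t in seq_len(Tn)) {
      fr <- cluster_frame(m1[t, ], m2[t, ], m3[t, ])
      loc[t, ] <- crossprod(fr$axes, p[t, ] - fr$origin)
    }
    list(cluster = cl, local = colMeans(loc))
  })
  names(local) <- names(CAST_ASSIGNMENT)
  structure(local, class = "cast_calibration")
}

#' Reconstruct anatomical landmarks from cluster motion
#'
#' Rebuilds the PUA/DUA technical frames in every frame of a dynamic trial and
#' appends EM, EL, RS, US at their calibrated local coordinates. Frames in
#' which a cluster is degenerate (marker dropout / collinearity) yield `NA`
#' positions for that cluster's landmarks and are flagged in
#' `attr(, "missing_frames")`.
#'
#' @param dynamic mocap-source [landmark_series()] containing PUA1-3, DUA1-3.
#' @param cal a [cast_calibrate()] result.
#' @return the input series with the four landmarks appended (replacing any
#'   measured copies).
#' @export
cast_reconstruct <- function(dynamic, cal) {
  stopifnot(inherits(cal, "cast_calibration"))
  validate_landmark_series(dynamic)
  Tn <- n_frames(dynamic)
  keep <- setdiff(dynamic$names, names(cal))
  out_names <- c(keep, names(cal))
  arr <- array(NA_real_, dim = c(Tn, 3, length(out_names)),
               dimnames = list(NULL, c("x", "y", "z"), out_names))
  arr[, , keep] <- dynamic$positions[, , keep]
  missing_frames <- matrix(FALSE, Tn, length(cal),
                           dimnames = list(NULL, names(cal)))
  frames <- list()
  for (cl in unique(vapply(cal, `[[`, "", "cluster"))) {
    m1 <- landmark_get(dynamic, paste0(cl, "1"))
    m2 <- landmark_get(dynamic, paste0(cl, "2"))
    m3 <- landmark_get(dynamic, paste0(cl, "3"))
    frames[[cl]] <- lapply(seq_len(Tn), function(t) {
      if (any(!is.finite(c(m1[t, ], m2[t, ], m3[t, ])))) return(NULL)
      tryCatch(cluster_frame(m1[t, ], m2[t, ], m3[t, ]),
               error = function(e) NULL)
    })
  }
  for (lm in names(cal)) {
    cl <- cal[[lm]]$cluster
    loc <- cal[[lm]]$local
    for (t in seq_len(Tn)) {
      fr <- frames[[cl]][[t]]
      if (is.null(fr)) {
        missing_frames[t, lm] <- TRUE
      } else {
        arr[t, , lm] <- fr$origin + as.vector(fr$axes %*% loc)
      }
    }
  }
  out <- landmark_series(arr, times = dynamic$times, rate_hz = dynamic$rate_hz,
                         source = dynamic$source, names = out_names,
                         validate = FALSE)
  attr(out, "missing_frames") <- missing_frames
  out
}

# ---------------------------------------------------------------------------

#' Upper-limb angle waveforms from a marker stream (model Gamma)
#'
#' Computes the gold-standard waveform `[FE, AA, IE, EFE]` from a trial's
#' mocap stream: CAST-reconstructs the elbow/wrist landmarks when they were
#' removed for the dynamic trial, builds thorax, upper-arm and forearm frames,
#' and decomposes shoulder (thorax -> upper arm) and elbow (upper arm ->
#' forearm) rotations with the same z-x-y sequence as the skeleton model.
#' Elbow varus/valgus and axial rotation are computed by the decomposition but
#' carried separately (they are not part of the 4-channel waveform).
#'
#' @param trial a [trial_record()], or a mocap [landmark_series()] that
#'   already contains EM/EL/RS/US.
#' @param max_singular_frac tolerated fraction of fully-extended-arm frames
#'   (see [kinematics_kinect()]).
#' @return an [angle_waveform()]; `attr(, "elbow_angles")` holds a `T x 3`
#'   matrix (EFE, EVV, EIE).
#' @export
kinematics_uwa <- function(trial, max_singular_frac = 0.2) {
  if (inherits(trial, "trial_record")) {
    dyn <- trial$mocap_stream
    if (!all(c("EM", "EL", "RS", "US") %in% dyn$names)) {
      cal <- cast_calibrate(trial$static_trial)
      dyn <- cast_reconstruct(dyn, cal)
    }
  } else {
    dyn <- trial
  }
  if (!all(c("EM", "EL", "RS", "US") %in% dyn$names)) {
    stop("mocap stream lacks EM/EL/RS/US and no static trial is available",
         call. = FALSE)
  }
  Tn <- n_frames(dyn)
  C7 <- landmark_get(dyn, "C7"); T10 <- landmark_get(dyn, "T10")
  CLAV <- landmark_get(dyn, "CLAV"); STRN <- landmark_get(dyn, "STRN")
  PSH <- landmark_get(dyn, "PSH"); ASH <- landmark_get(dyn, "ASH")
  ACR <- if ("ACR" %in% dyn$names) landmark_get(dyn, "ACR") else NULL
  EL <- landmark_get(dyn, "EL"); EM <- landmark_get(dyn, "EM")
  RS <- landmark_get(dyn, "RS"); US <- landmark_get(dyn, "US")
  if (any(!is.finite(cbind(EL, EM, RS, US)))) {
    stop("reconstructed landmarks contain missing frames; cannot compute ",
         "kinematics", call. = FALSE)
  }

  S <- if (is.null(ACR)) (PSH + ASH) / 2 else (PSH + ASH + ACR) / 3
  E <- (EL + EM) / 2
  W <- (RS + US) / 2

  # thorax
  o_thorax <- (C7 + CLAV) / 2
  o_torso <- (T10 + STRN) / 2
  ty <- rows_unit(o_thorax - o_torso)
  n_raw <- rows_cross(C7 - T10, CLAV - T10)
  if (any(rows_norm(n_raw) <= EPS_GEOM)) {
    stop("singular thorax plane in at least one frame", call. = FALSE)
  }
  tz <- rows_unit(n_raw)
  hint <- S - o_thorax   # toward the subject's right shoulder
  flip <- rowSums(tz * hint) < 0
  tz[flip, ] <- -tz[flip, ]
  tx <- rows_unit(rows_cross(ty, tz))
  tz <- rows_cross(tx, ty)
  thorax <- list(x = tx, y = ty, z = tz)

  # upper arm (carry-forward z on full extension, as in the skeleton model)
  uy <- rows_unit(S - E)
  fore <- E - W
  uz_raw <- rows_cross(uy, fore)
  sing <- rows_norm(uz_raw) <= EPS_GEOM * rows_norm(fore)
  if (mean(sing) > max_singular_frac) {
    stop(sprintf(paste0("unusable trial: %.1f%% of frames have a fully ",
                        "extended (collinear) arm"), 100 * mean(sing)),
         call. = FALSE)
  }
  uz <- matrix(NA_real_, Tn, 3)
  last <- NULL
  for (t in seq_len(Tn)) {
    if (!sing[t]) last <- uz_raw[t, ] / sqrt(sum(uz_raw[t, ]^2))
    uz[t, ] <- if (is.null(last)) tz[t, ] else last
  }
  first_valid <- which(!sing)[1]
  if (!is.na(first_valid) && first_valid > 1) {
    for (t in seq_len(first_valid - 1)) {
      uz[t, ] <- uz_raw[first_valid, ] / sqrt(sum(uz_raw[first_valid, ]^2))
    }
  }
  uz <- uz - uy * rowSums(uz * uy)
  uz <- rows_unit(uz)
  ux <- rows_unit(rows_cross(uy, uz))
  upper <- list(x = ux, y = uy, z = uz)

  # forearm; anterior sign fixed on the first frame, then temporal continuity
  fy <- rows_unit(E - W)
  sty <- RS - US
  fx_raw <- rows_cross(fy, sty)
  if (any(rows_norm(fx_raw) <= EPS_GEOM * rows_norm(sty))) {
    stop("degenerate styloid geometry in at least one frame", call. = FALSE)
  }
  fx <- rows_unit(fx_raw)
  if (sum(fx[1, ] * tx[1, ]) < 0) fx[1, ] <- -fx[1, ]
  for (t in seq_len(Tn)[-1]) {
    if (sum(fx[t, ] * fx[t - 1, ]) < 0) fx[t, ] <- -fx[t, ]
  }
  fz <- rows_unit(rows_cross(fx, fy))
  fx <- rows_cross(fy, fz)  # exact re-orthogonalization, keeps sign
  forearm <- list(x = fx, y = fy, z = fz)

  dec_sh <- euler_zxy_decompose_traj(relative_rotation_traj(thorax, upper))
  dec_el <- euler_zxy_decompose_traj(relative_rotation_traj(upper, forearm))

  values <- cbind(dec_sh$angles[, "fe"], dec_sh$angles[, "aa"],
                  dec_sh$angles[, "ie"], dec_el$angles[, "fe"])
  values <- apply(values, 2, unwrap_degrees)
  wf <- angle_waveform(values, rate_hz = dyn$rate_hz, times = dyn$times,
                       source = "uwa")
  elbow <- cbind(EFE = unwrap_degrees(dec_el$angles[, "fe"]),
                 EVV = dec_el$angles[, "aa"],
                 EIE = dec_el$angles[, "ie"])
  attr(wf, "elbow_angles") <- elbow
  attr(wf, "singular_frames") <- sing
  wf
}
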