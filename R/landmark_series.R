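# LandmarkSeries: time-stamped 3D trajectories of named landmarks, one stream.

#' Construct a landmark series
#'
#' The common container for skeleton-joint and reflective-marker trajectories.
#' Positions are stored as a `T x 3 x L` array (mm) over `T` frames and `L`
#' named landmarks, with strictly increasing timestamps in seconds.
#'
#' @param positions `T x 3 x L` numeric array, or a named list of `T x 3`
#'   matrices (one per landmark).
#' @param times strictly increasing numeric timestamps (s), length `T`.
#' @param rate_hz nominal sampling rate (> 0).
#' @param source one of `"kinect"`, `"mocap"`, `"synthetic-truth"`.
#' @param names landmark names; defaults to `dimnames(positions)[[3]]` or the
#'   list names.
#' @param validate check invariants (default TRUE).
#' @return object of class `landmark_series`.
#' @export
landmark_series <- function(positions, times, rate_hz, source,
                            names = NULL, validate = TRUE) {
  if (is.list(positions) && !is.array(positions)) {
    if (is.null(names)) names <- base::names(positions)
    if (length(positions) == 0) stop("no landmarks supplied", call. = FALSE)
    Tn <- nrow(positions[[1]])
    arr <- array(NA_real_, dim = c(Tn, 3, length(positions)),
                 dimnames = list(NULL, c("x", "y", "z"), names))
    for (i in seq_along(positions)) arr[, , i] <- positions[[i]]
    positions <- arr
  }
  if (is.null(names)) names <- dimnames(positions)[[3]]
  dimnames(positions) <- list(NULL, c("x", "y", "z"), names)
  obj <- structure(list(source = source,
                        rate_hz = as.numeric(rate_hz),
                        names = names,
                        positions = positions,
                        times = as.numeric(times)),
                   class = "landmark_series")
  if (validate) validate_landmark_series(obj)
  obj
}

validate_landmark_series <- function(x) {
  stopifnot(inherits(x, "landmark_series"))
  if (!x$source %in% c("kinect", "mocap", "synthetic-truth")) {
    stop("unknown source '", x$source, "'", call. = FALSE)
  }
  if (!is.finite(x$rate_hz) || x$rate_hz <= 0) {
    stop("rate_hz must be a positive number", call. = FALSE)
  }
  d <- dim(x$positions)
  if (length(d) != 3 || d[2] != 3) {
    stop("positions must be a T x 3 x L array", call. = FALSE)
  }
  if (d[1] < 2) stop("a landmark series needs at least 2 frames", call. = FALSE)
  if (length(x$times) != d[1]) {
    stop("ragged series: ", length(x$times), " timestamps for ", d[1],
         " frames", call. = FALSE)
  }
  if (any(diff(x$times) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (length(x$names) != d[3] || anyDuplicated(x$names)) {
    stop("landmark names must be unique and match the position array",
         call. = FALSE)
  }
  registry <- switch(x$source,
                     kinect = KINECT_LANDMARKS,
                     mocap = MOCAP_LANDMARKS,
                     "synthetic-truth" = NULL)
  if (!is.null(registry)) {
    unknown <- setdiff(x$names, registry)
    if (length(unknown) > 0) {
      stop("unknown ", x$source, " landmark name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  required <- switch(x$source,
                     kinect = KINECT_LANDMARKS,
                     mocap = MOCAP_REQUIRED_DYNAMIC,
                     NULL)
  if (!is.null(required)) {
    missing <- setdiff(required, x$names)
    if (length(missing) > 0) {
      stop("missing required ", x$source, " landmark(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

#' Extract one landmark's trajectory
#'
#' @param series a [landmark_series()].
#' @param name landmark name.
#' @return `T x 3` matrix (mm).
#' @export
landmark_get <- function(series, name) {
  if (!name %in% series$names) {
    stop("landmark '", name, "' not present in series", call. = FALSE)
  }
  series$positions[, , name, drop = TRUE]
}

n_frames <- function(series) dim(series$positions)[1]

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf("<landmark_series> source=%s  %d frames @ %.6g Hz  %d landmarks\n",
              x$source, n_frames(x), x$rate_hz, length(x$names)))
  cat(" landmarks:", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

#' Assemble a trial record
#'
#' Bundles the concurrently recorded skeleton and marker streams of one trial,
#' with the optional static calibration trial and (for synthetic corpora) the
#' generating truth angles.
#'
#' @param subject_id,task,trial_id identifiers; `task` must be one of the four
#'   task codes (see [task_profiles()]).
#' @param kinect_stream,mocap_stream [landmark_series()] of matching source.
#' @param static_trial optional mocap-source static (anatomical pose) series;
#'   required when the dynamic mocap stream lacks the elbow/wrist landmarks
#'   EM/EL/RS/US (they are then CAST-reconstructed from the clusters).
#' @param truth_angles optional generating [angle_waveform()] (synthetic only).
#' @return object of class `trial_record`.
#' @export
trial_record <- function(subject_id, task, trial_id,
                         kinect_stream, mocap_stream,
                         static_trial = NULL, truth_angles = NULL) {
  task <- match.arg(task, TASKS)
  stopifnot(inherits(kinect_stream, "landmark_series"),
            inherits(mocap_stream, "landmark_series"))
  if (kinect_stream$source != "kinect") stop("kinect_stream source must be 'kinect'")
  if (mocap_stream$source != "mocap") stop("mocap_stream source must be 'mocap'")
  needs_cast <- !all(c("EM", "EL", "RS", "US") %in% mocap_stream$names)
  if (needs_cast && is.null(static_trial)) {
    stop("static_trial is required when the dynamic mocap stream omits ",
         "EM/EL/RS/US", call. = FALSE)
  }
  structure(list(subject_id = subject_id, task = task, trial_id = trial_id,
                 kinect_stream = kinect_stream, mocap_stream = mocap_stream,
                 static_trial = static_trial, truth_angles = truth_angles),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> subject=%s task=%s trial=%s\n",
              x$subject_id, x$task, x$trial_id))
  invisible(x)
}
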