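# AngleWaveform: the 4-channel joint-angle time series [FE, AA, IE, EFE].

#' Construct an angle waveform
#'
#' A `T x 4` joint-angle time series in degrees with the fixed channel order
#' FE (shoulder flexion/extension), AA (shoulder adduction/abduction),
#' IE (shoulder internal/external rotation), EFE (elbow flexion/extension).
#' A waveform is *normalized* when it has exactly 101 samples representing
#' 0--100% of the movement.
#'
#' @param values `T x 4` numeric matrix (degrees).
#' @param rate_hz sampling rate in Hz, or `NA` for time-normalized waveforms.
#' @param times optional timestamps (s), length `T`.
#' @param normalized logical; TRUE requires `T == 101`.
#' @param task,subject_id,trial_id optional identifiers.
#' @param source free-text provenance tag (e.g. `"kinect"`, `"uwa"`,
#'   `"refined"`, `"truth"`).
#' @return object of class `angle_waveform`.
#' @export
angle_waveform <- function(values, rate_hz = NA_real_, times = NULL,
                           normalized = FALSE, task = NULL,
                           subject_id = NULL, trial_id = NULL,
                           source = "unknown") {
  values <- as.matrix(values)
  if (ncol(values) != 4) {
    stop("an angle waveform has exactly 4 channels [FE, AA, IE, EFE]",
         call. = FALSE)
  }
  colnames(values) <- ANGLE_CHANNELS
  if (!is.null(task)) task <- match.arg(task, TASKS)
  obj <- structure(list(values = values, rate_hz = as.numeric(rate_hz),
                        times = times, normalized = isTRUE(normalized),
                        task = task, subject_id = subject_id,
                        trial_id = trial_id, source = source),
                   class = "angle_waveform")
  validate_angle_waveform(obj)
  obj
}

validate_angle_waveform <- function(wf) {
  if (any(!is.finite(wf$values))) {
    stop("angle waveform contains non-finite values", call. = FALSE)
  }
  if (wf$normalized && nrow(wf$values) != 101) {
    stop("a normalized waveform must have exactly 101 samples", call. = FALSE)
  }
  if (!is.null(wf$times) && length(wf$times) != nrow(wf$values)) {
    stop("times length must match the number of samples", call. = FALSE)
  }
  invisible(wf)
}

#' @export
print.angle_waveform <- function(x, ...) {
  cat(sprintf("<angle_waveform> %d x 4 (%s)%s%s\n", nrow(x$values), x$source,
              if (x$normalized) " normalized" else
                sprintf(" @ %.6g Hz", x$rate_hz),
              if (!is.null(x$task)) paste0("  task=", x$task) else ""))
  invisible(x)
}

# Replace the value matrix, keeping metadata.
wf_with_values <- function(wf, values, rate_hz = wf$rate_hz,
                           times = wf$times, normalized = wf$normalized) {
  angle_waveform(values, rate_hz = rate_hz, times = times,
                 normalized = normalized, task = wf$task,
                 subject_id = wf$subject_id, trial_id = wf$trial_id,
                 source = wf$source)
}

#' Export / import an angle waveform as JSON
#'
#' The JSON document carries `channels`, `values` (row-major list of length-4
#' rows), `normalized`, `task`, `subject_id`, `trial_id` and `rate_hz`.
#'
#' @param wf an [angle_waveform()].
#' @param path file path.
#' @return `path` (write) or an [angle_waveform()] (read).
#' @export
write_angle_json <- function(wf, path) {
  doc <- list(channels = ANGLE_CHANNELS,
              values = unname(wf$values),
              normalized = wf$normalized,
              rate_hz = wf$rate_hz,
              task = wf$task, subject_id = wf$subject_id,
              trial_id = wf$trial_id, source = wf$source)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_angle_json
#' @export
read_angle_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(doc$channels), ANGLE_CHANNELS)) {
    stop("unexpected channel set in ", path, call. = FALSE)
  }
  angle_waveform(doc$values,
                 rate_hz = if (is.null(doc$rate_hz)) NA_real_ else doc$rate_hz,
                 normalized = isTRUE(doc$normalized),
                 task = doc$task, subject_id = doc$subject_id,
                 trial_id = doc$trial_id,
                 source = if (is.null(doc$source)) "unknown" else doc$source)
}
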