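# File formats: long-format landmark CSV (canonical interchange) and TRC.

#' Read a landmark trajectory CSV
#'
#' The canonical interchange dialect is long format with header
#' `time,landmark,x,y,z`, positions in mm and time in seconds. All landmarks
#' must share the same set of timestamps (frames are aligned on them).
#'
#' @param path file path.
#' @param source stream source: `"kinect"`, `"mocap"` or `"synthetic-truth"`;
#'   drives landmark-name validation.
#' @param rate_hz optional explicit rate; defaults to the inverse median
#'   timestamp step.
#' @return a [landmark_series()].
#' @export
read_landmark_csv <- function(path, source, rate_hz = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "landmark", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("landmark CSV must have columns time,landmark,x,y,z", call. = FALSE)
  }
  lms <- unique(df$landmark)
  times <- sort(unique(df$time))
  Tn <- length(times)
  arr <- array(NA_real_, dim = c(Tn, 3, length(lms)),
               dimnames = list(NULL, c("x", "y", "z"), lms))
  for (lm in lms) {
    sub <- df[df$landmark == lm, , drop = FALSE]
    if (nrow(sub) != Tn) {
      stop("ragged frame counts: landmark '", lm, "' has ", nrow(sub),
           " frames, expected ", Tn, call. = FALSE)
    }
    sub <- sub[order(sub$time), , drop = FALSE]
    if (any(sub$time != times)) {
      stop("landmark '", lm, "' is not aligned on the shared timestamps",
           call. = FALSE)
    }
    arr[, , lm] <- as.matrix(sub[, c("x", "y", "z")])
  }
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(diff(times))
  landmark_series(arr, times = times, rate_hz = rate_hz, source = source,
                  names = lms)
}

#' Write a landmark trajectory CSV
#'
#' Writes the long-format dialect read by [read_landmark_csv()]; re-reading
#' reproduces the series (positions to full double precision).
#'
#' @param series a [landmark_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(series, path) {
  validate_landmark_series(series)
  if (length(series$names) == 0) stop("empty landmark set", call. = FALSE)
  Tn <- n_frames(series)
  rows <- lapply(series$names, function(lm) {
    p <- series$positions[, , lm, drop = TRUE]
    data.frame(time = series$times, landmark = lm,
               x = p[, 1], y = p[, 2], z = p[, 3])
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) {
    stop("cannot write '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

#' Read a TRC marker file
#'
#' Supports the standard tab-separated TRC layout (header lines with
#' `DataRate`, `NumFrames`, `NumMarkers`, `Units`, a marker-name row, an
#' axis-label row, then `Frame# Time X1 Y1 Z1 ...`). Units `mm` are kept,
#' `m` converted to mm; anything else is rejected.
#'
#' @param path file path.
#' @param source source tag for the resulting series (default `"mocap"`).
#' @return a [landmark_series()].
#' @export
read_trc <- function(path, source = "mocap") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 6) stop("malformed TRC: too few lines", call. = FALSE)
  keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- stats::setNames(as.list(vals[seq_along(keys)]), keys)
  for (k in c("DataRate", "NumFrames", "NumMarkers", "Units")) {
    if (is.null(hdr[[k]]) || is.na(hdr[[k]])) {
      stop("malformed TRC header: missing ", k, call. = FALSE)
    }
  }
  rate <- as.numeric(hdr$DataRate)
  nmark <- as.integer(hdr$NumMarkers)
  units <- trimws(hdr$Units)
  scale <- switch(units, mm = 1, m = 1000,
                  stop("unsupported TRC units '", units, "'", call. = FALSE))
  name_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  marker_names <- name_row[-(1:2)]
  marker_names <- marker_names[marker_names != ""]
  if (length(marker_names) != nmark) {
    stop("malformed TRC: ", length(marker_names), " marker names for ",
         nmark, " markers", call. = FALSE)
  }
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  mat <- do.call(rbind, lapply(data_lines, function(l) {
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])
  }))
  if (ncol(mat) < 2 + 3 * nmark) stop("malformed TRC data rows", call. = FALSE)
  times <- mat[, 2]
  arr <- array(NA_real_, dim = c(nrow(mat), 3, nmark),
               dimnames = list(NULL, c("x", "y", "z"), marker_names))
  for (i in seq_len(nmark)) {
    arr[, , i] <- mat[, (3 + (i - 1) * 3):(5 + (i - 1) * 3)] * scale
  }
  landmark_series(arr, times = times, rate_hz = rate, source = source,
                  names = marker_names)
}

#' Write a TRC marker file
#'
#' Minimal standard-conforming writer (mm units), mainly so synthetic trials
#' can be exchanged with motion-capture tooling.
#'
#' @param series a [landmark_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trc <- function(series, path) {
  validate_landmark_series(series)
  Tn <- n_frames(series)
  L <- length(series$names)
  hdr1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  hdr2 <- "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames"
  hdr3 <- sprintf("%.6f\t%.6f\t%d\t%d\tmm\t%.6f\t1\t%d",
                  series$rate_hz, series$rate_hz, Tn, L, series$rate_hz, Tn)
  hdr4 <- paste(c("Frame#", "Time",
                  as.vector(rbind(series$names, "", ""))), collapse = "\t")
  axl <- unlist(lapply(seq_len(L), function(i) paste0(c("X", "Y", "Z"), i)))
  hdr5 <- paste(c("", "", axl), collapse = "\t")
  body <- vapply(seq_len(Tn), function(t) {
    xyz <- as.vector(series$positions[t, , ])  # x,y,z per marker, in order
    paste(c(t, format(series$times[t], digits = 12),
            format(xyz, digits = 12)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr1, hdr2, hdr3, hdr4, hdr5, "", body), path)
  invisible(path)
}
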