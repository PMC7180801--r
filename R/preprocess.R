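# Rate alignment, synchronization, zero-lag filtering, time normalization,
# and the [0,1] channel scaler.

#' Resample an angle waveform onto a uniform grid
#'
#' Cubic-spline interpolation of every channel onto a uniform `target_hz` grid
#' spanning the original time range; endpoints are preserved exactly. This is
#' the common 300 Hz grid on which the two systems are synchronized.
#'
#' @param wf an [angle_waveform()] with at least 4 samples and a known rate
#'   (or explicit `times`).
#' @param target_hz target rate (default 300).
#' @return resampled [angle_waveform()].
#' @export
resample_waveform <- function(wf, target_hz = 300) {
  validate_angle_waveform(wf)
  Tn <- nrow(wf$values)
  if (Tn < 4) stop("resampling needs at least 4 samples", call. = FALSE)
  times <- wf$times
  if (is.null(times)) {
    if (!is.finite(wf$rate_hz)) {
      stop("waveform has neither timestamps nor a known rate", call. = FALSE)
    }
    times <- (seq_len(Tn) - 1) / wf$rate_hz
  }
  new_times <- seq(times[1], times[Tn], by = 1 / target_hz)
  vals <- vapply(seq_len(4), function(j) {
    stats::spline(times, wf$values[, j], xout = new_times, method = "fmm")$y
  }, numeric(length(new_times)))
  wf_with_values(wf, vals, rate_hz = target_hz, times = new_times,
                 normalized = FALSE)
}

#' Synchronize two angle waveforms by cross-correlation
#'
#' Finds the integer lag maximizing the normalized cross-correlation of the
#' mean-removed synchronization channel (elbow FE by default, the
#' largest-amplitude channel in reaching tasks), shifts `b` by that lag and
#' trims both waveforms to their common overlap.
#'
#' @param a,b [angle_waveform()]s at a common rate.
#' @param channel synchronization channel (default `"EFE"`).
#' @param max_lag maximum |lag| searched, in samples (default: full overlap).
#' @param min_overlap_s minimum admissible overlap after the shift (s).
#' @return list with `lag` (samples by which `b` trails `a`), `a`, `b`
#'   (trimmed to equal length) and `peak_correlation`.
#' @export
synchronize_waveforms <- function(a, b, channel = "EFE", max_lag = NULL,
                                  min_overlap_s = 1) {
  validate_angle_waveform(a); validate_angle_waveform(b)
  if (!isTRUE(all.equal(a$rate_hz, b$rate_hz))) {
    stop("waveforms must share one rate before synchronization", call. = FALSE)
  }
  channel <- match.arg(channel, ANGLE_CHANNELS)
  xa <- a$values[, channel]; xb <- b$values[, channel]
  na <- length(xa); nb <- length(xb)
  # mild symmetric smoothing before correlation: suppresses noise-driven
  # peak wander without moving the peak of noise-free shifted copies
  smooth5 <- function(x) {
    y <- stats::filter(x, rep(1 / 5, 5), sides = 2)
    y[is.na(y)] <- x[is.na(y)]
    as.numeric(y)
  }
  sa <- smooth5(xa); sb <- smooth5(xb)
  min_overlap <- max(8, ceiling(min_overlap_s * a$rate_hz))
  if (is.null(max_lag)) max_lag <- min(na, nb) - 1
  max_lag <- min(max_lag, max(na, nb) - min_overlap)
  if (max_lag < 0 || min(na, nb) < min_overlap) {
    stop("overlap after synchronization is shorter than ", min_overlap_s,
         " s", call. = FALSE)
  }
  lags <- seq(-max_lag, max_lag)
  # positive lag: b is delayed by `lag` samples relative to a, i.e. a[t]
  # aligns with b[t + lag]. The correlation of each candidate overlap is
  # centered within that overlap (plain normalized cross-correlation of
  # step-like reaching signals has a nearly flat top whose maximum drifts
  # with the overlap window).
  overlap_idx <- function(l) {
    if (l >= 0) { ib <- (1 + l):nb; ia <- seq_len(na) }
    else { ia <- (1 - l):na; ib <- seq_len(nb) }
    n <- min(length(ia), length(ib))
    list(ia = ia[seq_len(n)], ib = ib[seq_len(n)], n = n)
  }
  cc <- vapply(lags, function(l) {
    ov <- overlap_idx(l)
    if (ov$n < min_overlap) return(-Inf)
    u <- sa[ov$ia]; v <- sb[ov$ib]
    u <- u - mean(u); v <- v - mean(v)
    su <- sqrt(sum(u^2)); sv <- sqrt(sum(v^2))
    if (su == 0 || sv == 0) return(-Inf)
    sum(u * v) / (su * sv)
  }, numeric(1))
  best <- which.max(cc)
  lag <- lags[best]
  peak <- cc[best]
  if (is.finite(peak) && peak < 0.5) {
    warning(sprintf("weak synchronization: peak correlation %.2f < 0.5", peak))
  }
  ov <- overlap_idx(lag)
  ia <- ov$ia; ib <- ov$ib; n <- ov$n
  if (n < min_overlap_s * a$rate_hz) {
    stop("overlap after synchronization is shorter than ", min_overlap_s,
         " s", call. = FALSE)
  }
  a2 <- wf_with_values(a, a$values[ia, , drop = FALSE],
                       times = if (is.null(a$times)) NULL else a$times[ia])
  b2 <- wf_with_values(b, b$values[ib, , drop = FALSE],
                       times = if (is.null(b$times)) NULL else b$times[ib])
  list(lag = lag, a = a2, b = b2, peak_correlation = peak)
}

# Steady-state initial conditions for an IIR filter (direct form II
# transposed), the standard construction that suppresses startup transients
# in forward-backward filtering.
iir_steady_state <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  comp <- matrix(0, n - 1, n - 1)         # companion matrix of a
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(comp), B)
}

#' Zero-lag Butterworth low-pass filter
#'
#' Fourth-order Butterworth low-pass (cut-off `fc`), applied forward and
#' backward so the net filter has zero phase lag and a squared magnitude
#' response `1 / (1 + (f/fc)^8)`. Edges are odd-reflection padded by
#' `3 * (order + 1)` samples and the filter state is initialized at steady
#' state, so constant signals pass through unchanged.
#'
#' @param wf an [angle_waveform()] with a known rate.
#' @param fc cut-off frequency in Hz (default 6).
#' @param order filter order for each pass (default 4).
#' @return filtered [angle_waveform()].
#' @export
lowpass_zero_lag <- function(wf, fc = 6, order = 4) {
  validate_angle_waveform(wf)
  fs <- wf$rate_hz
  if (!is.finite(fs)) stop("waveform rate is unknown", call. = FALSE)
  if (fs <= 2 * fc) stop("sampling rate must exceed twice the cut-off",
                         call. = FALSE)
  pad <- 3 * (order + 1)
  Tn <- nrow(wf$values)
  if (Tn <= 3 * pad) {
    stop("trial too short to filter (", Tn, " samples, need > ", 3 * pad, ")",
         call. = FALSE)
  }
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  b <- bf$b; a <- bf$a
  zi <- iir_steady_state(b, a)
  filt1 <- function(x) {
    # odd reflection about both endpoints
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[Tn] - x[(Tn - 1):(Tn - pad)])
    y <- cpp_iir_filter(b, a, xp, zi * xp[1])
    y <- rev(cpp_iir_filter(b, a, rev(y), zi * y[length(y)]))
    y[(pad + 1):(pad + Tn)]
  }
  vals <- apply(wf$values, 2, filt1)
  wf_with_values(wf, vals)
}

#' Time-normalize a waveform to 101 samples
#'
#' Cubic-spline resampling onto 101 evenly spaced points from the first to the
#' last sample, representing 0--100% of the movement. First and last values
#' are preserved exactly.
#'
#' @param wf an [angle_waveform()] with `T >= 4`.
#' @return normalized [angle_waveform()] (`T = 101`).
#' @export
time_normalize <- function(wf) {
  validate_angle_waveform(wf)
  Tn <- nrow(wf$values)
  if (Tn < 4) stop("time normalization needs at least 4 samples", call. = FALSE)
  if (Tn == 101 && wf$normalized) return(wf)
  s_in <- seq(0, 1, length.out = Tn)
  s_out <- seq(0, 1, length.out = 101)
  vals <- vapply(seq_len(4), function(j) {
    y <- stats::spline(s_in, wf$values[, j], xout = s_out, method = "fmm")$y
    y[1] <- wf$values[1, j]; y[101] <- wf$values[Tn, j]
    y
  }, numeric(101))
  wf_with_values(wf, vals, rate_hz = NA_real_, times = NULL, normalized = TRUE)
}

# ---------------------------------------------------------------------------
# Channel scaler: linear map of each channel onto [0,1], fitted on the pooled
# training waveforms of both systems so input and target share one geometry.

#' Fit the per-channel \[0,1\] scaler
#'
#' @param waveforms list of [angle_waveform()]s (training folds only, both the
#'   skeleton and gold-standard waveforms pooled).
#' @return object of class `channel_scaler` with per-channel `min` and `max`.
#' @export
fit_scaler <- function(waveforms) {
  if (length(waveforms) == 0) stop("empty training set", call. = FALSE)
  vals <- do.call(rbind, lapply(waveforms, function(w) w$values))
  mins <- apply(vals, 2, min)
  maxs <- apply(vals, 2, max)
  if (any(maxs - mins <= 0)) {
    bad <- ANGLE_CHANNELS[maxs - mins <= 0]
    stop("constant channel(s) in the training set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(min = mins, max = maxs), class = "channel_scaler")
}

#' Apply / invert the channel scaler
#'
#' `apply_scaler` maps degrees onto the unit interval; training values land in
#' \[0,1\], test values may exceed it and are deliberately not clipped.
#' `invert_scaler` is the exact inverse.
#'
#' @param scaler a [fit_scaler()] result.
#' @param wf an [angle_waveform()] (degrees / unit interval).
#' @return transformed [angle_waveform()].
#' @export
apply_scaler <- function(scaler, wf) {
  stopifnot(inherits(scaler, "channel_scaler"))
  vals <- sweep(sweep(wf$values, 2, scaler$min), 2, scaler$max - scaler$min, "/")
  wf_with_values(wf, vals)
}

#' @rdname apply_scaler
#' @export
invert_scaler <- function(scaler, wf) {
  stopifnot(inherits(scaler, "channel_scaler"))
  vals <- sweep(sweep(wf$values, 2, scaler$max - scaler$min, "*"), 2,
                scaler$min, "+")
  wf_with_values(wf, vals)
}
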