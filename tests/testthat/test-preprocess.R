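test_that("resampling preserves constants, endpoints and analytic sinusoids", {
  tt <- seq(0, 2, by = 1 / 30)
  const <- angle_waveform(matrix(5, length(tt), 4), rate_hz = 30, times = tt)
  rc <- resample_waveform(const, 300)
  expect_lt(max(abs(rc$values - 5)), 1e-12)
  expect_equal(rc$rate_hz, 300)

  sine <- angle_waveform(matrix(sin(2 * pi * tt), length(tt), 4),
                         rate_hz = 30, times = tt)
  rs <- resample_waveform(sine, 300)
  expect_lt(max(abs(rs$values[, 1] - sin(2 * pi * rs$times))), 1e-3)

  # already on the target grid: unchanged
  t3 <- seq(0, 1, by = 1 / 300)
  w3 <- angle_waveform(matrix(stats::rnorm(length(t3) * 4), ncol = 4),
                       rate_hz = 300, times = t3)
  expect_lt(max(abs(resample_waveform(w3, 300)$values - w3$values)), 1e-12)
})

test_that("synchronization recovers injected lags and trims to the overlap", {
  tt <- seq(0, 3, by = 1 / 300)
  base <- 40 * minimum_jerk((tt - 0.5) / 1.5)
  a <- angle_waveform(matrix(base, ncol = 4, nrow = length(tt)), rate_hz = 300)
  # b identical to a -> lag 0
  s0 <- synchronize_waveforms(a, a)
  expect_equal(s0$lag, 0)
  # b = a delayed by 47 samples (front padding with the initial value)
  delayed <- c(rep(base[1], 47), base[seq_len(length(base) - 47)])
  b <- angle_waveform(matrix(delayed, ncol = 4, nrow = length(tt)), rate_hz = 300)
  s <- synchronize_waveforms(a, b)
  expect_equal(s$lag, 47)
  expect_equal(nrow(s$a$values), nrow(s$b$values))
  expect_lt(max(abs(s$a$values - s$b$values)), 1e-9)
  # noisy delayed copy: within one sample at 5% amplitude noise. The fixture
  # is an irregular sequence of reaches -- a single slow ramp does not carry
  # enough timing information for sub-sample alignment at this noise level.
  rich <- 100 * minimum_jerk((tt - 0.4) / 0.45) -
    100 * minimum_jerk((tt - 1.1) / 0.5) +
    60 * minimum_jerk((tt - 1.8) / 0.4) - 25 * minimum_jerk((tt - 2.5) / 0.35)
  ar <- angle_waveform(matrix(rich, ncol = 4, nrow = length(tt)), rate_hz = 300)
  rich_del <- c(rep(0, 47), rich[seq_len(length(rich) - 47)])
  set.seed(77)
  for (k in 1:5) {
    noisy <- rich_del + stats::rnorm(length(rich_del), 0, 0.05 * 100)
    bn <- angle_waveform(matrix(noisy, ncol = 4, nrow = length(tt)), rate_hz = 300)
    expect_lte(abs(synchronize_waveforms(ar, bn)$lag - 47), 1)
  }
  # independent white noise -> weak-synchronization warning
  set.seed(78)
  wn1 <- angle_waveform(matrix(stats::rnorm(4 * length(tt)), ncol = 4), rate_hz = 300)
  wn2 <- angle_waveform(matrix(stats::rnorm(4 * length(tt)), ncol = 4), rate_hz = 300)
  expect_warning(synchronize_waveforms(wn1, wn2), "weak synchronization")
  # insufficient overlap after an extreme shift
  short <- angle_waveform(matrix(base[1:400], ncol = 4, nrow = 400), rate_hz = 300)
  expect_error(suppressWarnings(
    synchronize_waveforms(short, short, min_overlap_s = 2)), "overlap")
})

test_that("zero-lag Butterworth filter matches its analytic magnitude response", {
  fs <- 300
  tt <- seq(0, 3, by = 1 / fs)
  # DC gain exactly 1
  const <- angle_waveform(matrix(7, length(tt), 4), rate_hz = fs)
  expect_lt(max(abs(lowpass_zero_lag(const)$values - 7)), 1e-9)
  # two-pass magnitude 1/(1 + (f/fc)^8) at 1 Hz and 20 Hz, fc = 6 Hz
  for (f in c(1, 20)) {
    x <- sin(2 * pi * f * tt)
    wf <- angle_waveform(matrix(x, ncol = 4, nrow = length(tt)), rate_hz = fs)
    y <- lowpass_zero_lag(wf)$values[, 1]
    mid <- 200:(length(tt) - 200)
    gain <- sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2))
    expected <- 1 / (1 + (f / 6)^8)
    if (f == 1) expect_lt(abs(gain - expected), 1e-3)
    if (f == 20) expect_lt(gain, 0.01)
    if (f == 1) {
      # zero phase: cross-correlation peak at lag 0
      cc <- stats::ccf(y[mid], x[mid], lag.max = 20, plot = FALSE)
      expect_equal(cc$lag[which.max(cc$acf)], 0)
    }
  }
  expect_error(lowpass_zero_lag(angle_waveform(matrix(0, 10, 4), rate_hz = fs)),
               "short")
})

test_that("time normalization hits 101 samples, preserves endpoints and analytic curves", {
  tt <- seq(0, 1.7, by = 1 / 300)
  ramp <- angle_waveform(matrix(seq(0, 100, length.out = length(tt)),
                                ncol = 4, nrow = length(tt)), rate_hz = 300)
  n <- time_normalize(ramp)
  expect_true(n$normalized)
  expect_equal(nrow(n$values), 101)
  expect_lt(max(abs(n$values[, 1] - seq(0, 100, by = 1))), 1e-9)
  # endpoints exact
  expect_identical(n$values[1, 1], ramp$values[1, 1])
  expect_identical(n$values[101, 1], ramp$values[nrow(ramp$values), 1])
  # minimum-jerk curve against its closed form
  mj <- angle_waveform(matrix(90 * minimum_jerk(tt / 1.7), ncol = 4,
                              nrow = length(tt)), rate_hz = 300)
  nm <- time_normalize(mj)
  expect_lt(max(abs(nm$values[, 1] - 90 * minimum_jerk(seq(0, 1, by = 0.01)))),
            1e-6)
  # re-normalizing a normalized waveform is the identity
  expect_lt(max(abs(time_normalize(nm)$values - nm$values)), 1e-12)
})

test_that("the channel scaler is an exact invertible [0,1] map without clipping", {
  tau <- seq(0, 1, length.out = 101)
  w1 <- angle_waveform(matrix(seq(-40, 160, length.out = 101), 101, 4),
                       normalized = TRUE)
  sc <- fit_scaler(list(w1))
  mapped <- apply_scaler(sc, angle_waveform(matrix(60, 101, 4), normalized = TRUE))
  expect_equal(unname(mapped$values[1, 1]), 0.5)
  over <- apply_scaler(sc, angle_waveform(matrix(170, 101, 4), normalized = TRUE))
  expect_equal(unname(over$values[1, 1]), 1.05)  # not clipped
  set.seed(3)
  w2 <- angle_waveform(matrix(stats::rnorm(404, 20, 50), 101, 4), normalized = TRUE)
  back <- invert_scaler(sc, apply_scaler(sc, w2))
  expect_lt(max(abs(back$values - w2$values)), 1e-12)
  const <- angle_waveform(matrix(1, 101, 4), normalized = TRUE)
  expect_error(fit_scaler(list(const)), "constant")
})
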