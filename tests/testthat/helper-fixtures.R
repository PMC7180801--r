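# Shared fixtures: small noise-free trials and waveform builders.

# A noise-free single trial of the given task (deterministic).
make_clean_trial <- function(task = "t3_comb_hair", offset = 0.3,
                             subject_id = "S01") {
  pr <- task_profiles()[[task]]
  truth <- generate_truth(pr)
  fk <- forward_kinematics(truth, body_model(), offset = offset)
  trial_record(subject_id = subject_id, task = task, trial_id = "r1",
               kinect_stream = fk$kinect_truth, mocap_stream = fk$mocap,
               static_trial = fk$static, truth_angles = truth)
}

# Normalized 101-sample waveform from per-channel curves.
make_norm_waveform <- function(fun, task = NULL) {
  tau <- seq(0, 1, length.out = 101)
  v <- sapply(1:4, function(j) fun(tau, j))
  angle_waveform(v, normalized = TRUE, task = task)
}

# Random rigid transform (rotation + translation); returns function on T x 3.
random_rigid <- function() {
  th <- stats::runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]), 0, -sin(th[1]), cos(th[1])), 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0, sin(th[2]), 0, cos(th[2])), 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3)
  R <- Rz %*% Rx %*% Ry
  tr <- stats::runif(3, -500, 500)
  function(P) sweep(P %*% t(R), 2, -tr)
}

apply_rigid_series <- function(series, rigid) {
  arr <- series$positions
  for (i in seq_along(series$names)) arr[, , i] <- rigid(arr[, , i])
  out <- landmark_series(arr, times = series$times, rate_hz = series$rate_hz,
                         source = series$source, names = series$names,
                         validate = FALSE)
  for (a in c("truth_values", "body", "offset")) {
    attr(out, a) <- attr(series, a)
  }
  out
}

# Independent brute-force CMC (kept separate from the package implementation
# on purpose: dual-route check).
cmc_brute <- function(Y) {
  G <- ncol(Y); Tn <- nrow(Y)
  ybar_t <- apply(Y, 1, mean)
  ybar <- mean(Y)
  num <- 0; den <- 0
  for (g in seq_len(G)) for (t in seq_len(Tn)) {
    num <- num + (Y[t, g] - ybar_t[t])^2
    den <- den + (Y[t, g] - ybar)^2
  }
  1 - (num / (G * (Tn - 1))) / (den / (G * Tn - 1))
}
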