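# Shared fixtures, built in code.

# deterministic single-walk recording: 20 ICs spaced exactly 1 s
walk_fixture_config <- function(duration = 20, stride = 1, seed = 2) {
  sim_config(1, 0, stride_time_mean = stride, stride_time_sd = 0,
             gyro_bias = 0, noise_sd_accel = 0, noise_sd_gyro = 0,
             phase_plan = data.frame(phase = c("rest", "walk", "rest"),
                                     duration = c(2, duration, 2)),
             seed = seed)
}

# stride_window built directly from supplied channels
make_stride <- function(th, ay = NULL, az = NULL, gx = NULL, fs = 60,
                        tstance_frac = 0.55) {
  n <- length(th)
  dur <- n / fs
  structure(list(ic_start = 0, fc = tstance_frac * dur, ic_end = dur,
                 tstride = dur, tstance = tstance_frac * dur,
                 tswing = (1 - tstance_frac) * dur,
                 t = (seq_len(n) - 1) / fs, sample_rate = fs,
                 signals = list(ay = ay %||% th, az = az %||% th,
                                gx = gx %||% th, th = th)),
            class = "stride_window")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal orientation_trace wrapping one pitch channel
make_trace <- function(th, fs = 60) {
  n <- length(th)
  structure(list(t = (seq_len(n) - 1) / fs, theta_x = th,
                 theta_cov = rep(0, n), bias = rep(0, n), sample_rate = fs,
                 filtered_accel = cbind(th, th, th),
                 filtered_gyro = cbind(th, th, th),
                 filtered_theta = th),
            class = "orientation_trace")
}

# greedy event matching within a tolerance; returns precision and recall
match_events <- function(detected, truth, tol = 0.2) {
  tp <- 0; used <- rep(FALSE, length(truth))
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol)
    if (length(j)) { used[j[1]] <- TRUE; tp <- tp + 1 }
  }
  c(precision = if (length(detected)) tp / length(detected) else 0,
    recall = if (length(truth)) tp / length(truth) else 1)
}

interval_iou <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
  inter / (max(a[2], b[2]) - min(a[1], b[1]))
}

# steady-state amplitude of frequency f in y, by quadrature projection over
# the middle of the record (avoids edge transients and off-crest sampling)
measured_gain <- function(y, t, f, skip = 0.25) {
  m <- t >= skip * max(t) & t <= (1 - skip) * max(t)
  2 * abs(mean(y[m] * exp(-2i * pi * f * t[m])))
}

# perfectly linear regression fixture (the "linear generative law")
linear_law_fixture <- function(seed, n = 20, p = 8) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- sprintf("F%03d", seq_len(p))
  list(X = X, y = as.vector(X %*% c(3, 2, 1, rep(0, p - 3))))
}

# small shared hyperparameter grid (all four kernels, tie-break order)
small_grid <- function() {
  g <- svr_grid(c("linear", "quadratic", "cubic", "gaussian"),
                kernel_scale = c(0.1, 1, 10),
                box_constraint = c(0.001, 0.1, 10))
  g[g$kernel != "gaussian" | g$box_constraint %in% c(0.1, 10), ]
}

# memoized 10-subject pipeline cohort used by feature-level tests
shared_cohort_env <- new.env()
shared_cohort_features <- function() {
  if (is.null(shared_cohort_env$ft)) {
    cfg <- sim_config(10, severity = seq(1, 19, length.out = 10), seed = 401)
    shared_cohort_env$ft <- cohort_features(simulate_cohort(cfg))
  }
  shared_cohort_env$ft
}
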