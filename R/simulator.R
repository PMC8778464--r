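# Synthetic thigh-IMU TUG recordings with ground truth.
#
# The generator is angle-first: the thigh pitch theta_x(t) is synthesized from
# the TUG phase plan (sit, stand up, walk, turn, walk, sit down), the x-axis
# gyroscope is its derivative plus bias and noise, and the accelerometer is
# the gravity projection through the angle plus a small stride-locked motion
# term and noise. Ground-truth orientation, walking bouts, and gait events
# therefore exist by construction for every downstream detector.
#
# Severity (a PIGD-like 0-20 score) acts on the signal in fixed directions:
# oscillation amplitude (hence RMS and dominant-harmonic height) decreases,
# and stride-time variability increases, with severity.

#' Simulation configuration
#'
#' @param n_subjects Number of subjects.
#' @param severity Per-subject severity score in `[0, 20]` (PIGD scale span:
#'   five 0-4 items). Recycled to `n_subjects`; if `NULL`, cohort severities
#'   are the `n_subjects` quantiles of a Normal(7.3, 5.7) clipped to
#'   `[0, 20]` (the published cohort's PIGD OFF mean and SD).
#' @param stride_time_mean Mean stride time in seconds (default 1.13, the
#'   pooled parkinsonian value).
#' @param stride_time_sd Stride-time SD in seconds at severity 0 (default
#'   0.21); inflated by `(1 + severity/20)`.
#' @param walk_lengths Durations (s) of the two straight-walk bouts.
#' @param phase_plan Optional data.frame with columns `phase`
#'   (`rest|stand_up|walk|turn|sit_down`) and `duration` (s); overrides the
#'   default plan built from `walk_lengths`.
#' @param gyro_bias Constant gyroscope bias in deg/s (all channels).
#' @param noise_sd_accel Accelerometer white-noise SD in g.
#' @param noise_sd_gyro Gyroscope white-noise SD in deg/s.
#' @param fog_enabled Inject freezing-of-gait-like interruptions?
#' @param fog_rate Expected FOG episodes per walking bout.
#' @param sample_rate Sampling rate in Hz (default 60; must exceed 40 Hz to
#'   support the 0.5-20 Hz analysis band).
#' @param seed Integer seed; every draw derives deterministically from it.
#' @param base_amplitude_deg Thigh-pitch oscillation amplitude at severity 0.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_subjects = 1, severity = NULL,
                       stride_time_mean = 1.13, stride_time_sd = 0.21,
                       walk_lengths = c(10, 10), phase_plan = NULL,
                       gyro_bias = 0.5, noise_sd_accel = 0.02,
                       noise_sd_gyro = 1, fog_enabled = FALSE, fog_rate = 0.5,
                       sample_rate = 60, seed = 1L,
                       base_amplitude_deg = 20) {
  if (sample_rate <= 40) stop("sample_rate must exceed 2 x 20 Hz analysis band")
  if (stride_time_mean <= 0.5) stop("stride_time_mean must exceed 0.5 s")
  if (stride_time_sd < 0 || noise_sd_accel < 0 || noise_sd_gyro < 0 || fog_rate < 0) {
    stop("noise/variability parameters must be non-negative")
  }
  if (n_subjects < 1) stop("n_subjects must be at least 1")
  if (is.null(severity)) {
    severity <- pmin(20, pmax(0, stats::qnorm((seq_len(n_subjects) - 0.5) / n_subjects, 7.3, 5.7)))
  }
  severity <- rep_len(severity, n_subjects)
  if (any(severity < 0 | severity > 20)) stop("severity must lie in [0, 20]")
  if (is.null(phase_plan)) {
    phase_plan <- data.frame(
      phase = c("rest", "stand_up", "walk", "turn", "walk", "sit_down", "rest"),
      duration = c(2, 2, walk_lengths[1], 2, walk_lengths[2], 2, 2))
  }
  if (!all(c("phase", "duration") %in% names(phase_plan)) ||
      any(phase_plan$duration <= 0)) {
    stop("phase_plan needs positive durations and a 'phase' column")
  }
  structure(list(n_subjects = n_subjects, severity = severity,
                 stride_time_mean = stride_time_mean, stride_time_sd = stride_time_sd,
                 phase_plan = phase_plan, gyro_bias = gyro_bias,
                 noise_sd_accel = noise_sd_accel, noise_sd_gyro = noise_sd_gyro,
                 fog_enabled = fog_enabled, fog_rate = fog_rate,
                 sample_rate = sample_rate, seed = as.integer(seed),
                 base_amplitude_deg = base_amplitude_deg),
            class = "sim_config")
}

# run expr with a derived seed, restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

smoothstep <- function(u) { u <- pmin(1, pmax(0, u)); u * u * (3 - 2 * u) }

#' Simulate one subject's TUG recording
#'
#' @param config A [sim_config()].
#' @param subject_index 1-based subject index (`<= n_subjects`).
#' @param condition `"ON"` or `"OFF"`. The OFF state amplifies the
#'   severity-linked amplitude reduction (gain 1.2), emulating stronger
#'   impairment after therapy withdrawal.
#' @return List with elements `recording` (an [imu_recording()]) and `truth`
#'   (class `gait_ground_truth`: `bout_intervals` [start, end) matrix,
#'   `ic_times`, `fc_times`, `fog_intervals`, `severity`, and the noise-free
#'   pitch trace `theta_true` in radians).
#' @export
simulate_subject <- function(config, subject_index = 1, condition = c("ON", "OFF")) {
  stopifnot(inherits(config, "sim_config"))
  condition <- match.arg(condition)
  if (subject_index < 1 || subject_index > config$n_subjects) {
    stop("subject_index out of range")
  }
  seed_i <- (abs(config$seed) * 10007L + subject_index * 211L +
               if (condition == "OFF") 97L else 0L) %% 2147483647L
  with_sim_seed(seed_i, simulate_subject_impl(config, subject_index, condition))
}

simulate_subject_impl <- function(config, subject_index, condition) {
  fs <- config$sample_rate
  dt <- 1 / fs
  sev <- config$severity[subject_index]
  gain <- if (condition == "OFF") 1.2 else 1.0
  sev_frac <- min(1, sev / 20 * gain)
  # subject-level traits (condition-independent: drawn from a subject-only
  # seed): gait amplitude and preferred stride time vary between people
  # independently of severity
  traits <- with_sim_seed((abs(config$seed) * 7717L + subject_index * 13L) %% 2147483647L,
                          stats::rnorm(2))
  amp <- config$base_amplitude_deg * (1 - 0.6 * sev_frac) * exp(0.08 * traits[1])
  # gait-variability knob: stride_time_sd = 0 yields a fully deterministic
  # gait (exact periods, constant per-stride amplitude)
  vf <- config$stride_time_sd / 0.21
  st_mean <- max(0.7, config$stride_time_mean + 0.4 * config$stride_time_sd * traits[2])
  st_sd <- config$stride_time_sd * (1 + sev / 20)

  plan <- config$phase_plan
  starts <- cumsum(c(0, plan$duration))
  total <- starts[length(starts)]
  t <- seq(0, total - dt, by = dt)
  n <- length(t)

  theta <- numeric(n)          # deg
  u <- rep(NA_real_, n)        # stride phase (ICs at integer u)
  bouts <- NULL; ics <- c(); fcs <- c(); fogs <- NULL
  sit_angle <- 80
  # start seated only if the plan actually contains a stand-up transition
  standing <- !any(plan$phase == "stand_up")

  for (p in seq_len(nrow(plan))) {
    ph <- plan$phase[p]; t0 <- starts[p]; t1 <- starts[p + 1]
    idx <- which(t >= t0 & t < t1)
    if (ph == "rest") {
      theta[idx] <- if (standing) 0 else sit_angle
    } else if (ph == "stand_up") {
      theta[idx] <- sit_angle * (1 - smoothstep((t[idx] - t0) / (t1 - t0)))
      standing <- TRUE
    } else if (ph == "sit_down") {
      theta[idx] <- sit_angle * smoothstep((t[idx] - t0) / (t1 - t0))
      standing <- FALSE
    } else if (ph == "turn") {
      theta[idx] <- 2 * sin(2 * pi * 0.5 * (t[idx] - t0))
    } else if (ph == "walk") {
      # stride phase: ICs (pitch peaks) at integer phase, FC troughs at k+0.5.
      # The bout starts at phase -0.25 (a zero-crossing) so gait initiation is
      # continuous, and the trailing partial stride is amplitude-tapered to
      # zero so gait termination is continuous too.
      draw_T <- function() {
        Tk <- if (st_sd > 0) stats::rnorm(1, st_mean, st_sd) else st_mean
        min(2.5, max(0.6, Tk))
      }
      knots <- c(t0, t0 + 0.25 * draw_T())
      phases <- c(-0.25, 0)
      while (knots[length(knots)] < t1) {
        knots <- c(knots, knots[length(knots)] + draw_T())
        phases <- c(phases, phases[length(phases)] + 1)
      }
      uu <- stats::approx(knots, phases, xout = t[idx], rule = 2)$y
      u[idx] <- uu
      # per-stride amplitude jitter, more variable with severity
      amp_k <- amp * pmax(0.3, 1 + 0.05 * vf * (1 + sev / 20) * stats::rnorm(length(knots)))
      amp_t <- stats::approx(knots, amp_k, xout = t[idx], rule = 2)$y
      ic_k <- knots[-1][knots[-1] < t1]      # integer-phase knots inside the bout
      last_ic <- ic_k[length(ic_k)]
      taper <- rep(1, length(idx))
      tail_ <- t[idx] > last_ic
      taper[tail_] <- 1 - smoothstep((t[idx][tail_] - last_ic) / (t1 - last_ic))
      osc <- amp_t * taper * cos(2 * pi * uu)
      # FC truth: trough time (phase k + 0.5) between consecutive ICs
      fc_k <- stats::approx(phases, knots,
                            xout = seq_len(length(ic_k) - 1) - 1 + 0.5)$y

      if (config$fog_enabled) {
        n_ep <- stats::rpois(1, config$fog_rate)
        keep_ic <- rep(TRUE, length(ic_k))
        in_fog <- rep(FALSE, length(fc_k))
        for (e in seq_len(n_ep)) {
          dur <- stats::runif(1, 1.5, 3)
          s0 <- stats::runif(1, t0, max(t0, t1 - dur))
          s1 <- min(t1, s0 + dur)
          fogs <- rbind(fogs, c(s0, s1))
          inf_ <- t[idx] >= s0 & t[idx] < s1
          ftrem <- stats::runif(1, 3, 8)
          osc[inf_] <- 0.1 * osc[inf_] +
            2 * sin(2 * pi * ftrem * (t[idx][inf_] - s0))
          keep_ic <- keep_ic & !(ic_k >= s0 & ic_k < s1)
          in_fog <- in_fog | (fc_k >= s0 & fc_k < s1)
        }
        if (n_ep > 0) {
          # an FC is a truth event only if both flanking ICs survive and it
          # is itself outside every freeze interval
          fc_ok <- !in_fog & keep_ic[-length(keep_ic)] & keep_ic[-1]
          ic_k <- ic_k[keep_ic]; fc_k <- fc_k[fc_ok]
        }
      }
      theta[idx] <- osc
      bouts <- rbind(bouts, c(t0, t1))
      ics <- c(ics, ic_k); fcs <- c(fcs, fc_k)
    }
  }

  # locomotion bouts: walk intervals merged across interleaved turns (the
  # walk-turn-walk sequence of the TUG is one continuous locomotion period)
  if (!is.null(bouts) && nrow(bouts) > 1) {
    merged <- bouts[1, , drop = FALSE]
    for (k in 2:nrow(bouts)) {
      gap <- plan$phase[starts[-length(starts)] >= merged[nrow(merged), 2] &
                          starts[-length(starts)] < bouts[k, 1]]
      if (length(gap) && all(gap == "turn")) {
        merged[nrow(merged), 2] <- bouts[k, 2]
      } else {
        merged <- rbind(merged, bouts[k, ])
      }
    }
    bouts <- merged
  }

  theta_rad <- theta * pi / 180
  # gyro = central-difference derivative of the clean angle (deg/s) + bias + noise
  dtheta <- numeric(n)
  dtheta[1] <- (theta[2] - theta[1]) / dt
  dtheta[n] <- (theta[n] - theta[n - 1]) / dt
  dtheta[2:(n - 1)] <- (theta[3:n] - theta[1:(n - 2)]) / (2 * dt)
  gx <- dtheta + config$gyro_bias + stats::rnorm(n, 0, config$noise_sd_gyro)

  in_turn <- rep(FALSE, n)
  for (p in which(plan$phase == "turn")) {
    in_turn[t >= starts[p] & t < starts[p + 1]] <- TRUE
  }
  yaw_rate <- ifelse(in_turn, 90, 0)   # deg/s about the vertical (y) axis
  gy <- yaw_rate + config$gyro_bias + stats::rnorm(n, 0, config$noise_sd_gyro)
  gz <- config$gyro_bias + stats::rnorm(n, 0, config$noise_sd_gyro)

  # accel = gravity projection + stride-locked motion term + noise
  uu0 <- ifelse(is.na(u), 0, u)
  walkm <- !is.na(u)
  bounce <- 0.05 * (amp / config$base_amplitude_deg)
  ay <- cos(theta_rad) + bounce * walkm * sin(4 * pi * uu0) +
    stats::rnorm(n, 0, config$noise_sd_accel)
  az <- sin(theta_rad) + 0.6 * bounce * walkm * cos(4 * pi * uu0) +
    stats::rnorm(n, 0, config$noise_sd_accel)
  ax <- 0.3 * bounce * walkm * sin(2 * pi * uu0 + 1) +
    stats::rnorm(n, 0, config$noise_sd_accel)

  rec <- imu_recording(sprintf("S%02d", subject_index), condition, fs, t,
                       cbind(ax, ay, az), cbind(gx, gy, gz))
  truth <- structure(list(
    bout_intervals = bouts, ic_times = ics, fc_times = fcs,
    fog_intervals = fogs, severity = sev, condition = condition,
    theta_true = theta_rad, t = t), class = "gait_ground_truth")
  list(recording = rec, truth = truth)
}

#' Simulate a cohort
#'
#' One recording per subject per requested condition. The OFF condition
#' re-uses each subject with severity shifted by +1 point (the published
#' cohort's OFF-ON PIGD difference) and a 1.2 amplitude-effect gain, so OFF
#' recordings show stronger impairment than the matching ON ones.
#'
#' @param config A [sim_config()].
#' @param conditions Character vector, subset of `c("ON", "OFF")`.
#' @return List with `recordings` (list of `simulate_subject()` results) and
#'   `subject_table` (data.frame: subject_id, condition, pigd, updrs3,
#'   fog_status).
#' @export
simulate_cohort <- function(config, conditions = "ON") {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_subjects < 2) stop("a cohort needs at least 2 subjects")
  conditions <- match.arg(conditions, c("ON", "OFF"), several.ok = TRUE)
  recordings <- list()
  rows <- list()
  for (cond in conditions) {
    cfg <- config
    if (cond == "OFF") cfg$severity <- pmin(20, config$severity + 1)
    for (i in seq_len(config$n_subjects)) {
      sim <- simulate_subject(cfg, i, cond)
      key <- sprintf("S%02d_%s", i, cond)
      recordings[[key]] <- sim
      sev <- cfg$severity[i]
      updrs3 <- with_sim_seed((abs(config$seed) * 31L + i * 17L) %% 2147483647L,
                              round(pmin(108, pmax(0, 2.2 * sev + 12 + stats::rnorm(1, 0, 3)))))
      rows[[key]] <- data.frame(
        subject_id = sprintf("S%02d", i), condition = cond, pigd = sev,
        updrs3 = updrs3,
        fog_status = if (config$severity[i] >= 8) "FOG+" else "FOG-")
    }
  }
  list(recordings = recordings,
       subject_table = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Write a simulated cohort to disk
#'
#' One CSV per test (named `<subject>_<condition>.csv`) plus `subjects.csv`,
#' in the package's sensor CSV dialect.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(cohort$recordings)) {
    write_imu_csv(cohort$recordings[[key]]$recording,
                  file.path(dir, paste0(key, ".csv")))
  }
  write_subject_table(cohort$subject_table, file.path(dir, "subjects.csv"))
  invisible(dir)
}
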