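test_that("deterministic walk construction: ICs, spacing, periodic gyro", {
  cfg <- walk_fixture_config(duration = 20, stride = 1)
  s <- simulate_subject(cfg, 1)
  expect_length(s$truth$ic_times, 20)
  expect_equal(unique(round(diff(s$truth$ic_times), 9)), 1)
  # gyro x is periodic with the stride period during steady walking
  gx <- s$recording$gyro[, 1]
  i <- which(s$recording$t >= 5 & s$recording$t < 15)
  expect_equal(gx[i], gx[i + 60], tolerance = 1e-9)
})

test_that("same config and seed give bit-identical recordings", {
  cfg <- sim_config(2, c(4, 9), seed = 77)
  a <- simulate_subject(cfg, 1)
  b <- simulate_subject(cfg, 1)
  expect_identical(a, b)
})

test_that("ground-truth event invariants hold across severities and seeds", {
  for (seed in c(5, 6)) {
    cfg <- sim_config(3, c(0, 10, 20), fog_enabled = TRUE, fog_rate = 1,
                      seed = seed)
    for (i in 1:3) {
      tr <- simulate_subject(cfg, i)$truth
      expect_true(all(diff(tr$ic_times) > 0))
      # each FC strictly between consecutive ICs
      for (fc in tr$fc_times) {
        k <- findInterval(fc, tr$ic_times)
        expect_true(k >= 1 && k < length(tr$ic_times))
        expect_gt(fc, tr$ic_times[k]); expect_lt(fc, tr$ic_times[k + 1])
      }
      # every event inside some bout
      inside <- function(x) any(x >= tr$bout_intervals[, 1] &
                                  x < tr$bout_intervals[, 2])
      expect_true(all(vapply(tr$ic_times, inside, logical(1))))
      expect_true(all(vapply(tr$fc_times, inside, logical(1))))
      # no IC inside a FOG interval
      if (!is.null(tr$fog_intervals)) {
        for (r in seq_len(nrow(tr$fog_intervals))) {
          expect_false(any(tr$ic_times >= tr$fog_intervals[r, 1] &
                             tr$ic_times < tr$fog_intervals[r, 2]))
        }
      }
    }
  }
})

test_that("noiseless stride count equals bout duration / period within 1", {
  for (stride in c(0.9, 1.13, 1.4)) {
    cfg <- walk_fixture_config(duration = 18, stride = stride)
    tr <- simulate_subject(cfg, 1)$truth
    expect_lte(abs(length(tr$ic_times) - floor(18 / stride)), 1)
  }
})

test_that("oscillation amplitude decreases strictly with severity (r < -0.9)", {
  cfg <- sim_config(20, severity = 0:19, seed = 7)
  amps <- vapply(1:20, function(i) {
    tr <- simulate_subject(cfg, i)$truth
    m <- rep(FALSE, length(tr$t))
    for (k in seq_len(nrow(tr$bout_intervals))) {
      m <- m | (tr$t >= tr$bout_intervals[k, 1] & tr$t < tr$bout_intervals[k, 2])
    }
    stats::sd(tr$theta_true[m]) * sqrt(2)
  }, numeric(1))
  expect_lt(cor(amps, 0:19), -0.9)

  # stride-time variability is non-decreasing in severity (within-bout
  # intervals only: IC gaps spanning the turn are not stride times)
  stsd <- vapply(1:20, function(i) {
    tr <- simulate_subject(cfg, i)$truth
    d <- diff(tr$ic_times)
    stats::sd(d[d < 2.5])
  }, numeric(1))
  expect_gt(cor(stsd, 0:19), 0.3)
})

test_that("OFF condition is more impaired than ON for the same subject", {
  cfg <- sim_config(2, c(8, 14), seed = 9)
  for (i in 1:2) {
    on <- simulate_subject(cfg, i, "ON")$truth
    off <- simulate_subject(cfg, i, "OFF")$truth
    amp_of <- function(tr) {
      m <- tr$t >= tr$bout_intervals[1, 1] & tr$t < tr$bout_intervals[1, 2]
      stats::sd(tr$theta_true[m])
    }
    expect_lt(amp_of(off), amp_of(on))
  }
})

test_that("cohort has one recording and table row per subject-condition", {
  cfg <- sim_config(5, seed = 12)
  co <- simulate_cohort(cfg, conditions = c("ON", "OFF"))
  expect_length(co$recordings, 10)
  expect_equal(nrow(co$subject_table), 10)
  expect_equal(sum(co$subject_table$condition == "ON"), 5)
  # OFF severity is the ON severity + 1 (clipped)
  expect_equal(co$subject_table$pigd[co$subject_table$condition == "OFF"],
               pmin(20, co$subject_table$pigd[co$subject_table$condition == "ON"] + 1))
})

test_that("cohort CSV round trip preserves samples", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(2, c(3, 12), walk_lengths = c(5, 5), seed = 13)
  co <- simulate_cohort(cfg)
  write_cohort_csv(co, dir)
  back <- read_imu_csv(file.path(dir, "S01_ON.csv"), "S01", "ON")
  expect_equal(back$accel, co$recordings$S01_ON$recording$accel,
               tolerance = 1e-12)
  tab <- read_subject_table(file.path(dir, "subjects.csv"))
  expect_equal(tab$pigd, co$subject_table$pigd)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(sample_rate = 30), "sample_rate")
  expect_error(sim_config(stride_time_mean = 0.4), "stride_time_mean")
  expect_error(sim_config(severity = 25), "severity")
  expect_error(sim_config(phase_plan = data.frame(phase = "walk", duration = -1)),
               "duration")
  expect_error(simulate_subject(sim_config(2, c(1, 2)), 3), "out of range")
})
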