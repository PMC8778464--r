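# Walking-bout detection and stride segmentation.
#
# Bouts: the scalogram rows (one per scale) are averaged into a single
# intensity profile p(t); maximal runs where p(t) exceeds sd(p) -- computed
# globally over the whole recording -- are walking bouts. Runs separated by
# less than 0.5 s are merged, runs shorter than 2 s (less than two strides)
# are dropped.
#
# Contacts: within a bout the pitch signal is low-passed at 2 Hz (order 2,
# zero lag); initial contacts (ICs) are its positive peaks higher than the
# bout standard deviation and at least 0.5 s apart (higher peak wins a
# conflict); the final contact (FC) of stride i is the most negative local
# minimum strictly between IC_i and IC_{i+1}.

# Strict local maxima of x, height >= min_height, spacing >= min_dist samples
# (greedy by height: on conflict the higher peak is kept).
find_peaks <- function(x, min_height = -Inf, min_dist = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1
  cand <- cand[x[cand] >= min_height]
  if (!length(cand) || min_dist <= 0) return(sort(cand))
  cand <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect walking bouts from a scalogram
#'
#' Averages the |CWT| rows into one intensity profile and selects the regions
#' where it exceeds its global standard deviation.
#'
#' @param scalogram A [cwt_scalogram()].
#' @param min_duration Minimum bout length in seconds (default 2).
#' @param merge_gap Runs closer than this (s) are merged (default 0.5).
#' @return data.frame with columns `start`, `end` (seconds, `[start, end)`)
#'   and `mean_intensity`; zero rows when nothing exceeds threshold.
#' @export
detect_bouts <- function(scalogram, min_duration = 2, merge_gap = 0.5) {
  stopifnot(inherits(scalogram, "cwt_scalogram"))
  p <- colMeans(scalogram$magnitude)
  t <- scalogram$t
  thr <- stats::sd(p)
  above <- p > thr
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      mean_intensity = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs separated by short gaps
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- t[runs[i, 1]] - t[merged[nrow(merged), 2]]
      if (gap < merge_gap) merged[nrow(merged), 2] <- runs[i, 2]
      else merged <- rbind(merged, runs[i, ])
    }
  }
  dur <- t[merged[, 2]] - t[merged[, 1]]
  merged <- merged[dur >= min_duration, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  data.frame(start = t[merged[, 1]], end = t[merged[, 2]],
             mean_intensity = apply(merged, 1,
                                    function(rr) mean(p[rr[1]:rr[2]])))
}

#' Detect initial and final contacts within one walking bout
#'
#' @param theta Pitch signal restricted to one bout (radians or any
#'   monotone-equivalent unit; thresholds are scale-free).
#' @param fs Sampling rate in Hz.
#' @param t0 Time of the first sample (s), used to return absolute times.
#' @param lowpass_hz Anti-double-peak low-pass cut-off (default 2 Hz).
#' @param min_spacing IC minimum spacing in seconds (default 0.5).
#' @return List with `ic_times` and `fc_times` (absolute seconds); empty
#'   vectors when no peaks qualify.
#' @export
detect_contacts <- function(theta, fs, t0 = 0, lowpass_hz = 2,
                            min_spacing = 0.5) {
  if (length(theta) < fs) stop("bout shorter than 1 s")
  th <- lowpass_filter(theta, fs, lowpass_hz)
  ics <- find_peaks(th, min_height = stats::sd(th),
                    min_dist = round(min_spacing * fs))
  if (length(ics) < 1) return(list(ic_times = numeric(0), fc_times = numeric(0)))
  fcs <- integer(0)
  if (length(ics) >= 2) {
    for (i in seq_len(length(ics) - 1)) {
      seg <- (ics[i] + 1):(ics[i + 1] - 1)
      if (length(seg) < 3) next
      mins <- find_peaks(-th[seg])
      fcs <- c(fcs, if (length(mins)) seg[mins[which.min(th[seg][mins])]]
               else seg[which.min(th[seg])])
    }
  }
  list(ic_times = t0 + (ics - 1) / fs, fc_times = t0 + (fcs - 1) / fs)
}

#' Cut stride windows from an orientation trace
#'
#' One window per consecutive IC pair with its enclosed FC; each window
#' carries the band-passed `ay`, `az`, `gx` and pitch slices used by the
#' feature extractor, plus `Tstride = IC_{i+1} - IC_i`,
#' `Tstance = FC_i - IC_i`, `Tswing = IC_{i+1} - FC_i`.
#'
#' @param trace An `orientation_trace` (see [kalman_orientation()]).
#' @param ic_times,fc_times Contact times in seconds (one FC strictly inside
#'   each IC pair; strides with a missing or misplaced FC are dropped with a
#'   warning).
#' @return List of `stride_window` objects.
#' @export
cut_strides <- function(trace, ic_times, fc_times) {
  stopifnot(inherits(trace, "orientation_trace"))
  strides <- list()
  if (length(ic_times) < 2) return(strides)
  fs <- trace$sample_rate
  for (i in seq_len(length(ic_times) - 1)) {
    ic0 <- ic_times[i]; ic1 <- ic_times[i + 1]
    fc <- fc_times[fc_times > ic0 & fc_times < ic1]
    if (length(fc) != 1) {
      warning(sprintf("stride at %.2f s dropped: %s FC inside the IC pair",
                      ic0, if (length(fc)) "more than one" else "no"))
      next
    }
    idx <- which(trace$t >= ic0 & trace$t < ic1)
    if (length(idx) < 3) next
    strides[[length(strides) + 1]] <- structure(list(
      ic_start = ic0, fc = fc, ic_end = ic1,
      tstride = ic1 - ic0, tstance = fc - ic0, tswing = ic1 - fc,
      t = trace$t[idx], sample_rate = fs,
      signals = list(ay = trace$filtered_accel[idx, 2],
                     az = trace$filtered_accel[idx, 3],
                     gx = trace$filtered_gyro[idx, 1],
                     th = trace$filtered_theta[idx])),
      class = "stride_window")
  }
  strides
}

#' Full gait segmentation of one recording
#'
#' Convenience pipeline: Kalman orientation, CWT bout detection on the
#' band-passed pitch, contact detection and stride cutting.
#'
#' @param rec An [imu_recording()].
#' @param cwt_freq Locomotor band for the scalogram (Hz).
#' @param n_scales Number of CWT scales.
#' @param ... Passed to [kalman_orientation()].
#' @return List with `trace`, `bouts`, `ic_times`, `fc_times`, `strides`.
#' @export
segment_gait <- function(rec, cwt_freq = c(0.5, 2), n_scales = 32, ...) {
  trace <- kalman_orientation(rec, ...)
  sc <- cwt_scalogram(trace$filtered_theta, trace$sample_rate,
                      cwt_freq[1], cwt_freq[2], n_scales)
  bouts <- detect_bouts(sc)
  ics <- numeric(0); fcs <- numeric(0); strides <- list()
  for (b in seq_len(nrow(bouts))) {
    idx <- which(trace$t >= bouts$start[b] & trace$t < bouts$end[b])
    if (length(idx) < trace$sample_rate) next
    ct <- detect_contacts(trace$filtered_theta[idx], trace$sample_rate,
                          t0 = trace$t[idx[1]])
    ics <- c(ics, ct$ic_times); fcs <- c(fcs, ct$fc_times)
    # strides are cut per bout so no window spans a bout boundary
    strides <- c(strides, cut_strides(trace, ct$ic_times, ct$fc_times))
  }
  list(trace = trace, bouts = bouts, ic_times = ics, fc_times = fcs,
       strides = strides)
}
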