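# Per-stride gait features.
#
# 102 features per stride: 3 spatiotemporal (Tstride, Tstance, Tswing),
# 11 time-domain statistics x 4 components {ay, az, gx (omega_x), th
# (theta_x)} = 44, 7 correlation features, 6 spectral descriptors x 4
# components = 24, and 6 band-energy fractions x 4 components = 24.
# Components are the band-passed (0.5-20 Hz, zero-lag) signal slices of the
# stride window, the same channels the published correlation analysis uses.
#
# Spectra: every stride is represented on n = round(mean_stride_time * fs)
# points (68 at 60 Hz) by linear interpolation across its own duration, so
# all strides share a comparable representation with ~1 Hz resolution
# (frequency axis k / Tstride).

FEATURE_COMPONENTS <- c("ay", "az", "gx", "th")
TIME_FEATURE_IDS <- c("Min", "Max", "Mean", "Std", "RMS", "Range", "Entropy",
                      "nPeaks", "hPeaks", "vPeaks", "Zc")
CORR_FEATURES <- c("Corr_ay_az", "Corr_ay_gx", "Corr_ay_th", "Corr_az_gx",
                   "Corr_az_th", "Corr_gx_th", "Corr_th_lag1")
SPEC_FEATURE_IDS <- c("DHfrequency", "DHheight", "DHwidth", "Etot", "DHratio",
                      "sEntropy")
BIN_EDGES <- c(0.5, 2, 4, 8, 12, 16, 20)   # locomotor / freeze-band split

#' Canonical feature names
#'
#' The fixed, documented order of the 102 per-stride features: time-domain
#' statistics by feature then component, the 7 correlation features, spectral
#' descriptors by feature then component, 6 band-energy fractions per
#' component, and the three temporal gait parameters.
#'
#' @return Character vector of length 102.
#' @export
pigd_feature_names <- function() {
  c(as.vector(t(outer(TIME_FEATURE_IDS, FEATURE_COMPONENTS, paste, sep = "_"))),
    CORR_FEATURES,
    as.vector(t(outer(SPEC_FEATURE_IDS, FEATURE_COMPONENTS, paste, sep = "_"))),
    as.vector(t(outer(paste0("binEnergy", 1:6), FEATURE_COMPONENTS, paste, sep = "_"))),
    c("Tstride", "Tstance", "Tswing"))
}

# Shannon entropy of the normalized absolute-amplitude distribution
signal_entropy <- function(x, eps = 1e-5) {
  s <- sum(abs(x))
  if (s == 0) return(0)
  p <- abs(x) / s
  -sum(p * log(p + eps))
}

#' Time-domain features of one stride
#'
#' Per component: Min, Max, Mean, Std (population form), RMS, Range, Entropy
#' (Shannon entropy of the normalized absolute-amplitude distribution),
#' nPeaks (strict local maxima higher than Std), hPeaks/vPeaks (mean/SD of
#' those peak heights), Zc (zero crossings per second of the mean-removed
#' signal); plus the 6 pairwise Pearson correlations among the components and
#' the lag-one autocorrelation of the pitch slice.
#'
#' @param stride A `stride_window` (see [cut_strides()]).
#' @return Named numeric vector of 51 features.
#' @export
time_features <- function(stride) {
  stopifnot(inherits(stride, "stride_window"))
  fs <- stride$sample_rate
  out <- c()
  for (comp in FEATURE_COMPONENTS) {
    x <- stride$signals[[comp]]
    if (length(x) < 2) stop("stride has fewer than 2 samples")
    n <- length(x)
    mu <- mean(x)
    sdev <- sqrt(mean((x - mu)^2))
    pk <- find_peaks(x, min_height = sdev)
    hts <- x[pk]
    xc <- x - mu
    sgn <- sign(xc[xc != 0])
    zc <- if (length(sgn) > 1) sum(sgn[-1] != sgn[-length(sgn)]) else 0
    v <- c(min(x), max(x), mu, sdev, sqrt(mean(x^2)), max(x) - min(x),
           signal_entropy(x), length(pk),
           if (length(pk)) mean(hts) else 0,
           if (length(pk) > 1) stats::sd(hts) else 0,
           zc / (n / fs))
    names(v) <- paste(TIME_FEATURE_IDS, comp, sep = "_")
    out <- c(out, v)
  }
  corr <- numeric(7)
  pairs <- utils::combn(FEATURE_COMPONENTS, 2)
  for (j in 1:6) {
    a <- stride$signals[[pairs[1, j]]]
    b <- stride$signals[[pairs[2, j]]]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant channel in stride; correlation set to 0")
      corr[j] <- 0
    } else corr[j] <- stats::cor(a, b)
  }
  th <- stride$signals$th
  corr[7] <- if (stats::sd(th) == 0) 0 else
    stats::cor(th[-length(th)], th[-1])
  names(corr) <- CORR_FEATURES
  c(out, corr)
}

# one-sided magnitude spectrum of a stride slice on the canonical n points
stride_spectrum <- function(x, tdur, n_fft) {
  xi <- stats::approx(seq(0, tdur, length.out = length(x)), x,
                      xout = seq(0, tdur, length.out = n_fft))$y
  X <- stats::fft(xi)
  half <- n_fft %/% 2
  mag <- Mod(X[seq_len(half + 1)]) * 2 / n_fft   # amplitude spectrum
  mag[1] <- mag[1] / 2
  if (n_fft %% 2 == 0) mag[half + 1] <- mag[half + 1] / 2
  list(freq = (0:half) / tdur, mag = mag)
}

#' Spectral features of one stride
#'
#' Each component is interpolated onto `n_fft` points spanning the stride,
#' FFT-transformed, and described by: DHfrequency (dominant-harmonic
#' frequency in the 0.5-20 Hz search band), DHheight (its amplitude), DHwidth
#' (full width at half maximum), Etot (sum of spectral magnitudes above DC),
#' DHratio (share of Etot inside the DH width band), sEntropy (Shannon
#' entropy of the normalized magnitude spectrum), and 6 binEnergy fractions
#' over the bands 0.5-2 (locomotor), 2-4, 4-8 (freeze), 8-12, 12-16,
#' 16-20 Hz.
#'
#' @param stride A `stride_window`.
#' @param n_fft Number of FFT points; default `round(1.13 * fs)`, the pooled
#'   parkinsonian mean stride time times the sampling rate.
#' @return Named numeric vector of 48 features, or `NULL` when the stride is
#'   shorter than 3 samples (skipped).
#' @export
spectral_features <- function(stride, n_fft = NULL) {
  stopifnot(inherits(stride, "stride_window"))
  fs <- stride$sample_rate
  if (is.null(n_fft)) n_fft <- round(1.13 * fs)
  if (length(stride$signals[[1]]) < 3) return(NULL)
  spec <- c(); bins <- c()
  for (comp in FEATURE_COMPONENTS) {
    sp <- stride_spectrum(stride$signals[[comp]], stride$tstride, n_fft)
    f <- sp$freq; mag <- sp$mag
    etot <- sum(mag[-1])
    band <- which(f >= 0.5 & f <= 20 & f > 0)
    if (!length(band) || etot == 0) {
      v <- c(0, 0, 0, etot, 0, 0)
      be <- rep(0, 6)
    } else {
      pk <- band[which.max(mag[band])]
      dh_f <- f[pk]; dh_h <- mag[pk]
      half <- dh_h / 2
      # FWHM by linear interpolation away from the peak
      lo <- dh_f - (f[2] - f[1]) / 2
      for (j in rev(seq_len(pk - 1))) {
        if (mag[j] <= half) {
          lo <- f[j] + (f[j + 1] - f[j]) * (half - mag[j]) / (mag[j + 1] - mag[j])
          break
        }
        if (j == 1) lo <- f[1]
      }
      hi <- dh_f + (f[2] - f[1]) / 2
      nf <- length(f)
      for (j in (pk + 1):nf) {
        if (j > nf) break
        if (mag[j] <= half) {
          hi <- f[j - 1] + (f[j] - f[j - 1]) * (mag[j - 1] - half) / (mag[j - 1] - mag[j])
          break
        }
        if (j == nf) hi <- f[nf]
      }
      dh_w <- hi - lo
      # energy share of the dominant harmonic: power (|X|^2, Parseval) inside
      # the FWHM interval, which may sit asymmetrically around the peak when
      # leakage skews the lobe; Etot itself stays on the magnitude scale
      pw <- sum(mag[-1]^2)
      dh_ratio <- if (pw > 0) sum(mag[f >= lo & f <= hi & f > 0]^2) / pw else 0
      p <- mag[-1] / etot
      s_ent <- -sum(p * log(p + 1e-5))
      v <- c(dh_f, dh_h, dh_w, etot, min(1, dh_ratio), s_ent)
      be <- vapply(seq_len(6), function(k) {
        sum(mag[f > BIN_EDGES[k] & f <= BIN_EDGES[k + 1]]^2) / pw
      }, numeric(1))
    }
    names(v) <- paste(SPEC_FEATURE_IDS, comp, sep = "_")
    spec <- c(spec, v)
    names(be) <- paste(paste0("binEnergy", 1:6), comp, sep = "_")
    bins <- c(bins, be)
  }
  c(spec, bins)[c(as.vector(t(outer(SPEC_FEATURE_IDS, FEATURE_COMPONENTS, paste, sep = "_"))),
                  as.vector(t(outer(paste0("binEnergy", 1:6), FEATURE_COMPONENTS, paste, sep = "_"))))]
}

#' Extract the full 102-feature vector for each stride
#'
#' @param strides Nonempty list of `stride_window` objects.
#' @param n_fft Passed to [spectral_features()].
#' @return Matrix with one row per (non-skipped) stride and the 102 columns
#'   of [pigd_feature_names()].
#' @export
extract_features <- function(strides, n_fft = NULL) {
  if (!length(strides)) stop("no strides to extract features from")
  rows <- list()
  for (s in strides) {
    sp <- spectral_features(s, n_fft)
    if (is.null(sp)) next
    v <- c(time_features(s), sp,
           Tstride = s$tstride, Tstance = s$tstance, Tswing = s$tswing)
    rows[[length(rows) + 1]] <- v[pigd_feature_names()]
  }
  if (!length(rows)) stop("all strides were skipped")
  m <- do.call(rbind, rows)
  colnames(m) <- pigd_feature_names()
  stopifnot(ncol(m) == 102)
  m
}

#' Aggregate stride features to one subject-condition row
#'
#' Arithmetic mean over strides for every feature, plus metadata.
#'
#' @param vectors Feature matrix from [extract_features()].
#' @param subject_meta List or one-row data.frame with `subject_id`,
#'   `condition`, `fog_status`, `pigd`.
#' @return One-row data.frame: metadata, `n_strides`, then the 102 features.
#' @export
aggregate_subject <- function(vectors, subject_meta) {
  vectors <- rbind(vectors)
  if (!nrow(vectors)) stop("need at least one stride vector")
  cbind(data.frame(subject_id = subject_meta$subject_id,
                   condition = subject_meta$condition,
                   fog_status = subject_meta$fog_status,
                   pigd = subject_meta$pigd,
                   n_strides = nrow(vectors)),
        as.data.frame(t(colMeans(vectors))))
}

#' Process one recording end-to-end into a subject feature row
#'
#' Segmentation ([segment_gait()]) followed by feature extraction and
#' aggregation.
#'
#' @param rec An [imu_recording()].
#' @param subject_meta See [aggregate_subject()].
#' @param ... Passed to [segment_gait()].
#' @return One-row data.frame, or `NULL` when no strides were found.
#' @export
process_recording <- function(rec, subject_meta, ...) {
  seg <- segment_gait(rec, ...)
  if (length(seg$strides) < 1) return(NULL)
  aggregate_subject(extract_features(seg$strides), subject_meta)
}

#' Feature table for a whole cohort
#'
#' @param cohort Result of [simulate_cohort()], or a list with `recordings`
#'   (each holding `$recording`) and a `subject_table`.
#' @param ... Passed to [process_recording()].
#' @return data.frame with one row per subject-condition.
#' @export
cohort_features <- function(cohort, ...) {
  rows <- list()
  tab <- cohort$subject_table
  for (i in seq_len(nrow(tab))) {
    key <- sprintf("%s_%s", tab$subject_id[i], tab$condition[i])
    rec <- cohort$recordings[[key]]$recording
    r <- process_recording(rec, tab[i, ], ...)
    if (!is.null(r)) rows[[key]] <- r
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
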