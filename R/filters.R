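# Zero-lag Butterworth filtering.
#
# Digital Butterworth design by bilinear transform with band-edge pre-warping,
# applied forward and backward (odd-extension padding, steady-state initial
# conditions) so the net filter has zero phase lag and the squared magnitude
# response of the single-pass design.

#' Design a digital Butterworth filter
#'
#' Returns transfer-function coefficients for a low-, high- or band-pass
#' Butterworth filter obtained from the analog prototype by bilinear transform
#' with pre-warped band edges.
#'
#' @param order Filter order of the low-pass prototype (a band-pass of order
#'   `n` has `2n` poles).
#' @param cutoff Cut-off frequency in Hz (length 1 for `low`/`high`, length 2
#'   `c(low, high)` for `band`).
#' @param fs Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"band"`.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @keywords internal
butter_design <- function(order, cutoff, fs, type = c("low", "high", "band")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fs > 0)
  if (any(cutoff <= 0) || any(cutoff >= fs / 2)) {
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit-circle LHP poles
  warp <- function(f) 2 * fs * tan(pi * f / fs)

  if (type == "band") {
    if (length(cutoff) != 2 || cutoff[1] >= cutoff[2]) {
      stop("band-pass requires cutoff = c(low, high) with low < high")
    }
    w1 <- warp(cutoff[1]); w2 <- warp(cutoff[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    pa <- complex(0)
    for (p in proto) {
      m <- p * bw / 2
      d <- sqrt(m^2 - w0^2)
      pa <- c(pa, m + d, m - d)
    }
    za <- rep(0 + 0i, order)            # order zeros at s = 0, order at infinity
  } else {
    wc <- warp(cutoff[1])
    if (type == "low") {
      pa <- wc * proto
      za <- complex(0)
    } else {
      pa <- wc / proto
      za <- rep(0 + 0i, order)
    }
  }

  blt <- function(s) (2 * fs + s) / (2 * fs - s)
  pd <- blt(pa)
  zd <- c(blt(za), rep(-1 + 0i, length(pa) - length(za)))  # zeros at infinity -> z = -1

  poly_from_roots <- function(r) {
    cf <- 1 + 0i
    for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
    cf
  }
  b <- Re(poly_from_roots(zd))
  a <- Re(poly_from_roots(pd))

  # normalize passband gain at a reference frequency
  fref <- switch(type,
    low  = 0,
    high = fs / 2,
    band = sqrt(cutoff[1] * cutoff[2]))
  zref <- exp(-1i * 2 * pi * fref / fs)
  g <- abs(sum(b * zref^(seq_along(b) - 1)) / sum(a * zref^(seq_along(a) - 1)))
  list(b = b / g, a = a)
}

# Direct-form II transposed IIR filter with optional initial state.
lfilter <- function(b, a, x, zi = NULL) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, nf - 1) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nf > 2) {
      for (j in 1:(nf - 2)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[nf - 1] <- b[nf] * xi - a[nf] * yi
    y[i] <- yi
  }
  list(y = y, z = z)
}

# Steady-state DF2T state for a unit-step input (removes start-up transients).
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  comp <- matrix(0, nf - 1, nf - 1)
  comp[1, ] <- -a[2:nf]
  if (nf > 2) comp[cbind(2:(nf - 1), 1:(nf - 2))] <- 1
  solve(diag(nf - 1) - t(comp), b[2:nf] - a[2:nf] * b[1])
}

# Forward-backward application of b/a with odd-extension padding.
filtfilt_ba <- function(b, a, x) {
  n <- length(x)
  nf <- max(length(a), length(b))
  # generous odd-extension padding: narrow-band corners (0.5 Hz at 60 Hz)
  # have transients of hundreds of samples, far beyond the 3*(order) rule
  pad <- min(n - 1, max(3 * (nf - 1), 256))
  if (pad < 1) stop("signal too short to filter")
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  zi <- lfilter_zi(b, a)
  fwd <- lfilter(b, a, xe, zi * xe[1])$y
  bwd <- rev(lfilter(b, a, rev(fwd), zi * fwd[length(fwd)])$y)
  bwd[(pad + 1):(pad + n)]
}

#' Zero-lag Butterworth band-pass filter
#'
#' Forward-backward ("zero-phase") Butterworth filtering; the default
#' 0.5-20 Hz band of order 2 removes the mean, slow postural trends and
#' high-frequency noise from inertial gait signals while preserving timing.
#'
#' @param x Numeric vector, uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Order of the underlying low-pass prototype (default 2).
#' @return Filtered vector of the same length.
#' @examples
#' t <- seq(0, 5, by = 1 / 60)
#' x <- sin(2 * pi * 1 * t) + 2          # 1 Hz tone on a DC offset
#' y <- bandpass_filter(x, fs = 60)      # offset removed, tone kept
#' @export
bandpass_filter <- function(x, fs, low = 0.5, high = 20, order = 2) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high band edge must be below the Nyquist frequency")
  d <- butter_design(order, c(low, high), fs, "band")
  filtfilt_ba(d$b, d$a, x)
}

#' Zero-lag Butterworth low-pass filter
#'
#' @inheritParams bandpass_filter
#' @param cutoff Cut-off frequency in Hz.
#' @return Filtered vector of the same length.
#' @export
lowpass_filter <- function(x, fs, cutoff = 2, order = 2) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  d <- butter_design(order, cutoff, fs, "low")
  filtfilt_ba(d$b, d$a, x)
}
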