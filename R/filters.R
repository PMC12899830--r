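#' Zero-phase IIR filtering primitives
#'
#' Filter design (Butterworth band-pass via the analog prototype and the
#' bilinear transform; second-order mains notch) and zero-phase application
#' by forward-reverse filtering with odd reflection padding and steady-state
#' initial conditions. No external signal-processing dependency is used.
#'
#' @name filters
NULL

#' Filter specification for the fixed conditioning chain
#'
#' @param notch_freq Mains frequency to suppress, Hz.
#' @param notch_q Notch quality factor (centre frequency / -3 dB bandwidth).
#' @param bp_low,bp_high Band-pass edges, Hz.
#' @param bp_order Polynomial order of the band-pass before forward-reverse
#'   doubling (must be even; the low-pass prototype has `bp_order/2` poles).
#'   The default 4-pole band-pass becomes an effective 8th-order magnitude
#'   response after zero-phase application.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30,
                        bp_low = 1, bp_high = 45, bp_order = 4) {
  if (notch_q <= 0) eeg_stop("config", "notch_q must be positive")
  if (!(bp_low > 0 && bp_low < bp_high))
    eeg_stop("config", "need 0 < bp_low < bp_high")
  if (bp_order %% 2 != 0 || bp_order < 2)
    eeg_stop("config", "bp_order must be a positive even integer")
  structure(list(notch_freq = notch_freq, notch_q = notch_q,
                 bp_low = bp_low, bp_high = bp_high, bp_order = bp_order),
            class = "filter_spec")
}

# Real polynomial coefficients from a set of (conjugate-closed) roots.
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) + c(0, -ri * p)
  Re(p)
}

#' Butterworth band-pass design
#'
#' `order` is the polynomial order of the resulting band-pass transfer
#' function (even); the analog low-pass prototype therefore has `order/2`
#' poles. Frequencies are pre-warped for the bilinear transform.
#'
#' @param order Even band-pass polynomial order.
#' @param lo,hi Pass-band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` (length `order + 1`).
#' @export
butter_bandpass <- function(order, lo, hi, fs) {
  if (!(lo > 0 && lo < hi && hi < fs / 2))
    eeg_stop("config", "band edges must satisfy 0 < lo < hi < fs/2")
  n <- order / 2L
  k <- seq_len(n)
  # analog Butterworth prototype poles on the unit circle, left half plane
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warp <- function(f) 2 * fs * tan(pi * f / fs)
  w1 <- warp(lo); w2 <- warp(hi)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  # low-pass -> band-pass: each prototype pole splits into two
  ps <- p * bw / 2
  pbp <- c(ps + sqrt(ps^2 - w0^2), ps - sqrt(ps^2 - w0^2))
  zbp <- rep(0 + 0i, n)
  kg <- bw^n
  # bilinear transform
  fs2 <- 2 * fs
  zd <- (fs2 + zbp) / (fs2 - zbp)
  pd <- (fs2 + pbp) / (fs2 - pbp)
  kg <- kg * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  zd <- c(zd, rep(-1 + 0i, n))  # zeros at Nyquist from the transform
  list(b = kg * poly_from_roots(zd), a = poly_from_roots(pd))
}

#' Second-order IIR notch design (constrained biquad)
#'
#' @param freq Notch centre frequency, Hz.
#' @param q Quality factor.
#' @param fs Sampling rate, Hz.
#' @return list with `b` and `a`, each length 3.
#' @export
design_notch <- function(freq, q, fs) {
  if (freq <= 0 || freq >= fs / 2)
    eeg_stop("config", "notch frequency must lie inside (0, fs/2)")
  w0 <- 2 * pi * freq / fs
  # Orfanidis constrained biquad with -3 dB bandwidth w0/q
  beta <- tan(w0 / (2 * q))
  gain <- 1 / (1 + beta)
  list(b = gain * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * cos(w0) * gain, 2 * gain - 1))
}

# Steady-state initial conditions of the direct-form-II-transposed filter,
# so that a constant input x0 produces a constant output from sample one.
lfilter_zi <- function(b, a) {
  n <- length(a) - 1L
  if (n == 0L) return(numeric(0))
  # companion matrix of a (a[1] == 1)
  A <- matrix(0, n, n)
  if (n > 1L) A[cbind(2:n, 1:(n - 1))] <- 1
  A[1, ] <- -a[-1]
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n) - t(A), B)
}

# Linear filtering, direct form II transposed, with initial state zi.
lfilter <- function(b, a, x, zi = NULL) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  z <- if (is.null(zi)) numeric(n - 1L) else zi
  y <- numeric(length(x))
  bt <- b[-1]; at <- a[-1]; b1 <- b[1]
  for (i in seq_along(x)) {
    yi <- b1 * x[i] + z[1]
    z <- c(z[-1], 0) + bt * x[i] - at * yi
    y[i] <- yi
  }
  y
}

#' Zero-phase forward-reverse filtering
#'
#' Applies the filter once forward and once on the reversed signal, using odd
#' reflection padding of length `3 * max(length(a), length(b))` at both ends
#' and steady-state initial conditions scaled by the first padded sample.
#' The net phase response is zero and the magnitude response is squared.
#'
#' @param b,a Transfer-function coefficients.
#' @param x Numeric signal.
#' @return Filtered signal of the same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  padlen <- 3L * max(length(a), length(b))
  if (length(x) <= padlen)
    eeg_stop("data", "signal too short (%d samples) for padding length %d",
             length(x), padlen)
  # odd (antisymmetric) extension about the end points
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - padlen)]
  xe <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, xe, zi * xe[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1L):(padlen + length(x))]
}

#' Zero-phase mains notch filter
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length.
#' @export
notch_filter <- function(x, fs, spec = filter_spec()) {
  d <- design_notch(spec$notch_freq, spec$notch_q, fs)
  filtfilt(d$b, d$a, x)
}

#' Zero-phase Butterworth band-pass filter
#'
#' @inheritParams notch_filter
#' @return Filtered signal, same length.
#' @export
bandpass_filter <- function(x, fs, spec = filter_spec()) {
  if (spec$bp_high >= fs / 2)
    eeg_stop("config", "bp_high must be below Nyquist")
  d <- butter_bandpass(spec$bp_order, spec$bp_low, spec$bp_high, fs)
  filtfilt(d$b, d$a, x)
}
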