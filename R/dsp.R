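# Signal-processing primitives used by the event-detection chain.
# Implemented natively: the runtime has no DSP package, and each primitive
# (Savitzky-Golay differentiation, zero-phase Butterworth low-pass, analytic
# signal) is small, well-defined, and frozen against external oracle values
# in the test suite.

#' Savitzky-Golay convolution coefficients
#'
#' Least-squares polynomial smoothing/differentiation kernel for a centered
#' window. The returned vector `c` gives the estimate at the window center as
#' `sum(c * x[window])`, already scaled by `deriv!` so that applying it to
#' unit-spaced samples yields the `deriv`-th derivative per sample step.
#'
#' @param window odd window length in samples.
#' @param order polynomial order (`order < window`).
#' @param deriv derivative order (0 = smoothing).
#' @return numeric vector of length `window`.
#' @keywords internal
sg_coefficients <- function(window, order, deriv = 0L) {
  if (window %% 2L != 1L || window < 3L)
    abort("Savitzky-Golay window must be odd and >= 3", "config_error")
  if (order >= window)
    abort("Savitzky-Golay order must be < window", "config_error")
  if (deriv > order)
    abort("derivative order exceeds polynomial order", "config_error")
  h <- (window - 1L) / 2L
  x <- seq(-h, h)
  A <- outer(x, 0:order, `^`)
  G <- solve(crossprod(A), t(A))     # (order+1) x window
  G[deriv + 1L, ] * factorial(deriv)
}

# Apply a centered convolution kernel; returns NA in the half-window margins.
sg_apply <- function(x, coefs) {
  w <- length(coefs)
  h <- (w - 1L) / 2L
  n <- length(x)
  if (n < w) abort(sprintf("series length %d shorter than window %d", n, w),
                   "length_error")
  # stats::filter with sides = 2: y[i] = sum_j f[j] * x[i + h - j + 1]
  y <- as.numeric(stats::filter(x, rev(coefs), sides = 2))
  y[c(seq_len(h), seq(n - h + 1L, n))] <- NA_real_
  y
}

#' Low-pass Butterworth digital filter design
#'
#' Bilinear-transform design of an order-`n` low-pass Butterworth filter.
#' Returns transfer-function coefficients `b` (numerator) and `a`
#' (denominator), normalized so `a[1] = 1` and DC gain = 1.
#'
#' @param n filter order.
#' @param cutoff_hz -3 dB corner frequency in Hz.
#' @param fs sampling frequency in Hz.
#' @keywords internal
butter_lowpass <- function(n, cutoff_hz, fs) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2)
    abort("cutoff must lie in (0, fs/2)", "config_error")
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  k <- seq_len(n)
  # analog prototype poles on the left-half unit circle, scaled by warped wc
  theta <- pi * (2 * k + n - 1) / (2 * n)
  p_analog <- warped * complex(modulus = 1, argument = theta)
  # bilinear transform
  p_z <- (2 * fs + p_analog) / (2 * fs - p_analog)
  a <- Re(poly_from_roots(p_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, n)))   # n zeros at z = -1
  gain <- sum(a) / sum(b)                     # unit DC gain
  list(b = b * gain, a = a)
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0i) - c(0i, p * ri)
  p
}

# Direct-form IIR filtering y = filter(b, a, x). Initial conditions are
# the steady state for a constant input `x0` (the lfilter_zi convention),
# so a constant series passes through with no start-up transient.
iir_filter <- function(b, a, x, x0 = x[1]) {
  b <- b / a[1]; a <- a / a[1]
  nb <- length(b)
  v <- as.numeric(stats::filter(c(rep(x0, nb - 1L), x), b,
                                sides = 1))[-seq_len(nb - 1L)]
  if (length(a) > 1L) {
    y0 <- x0 * sum(b) / sum(a)
    as.numeric(stats::filter(v, -a[-1], method = "recursive",
                             init = rep(y0, length(a) - 1L)))
  } else v
}

#' Zero-phase forward-backward filtering
#'
#' Applies `iir_filter` forward and backward with odd-reflection padding at
#' both ends so start-up transients decay outside the data.
#'
#' @keywords internal
filtfilt_fb <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 20L)
  if (pad < 1L) return(x)
  pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  xe <- c(pre, x, post)
  y <- iir_filter(b, a, xe)
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq(pad + 1L, pad + n)]
}

#' Analytic signal via FFT
#'
#' Discrete analytic signal (positive-frequency spectrum doubled, negative
#' zeroed); `Arg()` of the result is the instantaneous phase.
#'
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Linear interpolation across TRUE runs of `mask`; ends extended with the
# nearest valid value. Errors if nothing is valid.
interp_masked <- function(x, mask) {
  if (all(mask)) abort("no valid samples to interpolate from", "signal_error")
  if (!any(mask)) return(x)
  idx <- seq_along(x)
  approx(idx[!mask], x[!mask], xout = idx, rule = 2)$y
}

# Maximal runs of TRUE in a logical vector -> data.frame(start, end) indices.
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Merge overlapping/adjacent integer intervals given as data.frame(start,end).
merge_runs <- function(runs) {
  if (nrow(runs) < 2L) return(runs)
  o <- order(runs$start)
  runs <- runs[o, , drop = FALSE]
  out_s <- runs$start[1]; out_e <- runs$end[1]
  res_s <- integer(0); res_e <- integer(0)
  for (i in seq(2L, nrow(runs))) {
    if (runs$start[i] <= out_e + 1L) {
      out_e <- max(out_e, runs$end[i])
    } else {
      res_s <- c(res_s, out_s); res_e <- c(res_e, out_e)
      out_s <- runs$start[i]; out_e <- runs$end[i]
    }
  }
  data.frame(start = c(res_s, out_s), end = c(res_e, out_e))
}
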