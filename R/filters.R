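# Zero-phase Butterworth bandpass filtering and FFT resampling.
#
# No DSP package ships with the supported stack, so the standard designs are
# implemented here: analog Butterworth prototype -> lowpass-to-bandpass
# transform -> bilinear transform, and forward-backward filtering with
# odd-extension padding and steady-state initial conditions.

# Polynomial coefficients (descending powers) from roots, via iterated
# convolution in the complex domain.
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0 + 0i) - c(0 + 0i, p * rt)
  p
}

#' Design a digital Butterworth bandpass filter
#'
#' Bilinear-transform design of an order-`order` analog Butterworth prototype
#' transformed to a bandpass (the resulting digital filter has `2 * order`
#' poles). Gain is normalized to unity at the (pre-warp corrected) geometric
#' center frequency.
#'
#' @param low,high band edges in Hz, `0 < low < high < fs / 2`.
#' @param fs sampling rate in Hz.
#' @param order prototype order (default 4).
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low, high, fs, order = 4) {
  if (!(low > 0 && high > low && high < fs / 2))
    stopf("band edges must satisfy 0 < low < high < fs/2 (got %g-%g at fs=%g)",
          low, high, fs)
  k <- seq_len(order)
  # analog prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low / fs)
  w2 <- fs2 * tan(pi * high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)
  # lowpass -> bandpass: each prototype pole yields a conjugate pair
  pb2 <- p * bw / 2
  disc <- sqrt(pb2^2 - w0^2)
  poles_a <- c(pb2 + disc, pb2 - disc)
  # bilinear transform; analog zeros are `order` at s=0 and `order` at infinity
  poles_d <- (fs2 + poles_a) / (fs2 - poles_a)
  zeros_d <- rep(c(1, -1), each = order)
  b <- Re(poly_from_roots(zeros_d))
  a <- Re(poly_from_roots(poles_d))
  # normalize to unit gain at the digital center frequency
  f0 <- fs / pi * atan(w0 / fs2)
  z0 <- exp(2i * pi * f0 / fs)
  h0 <- sum(b * z0^(-(seq_along(b) - 1))) / sum(a * z0^(-(seq_along(a) - 1)))
  list(b = b / Mod(h0), a = a)
}

#' Frequency response of a digital filter
#'
#' @param filt list with `b`, `a` as returned by [butter_bandpass()].
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return complex response at each frequency.
#' @export
filter_response <- function(filt, f, fs) {
  vapply(f, function(fi) {
    z <- exp(2i * pi * fi / fs)
    num <- sum(filt$b * z^(-(seq_along(filt$b) - 1)))
    den <- sum(filt$a * z^(-(seq_along(filt$a) - 1)))
    num / den
  }, complex(1))
}

# Steady-state initial filter state for a unit-step input (so that filtering a
# constant signal has no start-up transient).
lfilter_zi <- function(b, a) {
  m <- max(length(a), length(b))
  bb <- c(b, rep(0, m - length(b)))
  aa <- c(a, rep(0, m - length(a)))
  n <- m - 1
  # companion matrix of the denominator polynomial
  A <- matrix(0, n, n)
  A[1, ] <- -aa[-1] / aa[1]
  if (n > 1) A[cbind(2:n, 1:(n - 1))] <- 1
  B <- bb[-1] - bb[1] * aa[-1]
  solve(diag(n) - t(A), B)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward with odd-extension padding and
#' steady-state initial conditions, so edges carry no start-up transient and
#' the net phase response is zero.
#'
#' @param filt list with `b`, `a`.
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @export
filtfilt_zero_phase <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  n <- length(x)
  padlen <- 3 * max(length(a), length(b))
  if (n <= padlen)
    stopf("signal too short for zero-phase filtering (need > %d samples)", padlen)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- lfilter_cpp(b, a, y, zi * y[1])
  rev(y)[(padlen + 1):(padlen + n)]
}

#' Fourier-domain resampling of a vector
#'
#' Resamples `x` to `n_out` samples by spectral truncation / zero-padding
#' (band-limited interpolation); downsampling is inherently anti-aliased.
#'
#' @param x numeric vector.
#' @param n_out desired output length.
#' @return numeric vector of length `n_out`.
#' @export
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- fft(x)
  Y <- complex(length.out = n_out)
  N <- min(n, n_out)
  nyq <- N %/% 2 + 1
  Y[1:nyq] <- X[1:nyq]
  if (N > 2) {
    ntail <- N - nyq
    Y[(n_out - ntail + 1):n_out] <- X[(n - ntail + 1):n]
  }
  if (N %% 2 == 0) {
    if (n_out < n) {
      # fold the negative-Nyquist component of X into the retained bin
      Y[N %/% 2 + 1] <- Y[N %/% 2 + 1] + X[n - N %/% 2 + 1]
    } else {
      # split the Nyquist component between +/- bins
      Y[N %/% 2 + 1] <- Y[N %/% 2 + 1] * 0.5
      Y[n_out - N %/% 2 + 1] <- Y[N %/% 2 + 1]
    }
  }
  Re(fft(Y, inverse = TRUE)) / n
}
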