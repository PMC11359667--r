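#' Design a digital Butterworth band-pass filter
#'
#' Designs an order-`order` Butterworth band-pass filter for a signal sampled
#' at `fs` Hz, returning transfer-function coefficients in the usual
#' `b`/`a` convention (`a[1] == 1`). The design follows the classical route:
#' analog low-pass prototype, low-pass-to-band-pass transform, bilinear
#' transform with frequency pre-warping. The resulting filter has `2 * order`
#' poles.
#'
#' @param order prototype filter order (the band-pass filter has twice as
#'   many poles). Default 4, a common choice for sEMG conditioning.
#' @param low,high band edges in Hz; requires `0 < low < high < fs / 2`.
#' @param fs sampling rate in Hz.
#' @return list with numeric vectors `b` (numerator) and `a` (denominator),
#'   both of length `2 * order + 1`.
#' @examples
#' co <- butter_bandpass(4, 20, 99, fs = 200)
#' length(co$b)
#' @export
butter_bandpass <- function(order, low, high, fs) {
  if (!is.numeric(order) || length(order) != 1L || order < 1)
    stop("'order' must be a positive integer")
  if (!(low > 0 && high > low))
    stop("band edges must satisfy 0 < low < high")
  if (high >= fs / 2)
    stop_config(sprintf(
      "upper band edge (%g Hz) must be strictly below Nyquist (%g Hz)",
      high, fs / 2))
  order <- as.integer(order)

  # analog low-pass prototype poles (Butterworth circle), unit cutoff
  m <- seq(-order + 1L, order - 1L, by = 2L)
  p <- -exp(1i * pi * m / (2 * order))
  k <- 1

  # pre-warped analog band edges (internal rate 2, matching the bilinear step)
  fs2 <- 2
  w1 <- 2 * fs2 * tan(pi * (low / (fs / 2)) / fs2)
  w2 <- 2 * fs2 * tan(pi * (high / (fs / 2)) / fs2)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # low-pass -> band-pass: each prototype pole splits in two; 'order' zeros
  # appear at s = 0
  p_lp <- p * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - w0^2), p_lp - sqrt(p_lp^2 - w0^2))
  z_bp <- rep(0 + 0i, order)
  k_bp <- k * bw^order

  # bilinear transform s -> 2*fs2*(z-1)/(z+1)
  fs4 <- 2 * fs2
  z_z <- (fs4 + z_bp) / (fs4 - z_bp)
  p_z <- (fs4 + p_bp) / (fs4 - p_bp)
  z_z <- c(z_z, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  k_z <- k_bp * Re(prod(fs4 - z_bp) / prod(fs4 - p_bp))

  list(b = Re(k_z * poly_from_roots(z_z)), a = Re(poly_from_roots(p_z)))
}

# monic polynomial coefficients (descending powers) from complex roots
poly_from_roots <- function(r) {
  coefs <- c(1 + 0i)
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs) * root
  coefs
}

#' Frequency response of a digital filter
#'
#' Evaluates `H(e^{i omega})` for transfer-function coefficients `b`, `a` at
#' physical frequencies `f` (Hz) given the sampling rate. Used mainly to
#' verify pass-band and stop-band behavior of designed filters.
#'
#' @param b,a transfer-function coefficients.
#' @param f frequencies in Hz at which to evaluate.
#' @param fs sampling rate in Hz.
#' @return complex vector of responses, one per frequency.
#' @export
freq_response <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  ev <- function(co, w) {
    vapply(w, function(wi) sum(co * exp(-1i * wi * (seq_along(co) - 1))),
           complex(1))
  }
  ev(b, w) / ev(a, w)
}

# steady-state initial filter state for a unit step input, so that the
# forward-backward pass starts without a startup transient
lfilter_zi <- function(b, a) {
  n <- length(a)
  companion <- matrix(0, n - 1, n - 1)
  companion[1, ] <- -a[2:n] / a[1]
  if (n > 2)
    companion[cbind(2:(n - 1), 1:(n - 2))] <- 1
  i_minus_a <- diag(n - 1) - t(companion)
  rhs <- b[2:n] - a[2:n] * b[1]
  solve(i_minus_a, rhs)
}

pad_ba <- function(b, a) {
  nf <- max(length(b), length(a))
  b <- c(b, rep(0, nf - length(b)))
  a <- c(a, rep(0, nf - length(a)))
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  list(b = b, a = a)
}

#' Apply an IIR filter (single pass)
#'
#' Causal application of the filter `b`,`a` with steady-state initial
#' conditions scaled to the first sample, which suppresses the worst of the
#' startup transient.
#'
#' @param b,a transfer-function coefficients.
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
iir_filter <- function(b, a, x) {
  co <- pad_ba(b, a)
  zi <- lfilter_zi(co$b, co$a)
  cpp_lfilter(co$b, co$a, x, zi * x[1])$y
}

#' Zero-phase forward-backward filtering
#'
#' Applies the filter forward and then backward so that the net phase
#' response is zero (no group delay). The signal is extended at both ends by
#' odd reflection before filtering and the extension is discarded afterwards;
#' each pass starts from the steady-state filter state matched to its first
#' sample.
#'
#' @param b,a transfer-function coefficients.
#' @param x numeric signal; must be longer than three times the filter order.
#' @return zero-phase filtered signal, same length as `x`.
#' @export
filtfilt_zero_phase <- function(b, a, x) {
  co <- pad_ba(b, a)
  nf <- length(co$b)
  padlen <- 3L * (nf - 1L)
  n <- length(x)
  if (n <= padlen)
    stop_data(sprintf(
      "signal too short for zero-phase filtering: %d samples, need > %d",
      n, padlen))
  zi <- lfilter_zi(co$b, co$a)
  ext <- c(2 * x[1] - x[(padlen + 1L):2],
           x,
           2 * x[n] - x[(n - 1L):(n - padlen)])
  y <- cpp_lfilter(co$b, co$a, ext, zi * ext[1])$y
  y <- rev(y)
  y <- cpp_lfilter(co$b, co$a, y, zi * y[1])$y
  y <- rev(y)
  y[(padlen + 1L):(padlen + n)]
}
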