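#' Configuration for the preprocessing chain
#'
#' Band-pass filtering, per-channel normalization, rectification, moving-RMS
#' envelope extraction, and segmentation into fixed-length labeled windows.
#'
#' The default upper band edge is 99 Hz rather than the nominal 100 Hz of a
#' "20-100 Hz" sEMG passband: at 200 Hz sampling, 100 Hz sits exactly at
#' Nyquist and no digital filter can realize it, so the edge is pulled just
#' inside while preserving the intent.
#'
#' @param band passband `(low, high)` in Hz (default `c(20, 99)`).
#' @param filter_order Butterworth prototype order (default 4).
#' @param zero_phase apply the filter forward-backward for zero group delay
#'   (default TRUE).
#' @param normalization per-channel normalization, `"zscore"` or `"maxabs"`
#'   (default `"zscore"`); applied once per channel over the whole recording
#'   so relative burst amplitudes across segments are preserved.
#' @param envelope_window moving-RMS window in samples (default 25,
#'   i.e. 125 ms at 200 Hz).
#' @param raw_window raw samples extracted around each event (default 200).
#' @param kept_window samples retained after symmetric trimming (default
#'   150); `raw_window - kept_window` must be even.
#' @return object of class `emg_preprocess_config`.
#' @export
preprocess_config <- function(band = c(20, 99),
                              filter_order = 4L,
                              zero_phase = TRUE,
                              normalization = c("zscore", "maxabs"),
                              envelope_window = 25L,
                              raw_window = 200L,
                              kept_window = 150L) {
  normalization <- match.arg(normalization)
  cfg <- structure(list(
    band = as.numeric(band), filter_order = as.integer(filter_order),
    zero_phase = isTRUE(zero_phase), normalization = normalization,
    envelope_window = as.integer(envelope_window),
    raw_window = as.integer(raw_window),
    kept_window = as.integer(kept_window)),
    class = "emg_preprocess_config")
  if (length(cfg$band) != 2 || cfg$band[1] <= 0 || cfg$band[2] <= cfg$band[1])
    stop_config("band must be (low, high) with 0 < low < high")
  if (cfg$envelope_window < 1) stop_config("envelope_window must be >= 1")
  if (cfg$kept_window > cfg$raw_window)
    stop_config("kept_window must not exceed raw_window")
  if ((cfg$raw_window - cfg$kept_window) %% 2L != 0L)
    stop_config("raw_window - kept_window must be even (symmetric trim)")
  cfg
}

#' Band-pass filter one channel
#'
#' Applies the configured Butterworth band-pass to a single-channel signal.
#' With `zero_phase` the filter runs forward and backward, giving zero group
#' delay at the cost of squaring the magnitude response. The upper band edge
#' must lie strictly below Nyquist (`fs / 2`): a printed passband whose upper
#' edge equals Nyquist is undesignable and is rejected with an explicit
#' configuration error.
#'
#' @param signal numeric vector, one channel.
#' @param fs sampling rate in Hz.
#' @param cfg an [preprocess_config()] object.
#' @return filtered signal, same length as the input.
#' @export
bandpass <- function(signal, fs, cfg = preprocess_config()) {
  if (length(signal) <= 3 * cfg$filter_order)
    stop_data(sprintf("signal length %d too short for filter order %d",
                      length(signal), cfg$filter_order))
  co <- butter_bandpass(cfg$filter_order, cfg$band[1], cfg$band[2], fs)
  if (cfg$zero_phase) filtfilt_zero_phase(co$b, co$a, signal)
  else iir_filter(co$b, co$a, signal)
}

#' Normalize a signal
#'
#' `"zscore"` subtracts the mean and divides by the sample SD (denominator
#' `N - 1`); a constant input is a degenerate-input error. `"maxabs"` divides
#' by the maximum absolute value; an all-zero input is returned unchanged
#' with a warning.
#'
#' @param signal numeric vector.
#' @param mode `"zscore"` or `"maxabs"`.
#' @return normalized signal.
#' @export
normalize_signal <- function(signal, mode = c("zscore", "maxabs")) {
  mode <- match.arg(mode)
  if (mode == "zscore") {
    s <- sd(signal)
    if (!is.finite(s) || s == 0)
      stop_data("z-score normalization of a constant signal is undefined")
    (signal - mean(signal)) / s
  } else {
    m <- max(abs(signal))
    if (m == 0) {
      warning("maxabs normalization of an all-zero signal: returned unchanged")
      signal
    } else signal / m
  }
}

#' Full-wave rectification
#'
#' @param signal numeric vector.
#' @return elementwise absolute value.
#' @export
rectify <- function(signal) abs(signal)

#' Moving-RMS envelope
#'
#' Centered moving root-mean-square of a rectified signal; edge windows are
#' truncated so the output has the same length as the input. `window = 1`
#' returns the input.
#'
#' @param rectified nonnegative numeric vector.
#' @param window window length in samples (>= 1).
#' @return nonnegative envelope, same length as the input.
#' @export
envelope_rms <- function(rectified, window = 25L) {
  n <- length(rectified)
  window <- as.integer(window)
  if (window < 1) stop_config("envelope window must be >= 1")
  if (window > n) stop_config(sprintf(
    "envelope window (%d) exceeds signal length (%d)", window, n))
  h1 <- (window - 1L) %/% 2L
  h2 <- window %/% 2L
  cs <- cumsum(c(0, rectified^2))
  i <- seq_len(n)
  lo <- pmax(1L, i - h1)
  hi <- pmin(n, i + h2)
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Segment a recording into labeled windows
#'
#' Preprocesses each channel of the recording (zero-phase band-pass over the
#' full channel, then per-channel normalization over the whole recording),
#' extracts a `raw_window`-sample window centered on each event, trims
#' `(raw_window - kept_window) / 2` samples from each end (the ends of each
#' gesture peak are static and carry little information), and attaches the
#' rectified track and the moving-RMS envelope. The trimmed pre-rectification
#' track is kept because zero crossings must be counted before rectification.
#'
#' @param rec an `emg_recording`.
#' @param cfg an [preprocess_config()] object.
#' @return list of `emg_segment` objects, each a list with `label` and three
#'   channels x `kept_window` matrices: `filtered`, `rectified`, `envelope`.
#' @export
segment_recording <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  n <- ncol(rec$signal)
  n_ch <- nrow(rec$signal)
  rw <- cfg$raw_window
  kw <- cfg$kept_window
  trim <- (rw - kw) %/% 2L
  half <- rw %/% 2L

  ev <- rec$events
  if (nrow(ev) == 0) return(list())
  start <- ev$center_index - half
  end <- start + rw - 1L
  bad <- which(start < 1L | end > n)
  if (length(bad) > 0)
    stop_data(sprintf(
      "event %d (class %d, center %d) too close to the recording edge",
      bad[1], ev$class_id[bad[1]], ev$center_index[bad[1]]))

  proc <- matrix(0, nrow = n_ch, ncol = n)
  for (ch in seq_len(n_ch)) {
    filt <- bandpass(rec$signal[ch, ], rec$fs, cfg)
    proc[ch, ] <- normalize_signal(filt, cfg$normalization)
  }

  lapply(seq_len(nrow(ev)), function(e) {
    idx <- (start[e] + trim):(end[e] - trim)
    filtered <- proc[, idx, drop = FALSE]
    rectified <- abs(filtered)
    env <- t(apply(rectified, 1, envelope_rms, window = cfg$envelope_window))
    if (n_ch == 1) env <- matrix(env, nrow = 1)
    structure(list(label = ev$class_id[e], filtered = filtered,
                   rectified = rectified, envelope = env),
              class = "emg_segment")
  })
}
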