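#' Names and order of the ten time-domain features
#'
#' Fixed column order used throughout the package: for channel `j`, the ten
#' features occupy columns `(j - 1) * 10 + 1 .. j * 10` in this order.
#'
#' @return character vector of length 10.
#' @export
feature_names <- function() {
  c("min", "max", "sd", "zc", "rms", "aac", "afb", "mav", "len", "wamp")
}

#' Configuration for feature extraction
#'
#' Thresholds are in normalized amplitude units (the preprocessing chain
#' z-scores each channel, so 0.05 is 5% of one channel SD). The source study
#' never states its threshold values; these defaults are exposed so they can
#' be tuned.
#'
#' @param wamp_threshold Willison-amplitude threshold T (default 0.05).
#' @param afb_threshold first-burst detection threshold T (default 0.05).
#' @param afb_window samples searched after the first threshold crossing
#'   (default 40, i.e. 200 ms at 200 Hz).
#' @return object of class `emg_feature_config`.
#' @export
feature_config <- function(wamp_threshold = 0.05,
                           afb_threshold = 0.05,
                           afb_window = 40L) {
  if (wamp_threshold <= 0 || afb_threshold <= 0)
    stop_config("feature thresholds must be positive")
  if (afb_window < 1) stop_config("afb_window must be >= 1")
  structure(list(wamp_threshold = wamp_threshold,
                 afb_threshold = afb_threshold,
                 afb_window = as.integer(afb_window)),
            class = "emg_feature_config")
}

#' Time-domain feature operators
#'
#' The ten per-window feature operators used for gesture classification.
#' `x` is one channel of one segment. All magnitude features are intended
#' for the rectified track; `f_zc()` must be given the pre-rectification
#' filtered track, since rectification destroys sign changes.
#'
#' * `f_min()`, `f_max()`: smallest / largest value in the window.
#' * `f_sd()`: sample standard deviation (denominator `N - 1`).
#' * `f_zc()`: zero crossings, the number of indices with
#'   `x[i] * x[i + 1] < 0` (strict product rule: exact zeros do not count).
#' * `f_rms()`: root mean square.
#' * `f_aac()`: average amplitude change, `mean(abs(diff(x)))`.
#' * `f_afb()`: amplitude of first burst - the maximum of `x` over the
#'   window starting at the first index where `x >= threshold` and extending
#'   `window` samples (clipped to the end); 0 if the threshold is never
#'   crossed, so rest segments still yield a finite feature.
#' * `f_mav()`: mean absolute value.
#' * `f_len()`: waveform length, `sum(abs(diff(x)))`; satisfies
#'   `f_len(x) == f_aac(x) * (N - 1)`.
#' * `f_wamp()`: Willison amplitude, the number of consecutive-sample
#'   differences with `abs(diff) >= threshold`.
#'
#' @param x numeric vector (one channel of one segment).
#' @param threshold amplitude threshold for `f_afb()` / `f_wamp()`.
#' @param window search window in samples for `f_afb()`.
#' @return a single numeric value (a count for `f_zc()` and `f_wamp()`).
#' @name features
NULL

#' @rdname features
#' @export
f_min <- function(x) {
  if (length(x) < 1) stop_data("empty window")
  min(x)
}

#' @rdname features
#' @export
f_max <- function(x) {
  if (length(x) < 1) stop_data("empty window")
  max(x)
}

#' @rdname features
#' @export
f_sd <- function(x) {
  if (length(x) < 2) stop_data("SD needs at least two samples")
  sd(x)
}

#' @rdname features
#' @export
f_zc <- function(x) {
  n <- length(x)
  if (n < 2) return(0L)
  sum(x[-n] * x[-1] < 0)
}

#' @rdname features
#' @export
f_rms <- function(x) sqrt(mean(x^2))

#' @rdname features
#' @export
f_aac <- function(x) {
  if (length(x) < 2) stop_data("AAC needs at least two samples")
  mean(abs(diff(x)))
}

#' @rdname features
#' @export
f_afb <- function(x, threshold = 0.05, window = 40L) {
  tc <- which(x >= threshold)[1]
  if (is.na(tc)) return(0)
  max(x[tc:min(tc + window, length(x))])
}

#' @rdname features
#' @export
f_mav <- function(x) mean(abs(x))

#' @rdname features
#' @export
f_len <- function(x) sum(abs(diff(x)))

#' @rdname features
#' @export
f_wamp <- function(x, threshold = 0.05) {
  sum(abs(diff(x)) >= threshold)
}

#' Extract the feature matrix from segments
#'
#' Computes the ten features for every channel of every segment, giving
#' `10 * n_channels` columns per segment (80 for the 8-electrode armband).
#' Zero crossings are computed on the pre-rectification filtered track; all
#' other features on the rectified track. Columns are channel-major and
#' named `ch<j>_<feature>` in the order of [feature_names()].
#'
#' @param segments list of `emg_segment` objects with a common channel count.
#' @param cfg an [feature_config()] object.
#' @return object of class `emg_feature_matrix`: list with `values`
#'   (segments x features numeric matrix, no missing values) and `labels`
#'   (integer class ids).
#' @export
extract_features <- function(segments, cfg = feature_config()) {
  if (length(segments) == 0)
    stop_data("no segments to extract features from")
  n_ch <- nrow(segments[[1]]$filtered)
  feats <- feature_names()
  cols <- as.vector(vapply(seq_len(n_ch),
                           function(j) paste0("ch", j, "_", feats),
                           character(length(feats))))
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    if (nrow(seg$filtered) != n_ch)
      stop_data(sprintf("segment %d has %d channels, expected %d",
                        i, nrow(seg$filtered), n_ch))
    out <- numeric(length(cols))
    for (j in seq_len(n_ch)) {
      xf <- seg$filtered[j, ]
      xr <- seg$rectified[j, ]
      out[(j - 1L) * 10L + 1:10] <- c(
        f_min(xr), f_max(xr), f_sd(xr), f_zc(xf), f_rms(xr), f_aac(xr),
        f_afb(xr, cfg$afb_threshold, cfg$afb_window), f_mav(xr), f_len(xr),
        f_wamp(xr, cfg$wamp_threshold))
    }
    out
  })
  values <- do.call(rbind, rows)
  colnames(values) <- cols
  if (anyNA(values)) stop_data("feature matrix contains missing values")
  structure(list(values = values,
                 labels = vapply(segments, function(s) as.integer(s$label),
                                 integer(1))),
            class = "emg_feature_matrix")
}

#' @export
print.emg_feature_matrix <- function(x, ...) {
  cat(sprintf("<emg_feature_matrix> %d segments x %d features, %d classes\n",
              nrow(x$values), ncol(x$values), length(unique(x$labels))))
  invisible(x)
}
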