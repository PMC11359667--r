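#' Per-class gesture segment counts of the emulated acquisition
#'
#' Number of recorded instances for each of the seven gesture classes in the
#' single-subject acquisition the synthetic generator emulates: index,
#' middle, ring and little finger extension, thumbs up, victory, and relaxed
#' hand. The counts sum to 6822 segments.
#'
#' @return named integer vector of length 7 (names `"1"`..`"7"`).
#' @export
default_class_counts <- function() {
  stats::setNames(c(1039L, 1017L, 1045L, 1084L, 1016L, 726L, 895L),
                  as.character(1:7))
}

#' Default per-class channel activation profile
#'
#' Burst gain multipliers (rows = classes, columns = channels) used by the
#' generator. Single-finger gestures (classes 1-5) each have one dominant
#' electrode with smooth leakage into the two neighboring electrodes,
#' mimicking electrode-position specificity of a circumferential armband.
#' The victory gesture (class 6) activates the index- and middle-finger
#' electrodes jointly, and the relaxed hand (class 7) produces no burst at
#' all - rest segments contain baseline noise only.
#'
#' @param n_channels number of electrodes (default 8).
#' @return 7 x `n_channels` nonnegative matrix.
#' @export
default_activation_profile <- function(n_channels = 8L) {
  prof <- matrix(0.05, nrow = 7, ncol = n_channels)
  wrap <- function(j) ((j - 1L) %% n_channels) + 1L
  for (k in 1:5) {
    prof[k, wrap(k)] <- 1.0
    prof[k, wrap(k - 1L)] <- 0.4
    prof[k, wrap(k + 1L)] <- 0.4
  }
  prof[6, ] <- 0.05
  prof[6, wrap(1L)] <- 0.8
  prof[6, wrap(2L)] <- 0.8
  prof[6, wrap(3L)] <- 0.3
  prof[6, wrap(8L)] <- 0.3
  prof[7, ] <- 0
  prof
}

#' Configuration for the synthetic sEMG generator
#'
#' Describes an armband-style acquisition: `n_channels` electrodes sampled at
#' `fs` Hz, one gesture instance per raw window of `segment_raw_len` samples,
#' class composition given by `class_counts`, and per-class per-channel burst
#' gains in `activation_profile`. Each gesture burst is band-limited Gaussian
#' noise (passband `burst_band`) amplitude-modulated by a raised-cosine
#' window of `burst_duration` seconds centered in the raw window, on top of
#' white baseline noise of standard deviation `baseline_sd`.
#'
#' @param n_channels electrode count (default 8).
#' @param fs sampling rate in Hz (default 200).
#' @param segment_raw_len raw samples per gesture window (default 200).
#' @param class_counts integer vector, instances per class id 1..7
#'   (default [default_class_counts()]).
#' @param activation_profile class x channel gain matrix
#'   (default [default_activation_profile()]).
#' @param burst_duration activation burst length in seconds (default 1.0).
#' @param baseline_sd baseline noise SD in signal units (default 0.1).
#' @param burst_band carrier passband in Hz (default c(20, 95)); the upper
#'   edge must be below `fs / 2`.
#' @param seed integer RNG seed; identical configurations with identical
#'   seeds produce bit-identical recordings.
#' @return object of class `emg_synth_config`.
#' @export
synth_config <- function(n_channels = 8L,
                         fs = 200,
                         segment_raw_len = 200L,
                         class_counts = default_class_counts(),
                         activation_profile = default_activation_profile(n_channels),
                         burst_duration = 1.0,
                         baseline_sd = 0.1,
                         burst_band = c(20, 95),
                         seed = 1L) {
  cfg <- structure(list(
    n_channels = as.integer(n_channels), fs = fs,
    segment_raw_len = as.integer(segment_raw_len),
    class_counts = as.integer(class_counts),
    activation_profile = activation_profile,
    burst_duration = burst_duration, baseline_sd = baseline_sd,
    burst_band = as.numeric(burst_band), seed = as.integer(seed)),
    class = "emg_synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  if (cfg$n_channels < 1) stop_config("n_channels must be >= 1")
  if (cfg$fs <= 0) stop_config("fs must be positive")
  if (cfg$segment_raw_len < 2) stop_config("segment_raw_len must be >= 2")
  if (any(cfg$class_counts < 0) || anyNA(cfg$class_counts))
    stop_config("class_counts must be nonnegative integers")
  ap <- cfg$activation_profile
  if (!is.matrix(ap) || nrow(ap) != length(cfg$class_counts) ||
      ncol(ap) != cfg$n_channels)
    stop_config(sprintf(
      "activation_profile must be a %d x %d matrix (class x channel)",
      length(cfg$class_counts), cfg$n_channels))
  if (any(!is.finite(ap)) || any(ap < 0))
    stop_config("activation_profile entries must be finite and >= 0")
  if (length(cfg$burst_band) != 2 || cfg$burst_band[1] <= 0 ||
      cfg$burst_band[2] <= cfg$burst_band[1])
    stop_config("burst_band must be (low, high) with 0 < low < high")
  if (cfg$burst_band[2] >= cfg$fs / 2)
    stop_config(sprintf(
      "burst_band upper edge (%g Hz) must be below Nyquist (%g Hz)",
      cfg$burst_band[2], cfg$fs / 2))
  if (cfg$burst_duration <= 0) stop_config("burst_duration must be positive")
  if (cfg$baseline_sd < 0) stop_config("baseline_sd must be >= 0")
  invisible(cfg)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Generate a synthetic labeled sEMG recording
#'
#' Draws a seeded random ordering of the gesture class multiset given by
#' `class_counts`, lays the gesture windows on a regular grid separated by
#' small seeded jitter gaps of baseline noise, and synthesizes each channel
#' as `baseline + modulation * carrier`: white Gaussian baseline noise of SD
#' `baseline_sd`, a unit-variance band-limited Gaussian carrier (zero-phase
#' band-passed to `burst_band`), and a raised-cosine modulation envelope of
#' `burst_duration` seconds scaled by `activation_profile[class, channel]`
#' and centered on each event.
#'
#' @param cfg an [synth_config()] object.
#' @return object of class `emg_recording`: list with `signal` (channels x
#'   samples matrix), `fs`, and `events` (data.frame `class_id`,
#'   `center_index`, ordered by `center_index`). Every event admits a full
#'   `segment_raw_len` window; raw windows do not overlap.
#' @export
generate_recording <- function(cfg) {
  validate_synth_config(cfg)
  counts <- cfg$class_counts
  n_events <- sum(counts)
  if (n_events == 0)
    stop_config("class_counts sum to 0: refusing to generate an empty recording")

  rw <- cfg$segment_raw_len
  half <- rw %/% 2L
  burst_len <- max(1L, round(cfg$burst_duration * cfg$fs))

  with_seed(cfg$seed, {
    class_seq <- sample(rep.int(seq_along(counts), counts))
    gaps <- sample(10:40, n_events, replace = TRUE)
    starts <- cumsum(c(rw, head(rw + gaps, -1L)))  # margin of one raw window
    centers <- starts + half
    n_samples <- starts[n_events] + rw - 1L + rw   # trailing margin

    # modulation envelopes are shared across channels up to the class gain
    win <- hann_window(burst_len)
    woff <- seq_len(burst_len) - 1L - (burst_len %/% 2L)
    co <- butter_bandpass(4, cfg$burst_band[1], cfg$burst_band[2], cfg$fs)

    signal <- matrix(0, nrow = cfg$n_channels, ncol = n_samples)
    for (ch in seq_len(cfg$n_channels)) {
      baseline <- rnorm(n_samples, 0, cfg$baseline_sd)
      carrier <- filtfilt_zero_phase(co$b, co$a, rnorm(n_samples))
      carrier <- carrier / sd(carrier)
      modenv <- numeric(n_samples)
      gains <- cfg$activation_profile[class_seq, ch]
      for (e in seq_len(n_events)) {
        if (gains[e] == 0) next
        pos <- centers[e] + woff
        ok <- pos >= 1L & pos <= n_samples
        modenv[pos[ok]] <- modenv[pos[ok]] + gains[e] * win[ok]
      }
      signal[ch, ] <- baseline + modenv * carrier
    }

    structure(list(signal = signal, fs = cfg$fs,
                   events = data.frame(class_id = as.integer(class_seq),
                                       center_index = as.integer(centers))),
              class = "emg_recording")
  })
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$events)))
  tab <- table(factor(x$events$class_id, levels = 1:7))
  cat("  events per class:", paste(tab, collapse = " "), "\n")
  invisible(x)
}

#' Write / read a recording as delimited text
#'
#' `write_recording()` stores the signal as a CSV with header `ch1..chN`
#' (one row per sample), the events as a sidecar CSV `<stem>.events.csv`
#' with header `class_id,center_index`, and the sampling rate in a JSON
#' sidecar `<stem>.meta.json`. `read_recording()` reverses the operation and
#' validates the files, naming the offending line on malformed input.
#'
#' @param rec an `emg_recording`.
#' @param path path of the signal CSV; sidecar paths are derived from it.
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns an `emg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  sig <- data.table::as.data.table(t(rec$signal))
  data.table::setnames(sig, paste0("ch", seq_len(nrow(rec$signal))))
  data.table::fwrite(sig, path)
  data.table::fwrite(rec$events, recording_sidecar(path, "events.csv"))
  jsonlite::write_json(list(fs = rec$fs, n_channels = nrow(rec$signal)),
                       recording_sidecar(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

recording_sidecar <- function(path, ext) {
  sub("\\.csv$", paste0(".", ext), path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop_data(paste("no such recording file:", path))
  sig <- data.table::fread(path)
  if (ncol(sig) < 1 || !all(grepl("^ch[0-9]+$", names(sig))))
    stop_data(sprintf("%s line 1: header must be ch1..chN", path))
  if (!all(vapply(sig, is.numeric, logical(1)))) {
    bad <- which(!vapply(sig, is.numeric, logical(1)))[1]
    stop_data(sprintf("%s: column %s is not numeric", path, names(sig)[bad]))
  }
  meta_path <- recording_sidecar(path, "meta.json")
  fs <- if (file.exists(meta_path))
    as.numeric(jsonlite::read_json(meta_path)$fs) else 200
  ev_path <- recording_sidecar(path, "events.csv")
  if (!file.exists(ev_path)) stop_data(paste("missing events sidecar:", ev_path))
  ev <- data.table::fread(ev_path)
  if (!identical(names(ev), c("class_id", "center_index")))
    stop_data(sprintf("%s line 1: header must be class_id,center_index", ev_path))
  n <- nrow(sig)
  bad <- which(ev$center_index < 1 | ev$center_index > n)
  if (length(bad) > 0)
    stop_data(sprintf("%s line %d: center_index %d outside recording (1..%d)",
                      ev_path, bad[1] + 1L, ev$center_index[bad[1]], n))
  bad <- which(!ev$class_id %in% 1:7)
  if (length(bad) > 0)
    stop_data(sprintf("%s line %d: class_id %s is not in 1..7",
                      ev_path, bad[1] + 1L, ev$class_id[bad[1]]))
  structure(list(signal = t(as.matrix(sig)), fs = fs,
                 events = as.data.frame(ev)),
            class = "emg_recording")
}
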