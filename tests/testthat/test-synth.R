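test_that("generation is deterministic and reproduces the class composition", {
  cfg <- synth_config(class_counts = c(5L, 3L, 7L, 2L, 4L, 6L, 1L), seed = 7L)
  rec1 <- generate_recording(cfg)
  rec2 <- generate_recording(cfg)
  expect_identical(rec1$signal, rec2$signal)
  expect_identical(rec1$events, rec2$events)

  counts <- tabulate(rec1$events$class_id, nbins = 7)
  expect_identical(counts, c(5L, 3L, 7L, 2L, 4L, 6L, 1L))
  expect_identical(nrow(rec1$events), 28L)

  # events ordered, non-overlapping raw windows, full window inside recording
  centers <- rec1$events$center_index
  expect_true(all(diff(centers) >= cfg$segment_raw_len))
  expect_true(all(centers - cfg$segment_raw_len %/% 2 >= 1))
  expect_true(all(centers + cfg$segment_raw_len %/% 2 - 1 <= ncol(rec1$signal)))
})

test_that("zero activation gain leaves pure baseline noise", {
  zero_prof <- matrix(0, 7, 8)
  cfg0 <- synth_config(class_counts = rep(3L, 7), seed = 4L,
                       activation_profile = zero_prof, baseline_sd = 0)
  rec0 <- generate_recording(cfg0)
  expect_true(all(rec0$signal == 0))

  cfg <- synth_config(class_counts = rep(40L, 7), seed = 4L,
                      activation_profile = zero_prof, baseline_sd = 0.3)
  rec <- generate_recording(cfg)
  # event windows must look like baseline: compare per-window SD to baseline_sd
  half <- cfg$segment_raw_len %/% 2
  win_sd <- vapply(rec$events$center_index, function(cn)
    sd(rec$signal[1, (cn - half):(cn + half - 1)]), numeric(1))
  expect_lt(abs(mean(win_sd) - 0.3), 0.02)
})

test_that("burst spectrum concentrates inside the configured passband", {
  # long bursts, no baseline noise: periodogram power >= 90% inside the band
  cfg <- synth_config(class_counts = c(3L, rep(0L, 6)), seed = 2L,
                      baseline_sd = 0, burst_duration = 10,
                      segment_raw_len = 2048L,
                      activation_profile = matrix(1, 7, 8))
  rec <- generate_recording(cfg)
  half <- cfg$segment_raw_len %/% 2
  fracs <- vapply(rec$events$center_index, function(cn) {
    x <- rec$signal[1, (cn - half):(cn + half - 1)]
    p <- Mod(fft(x))^2
    n <- length(x)
    f <- (seq_len(n) - 1) * cfg$fs / n
    keep <- seq_len(n %/% 2)  # one-sided
    inband <- f[keep] >= cfg$burst_band[1] & f[keep] <= cfg$burst_band[2]
    sum(p[keep][inband]) / sum(p[keep])
  }, numeric(1))
  expect_true(all(fracs >= 0.9))
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(burst_band = c(20, 100)), class = "emgpipe_config_error")
  expect_error(generate_recording(synth_config(class_counts = rep(0L, 7))),
               class = "emgpipe_config_error")
  expect_error(synth_config(activation_profile = matrix(1, 3, 8)),
               class = "emgpipe_config_error")
  expect_error(synth_config(activation_profile = matrix(-1, 7, 8)),
               class = "emgpipe_config_error")
})

test_that("recordings round-trip through their text form", {
  # toy 2-channel recording written by hand
  rec <- structure(list(
    signal = matrix(sin(1:20 / 3), nrow = 2),
    fs = 200,
    events = data.frame(class_id = c(2L, 5L), center_index = c(4L, 8L))),
    class = "emg_recording")
  path <- file.path(tempdir(), "toy.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$signal, rec$signal, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(back$events$class_id, rec$events$class_id)
  expect_identical(back$events$center_index, rec$events$center_index)
  expect_identical(back$fs, 200)

  # a generated recording round-trips too
  rec2 <- tiny_recording(2L, seed = 9L)
  path2 <- file.path(tempdir(), "gen.csv")
  write_recording(rec2, path2)
  back2 <- read_recording(path2)
  expect_equal(back2$signal, rec2$signal, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("malformed recording files produce named format errors", {
  path <- file.path(tempdir(), "bad.csv")
  rec <- structure(list(signal = matrix(rnorm(2000), nrow = 2), fs = 200,
                        events = data.frame(class_id = 1L,
                                            center_index = 500L)),
                   class = "emg_recording")
  write_recording(rec, path)
  # event index far outside the file
  writeLines(c("class_id,center_index", "1,1000000000"),
             sub("\\.csv$", ".events.csv", path))
  err <- expect_error(read_recording(path), class = "emgpipe_data_error")
  expect_match(conditionMessage(err), "line 2")

  # empty events list is a valid recording with zero segments downstream
  writeLines("class_id,center_index", sub("\\.csv$", ".events.csv", path))
  empty <- read_recording(path)
  expect_identical(nrow(empty$events), 0L)
  expect_identical(segment_recording(empty), list())
})
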