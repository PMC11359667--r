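# Small synthetic fixtures shared across tests. All are generated in code;
# sizes are scaled well below the emulated acquisition to keep the suite
# fast, without changing any generator default other than the class counts.

tiny_recording <- function(per_class = 8L, seed = 11L, ...) {
  generate_recording(synth_config(class_counts = rep(per_class, 7L),
                                  seed = seed, ...))
}

tiny_features <- function(per_class = 8L, seed = 11L) {
  rec <- tiny_recording(per_class, seed)
  extract_features(segment_recording(rec))
}

# an activation profile whose rows are all identical: classes carry no
# channel information, so classifiers must fall to chance
flat_profile <- function(n_channels = 8L) {
  matrix(rep(c(1, 0.4, rep(0.1, n_channels - 3L), 0.4), each = 7L),
         nrow = 7L)
}

make_segment <- function(filtered, label = 1L, envelope_window = 5L) {
  if (!is.matrix(filtered)) filtered <- matrix(filtered, nrow = 1)
  rectified <- abs(filtered)
  env <- t(apply(rectified, 1, envelope_rms, window = envelope_window))
  if (nrow(filtered) == 1) env <- matrix(env, nrow = 1)
  structure(list(label = label, filtered = filtered, rectified = rectified,
                 envelope = env), class = "emg_segment")
}
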