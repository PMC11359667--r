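#' Write / read segments as delimited text
#'
#' Long CSV with one row per (segment, channel, track) and columns
#' `segment_id,label,channel,track,s1..sN`, where the track is one of
#' `filtered`, `rectified`, `envelope`.
#'
#' @param segments list of `emg_segment` objects.
#' @param path CSV path.
#' @return `write_segments()` returns `path` invisibly; `read_segments()`
#'   the reconstructed list of segments.
#' @export
write_segments <- function(segments, path) {
  if (length(segments) == 0) stop_data("no segments to write")
  tracks <- c("filtered", "rectified", "envelope")
  blocks <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    do.call(rbind, lapply(tracks, function(tr) {
      m <- seg[[tr]]
      data.table::data.table(segment_id = i, label = seg$label,
                             channel = seq_len(nrow(m)), track = tr, m)
    }))
  })
  dt <- data.table::rbindlist(blocks)
  data.table::setnames(dt, c("segment_id", "label", "channel", "track",
                             paste0("s", seq_len(ncol(dt) - 4L))))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop_data(paste("no such segments file:", path))
  dt <- data.table::fread(path)
  need <- c("segment_id", "label", "channel", "track")
  if (!all(need %in% names(dt)))
    stop_data(sprintf("%s line 1: header must start with %s",
                      path, paste(need, collapse = ",")))
  svals <- as.matrix(dt[, -seq_along(need), with = FALSE])
  segs <- lapply(split(seq_len(nrow(dt)), dt$segment_id), function(rows) {
    sub <- dt[rows]
    grab <- function(tr) {
      ri <- rows[sub$track == tr][order(sub$channel[sub$track == tr])]
      if (length(ri) == 0) stop_data(sprintf(
        "%s: segment %d is missing its %s track", path, sub$segment_id[1], tr))
      svals[ri, , drop = FALSE]
    }
    structure(list(label = sub$label[1], filtered = grab("filtered"),
                   rectified = grab("rectified"), envelope = grab("envelope")),
              class = "emg_segment")
  })
  unname(segs)
}

#' Write / read a feature matrix as delimited text
#'
#' CSV with header `segment_id,label,ch1_min,...`.
#'
#' @param fm an `emg_feature_matrix`.
#' @param path CSV path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   an `emg_feature_matrix`.
#' @export
write_features <- function(fm, path) {
  stopifnot(inherits(fm, "emg_feature_matrix"))
  dt <- data.table::data.table(segment_id = seq_len(nrow(fm$values)),
                               label = fm$labels, fm$values)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop_data(paste("no such feature file:", path))
  dt <- data.table::fread(path)
  if (!all(c("segment_id", "label") %in% names(dt)))
    stop_data(sprintf("%s line 1: header must start with segment_id,label",
                      path))
  vals <- as.matrix(dt[, setdiff(names(dt), c("segment_id", "label")),
                       with = FALSE])
  structure(list(values = vals, labels = as.integer(dt$label)),
            class = "emg_feature_matrix")
}

#' Write an engineered dataset and its fitted parameters
#'
#' Writes the projected rows as CSV `segment_id,label,pc1..pck` and the
#' fitted transform (per-column means and SDs, retained basis vectors,
#' explained-variance ratios) as JSON alongside.
#'
#' @param eng result of [engineer_features()].
#' @param path CSV path; the params file is `<stem>.params.json`.
#' @return `path`, invisibly.
#' @export
write_engineered <- function(eng, path) {
  fit <- eng$pca
  proj <- fit$projected
  dt <- data.table::data.table(segment_id = seq_len(nrow(proj)),
                               label = fit$labels %||% NA_integer_, proj)
  data.table::setnames(dt, c("segment_id", "label",
                             paste0("pc", seq_len(ncol(proj)))))
  data.table::fwrite(dt, path)
  jsonlite::write_json(list(
    mean = unname(eng$zscore$center), sd = unname(eng$zscore$scale),
    pca_center = unname(fit$center),
    basis = unname(as.data.frame(fit$rotation[, seq_len(fit$k), drop = FALSE])),
    explained_ratio = fit$explained_ratio, k = fit$k,
    cumulative_variance = fit$cumulative_variance),
    sub("\\.csv$", ".params.json", path), digits = NA, auto_unbox = TRUE)
  invisible(path)
}
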