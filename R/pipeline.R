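#' Encode a list of beats as an image stack
#'
#' Applies [encode_beat()] to every beat and stacks the resulting pixel
#' images into an (side, side, N) array scaled to [0, 1] (pixel value /
#' 255), ready for [fit_model()] / [train_and_evaluate()].
#'
#' @param beats List of `bcg_beat` objects (or numeric vectors).
#' @param config An [imaging_config()].
#' @return Numeric array (side, side, N).
#' @export
encode_beats <- function(beats, config) {
  imgs <- lapply(beats, encode_beat, config = config)
  side <- nrow(imgs[[1]]$pixels)
  arr <- array(0, dim = c(side, side, length(imgs)))
  for (i in seq_along(imgs)) arr[, , i] <- imgs[[i]]$pixels / 255
  arr
}

#' Stack the BCG channels of beats into a series matrix
#'
#' Returns the N x L matrix consumed by the 1-D FCN baseline, optionally
#' PAA-shortened. Each row is min-max rescaled to [-1, 1] so the 1-D and
#' 2-D inputs share a comparable scale.
#'
#' @param beats List of `bcg_beat` objects.
#' @param paa_output_len Optional PAA target length.
#' @return Numeric matrix, one row per beat.
#' @export
beats_to_series <- function(beats, paa_output_len = NULL) {
  rows <- lapply(beats, function(b) {
    x <- if (inherits(b, "bcg_beat")) b$channels$bcg else as.numeric(b)
    if (!is.null(paa_output_len)) x <- paa(x, paa_output_len)
    minmax_rescale(x)
  })
  do.call(rbind, rows)
}

#' Write beats to delimited text with a JSON annotation sidecar
#'
#' Long-format CSV with columns `beat_id`, `t_ms`, `ecg`, `ppg`, `bcg`
#' (one row per sample), plus `<path>.json` holding the sampling rate and
#' per-beat annotations/labels. [read_beats_csv()] inverts the pair.
#'
#' @param beats List of `bcg_beat` objects.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @return Invisibly, `path`.
#' @export
write_beats_csv <- function(beats, path) {
  tab <- do.call(rbind, lapply(beats, function(b) {
    n <- length(b$channels$ecg)
    data.frame(beat_id = b$beat_id, t_ms = seq_len(n) - 1,
               ecg = b$channels$ecg, ppg = b$channels$ppg,
               bcg = b$channels$bcg)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(
    fs_hz = beats[[1]]$fs_hz,
    beats = lapply(beats, function(b) {
      list(beat_id = b$beat_id, r_index = b$r_index,
           ppg_foot_idx = b$ppg_foot_idx,
           ground_truth_label = b$ground_truth_label,
           annotations = b$annotations)
    }))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  tab <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  ids <- unique(tab$beat_id)
  beats <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sub <- tab[tab$beat_id == ids[k], ]
    mb <- meta$beats[[k]]
    beats[[k]] <- structure(
      list(beat_id = as.integer(ids[k]), fs_hz = as.numeric(meta$fs_hz),
           channels = list(ecg = sub$ecg, ppg = sub$ppg, bcg = sub$bcg),
           r_index = if (is.null(mb$r_index)) NA_integer_ else
             as.integer(mb$r_index),
           ppg_foot_idx = if (is.null(mb$ppg_foot_idx)) NA_integer_ else
             as.integer(mb$ppg_foot_idx),
           annotations = mb$annotations,
           ground_truth_label = mb$ground_truth_label,
           params = NULL),
      class = "bcg_beat")
  }
  beats
}

#' Write / read a three-channel recording as CSV
#'
#' Plain CSV with columns `ecg`, `ppg`, `bcg` and a JSON sidecar carrying
#' the sampling rate.
#'
#' @param rec A [recording()].
#' @param path CSV path; sidecar at `<path>.json`.
#' @return Invisibly `path` (write) or a `bcg_recording` (read).
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "bcg_recording"))
  utils::write.csv(data.frame(ecg = rec$ecg, ppg = rec$ppg, bcg = rec$bcg),
                   path, row.names = FALSE)
  jsonlite::write_json(list(fs_hz = rec$fs_hz), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  tab <- utils::read.csv(path)
  side <- paste0(path, ".json")
  fs <- if (file.exists(side)) jsonlite::read_json(side)$fs_hz else 1000
  recording(tab$ecg, tab$ppg, tab$bcg, fs_hz = as.numeric(fs))
}

#' Write a beat image as an 8-bit grayscale PNG
#'
#' @param img A `bcg_beat_image`.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_beat_image_png <- function(img, path) {
  stopifnot(inherits(img, "bcg_beat_image"))
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("write_beat_image_png() needs the 'png' package")
  }
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}
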