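# CSV / JSON interchange helpers

#' Write an analysis result as JSON
#'
#' @param x list-like result (cluster summaries, decoding summaries,
#'   configs).  Matrices are written as arrays.
#' @param path output path.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Write a gaze block as plain-text tables
#'
#' Writes `<stem>.csv` (time_s, x, y, pupil_mm, valid) plus
#' `<stem>_fixations.csv` and `<stem>_blinks.csv` event tables.
#'
#' @param block a `gaze_block`.
#' @param stem output path without extension.
#' @export
write_gaze_csv <- function(block, stem) {
  write.csv(data.frame(time_s = block$time, x = block$x, y = block$y,
                       pupil_mm = block$pupil_mm,
                       valid = as.integer(block$valid)),
            paste0(stem, ".csv"), row.names = FALSE)
  write.csv(block$fixations, paste0(stem, "_fixations.csv"),
            row.names = FALSE)
  write.csv(block$blinks, paste0(stem, "_blinks.csv"), row.names = FALSE)
  invisible(stem)
}

#' Read a gaze block written by [write_gaze_csv()]
#'
#' @param stem path stem used when writing.
#' @param fs sampling rate (Hz); inferred from the time column when
#'   omitted.
#' @return a `gaze_block`.
#' @export
read_gaze_csv <- function(stem, fs = NULL) {
  d <- read.csv(paste0(stem, ".csv"))
  if (is.null(fs)) fs <- 1 / median(diff(d$time_s))
  structure(list(time = d$time_s, x = d$x, y = d$y, pupil_mm = d$pupil_mm,
                 valid = d$valid > 0, fs = fs,
                 duration_s = length(d$time_s) / fs,
                 fixations = read.csv(paste0(stem, "_fixations.csv")),
                 blinks = read.csv(paste0(stem, "_blinks.csv"))),
            class = "gaze_block")
}

#' Write a telemetry block as plain-text tables
#'
#' @param block a `telemetry_block`.
#' @param stem output path without extension.
#' @export
write_telemetry_csv <- function(block, stem) {
  write.csv(data.frame(time_s = block$time, accel = block$accel,
                       steer = block$steer, brake = block$brake,
                       lane_pos = block$lane_pos),
            paste0(stem, ".csv"), row.names = FALSE)
  write.csv(data.frame(time_s = block$lane_changes),
            paste0(stem, "_lane_changes.csv"), row.names = FALSE)
  write.csv(block$violations, paste0(stem, "_violations.csv"),
            row.names = FALSE)
  invisible(stem)
}

#' Export a spectrum set as a tidy CSV table
#'
#' Long format with columns `series_id`, `frequency_hz`, `power`.
#'
#' @param spectra a `spectrum_set`.
#' @param path CSV output path.
#' @export
write_spectra_csv <- function(spectra, path) {
  n_s <- nrow(spectra$power)
  df <- data.frame(
    series_id = rep(seq_len(n_s), times = length(spectra$freqs)),
    frequency_hz = rep(spectra$freqs, each = n_s),
    power = as.numeric(spectra$power))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a cluster result as a tidy vertex table
#'
#' @param result a `cluster_result`.
#' @param path CSV output path.
#' @export
write_cluster_csv <- function(result, path) {
  rows <- do.call(rbind, lapply(seq_along(result$clusters), function(i) {
    cl <- result$clusters[[i]]
    data.frame(cluster = i, vertex = cl$vertices, mass = cl$mass, p = cl$p)
  }))
  if (is.null(rows))
    rows <- data.frame(cluster = integer(0), vertex = integer(0),
                       mass = numeric(0), p = numeric(0))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
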