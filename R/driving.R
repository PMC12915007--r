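#' Root mean square of successive differences
#'
#' @param x numeric series (length >= 2).
#' @return `sqrt(mean(diff(x)^2))`.
#' @export
rmssd <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  sqrt(mean(diff(x)^2))
}

#' Mean absolute lane deviation with lane-change exclusion
#'
#' Mean of `|lane_pos|` over samples outside the union of
#' `[t - exclusion_s, t + exclusion_s]` windows around each lane change.
#'
#' @param lane_pos lane position (m from centre), uniformly sampled.
#' @param fs sampling rate (Hz).
#' @param lane_change_times lane-change event times (s).
#' @param exclusion_s half-width of the excluded window (s).
#' @return mean absolute deviation (m).
#' @export
lane_deviation <- function(lane_pos, fs, lane_change_times = numeric(0),
                           exclusion_s = 2) {
  if (exclusion_s < 0) stop("`exclusion_s` must be >= 0")
  t <- (seq_along(lane_pos) - 1) / fs
  keep <- rep(TRUE, length(t))
  for (tc in lane_change_times)
    keep <- keep & !(t >= tc - exclusion_s & t <= tc + exclusion_s)
  if (!any(keep)) stop("all samples fall inside lane-change exclusion windows")
  mean(abs(lane_pos[keep]))
}

#' Count traffic-rule violations
#'
#' @param events data.frame with a `type` column; rows with type
#'   `"radar"` or `"collision"` are counted, others ignored.
#' @return integer count.
#' @export
count_violations <- function(events) {
  if (nrow(events) == 0) return(0L)
  sum(events$type %in% c("radar", "collision"))
}

#' Driving measures of one telemetry block
#'
#' @param block a `telemetry_block`.
#' @return named list: `accel_rmssd`, `steer_rmssd`, `brake_mean`,
#'   `lane_dev_mean`, `violations`.
#' @export
driving_measures <- function(block) {
  list(accel_rmssd = rmssd(block$accel),
       steer_rmssd = rmssd(block$steer),
       brake_mean = mean(block$brake),
       lane_dev_mean = lane_deviation(block$lane_pos, block$fs,
                                      block$lane_changes),
       violations = count_violations(block$violations))
}

#' Composite driving-performance score
#'
#' Each measure (all oriented so that larger = worse) is min-max
#' normalized across the blocks of one subject, the normalized measures
#' averaged, the aggregate inverted (1 - x) so higher = better, and the
#' result min-max rescaled once more to `[0, 1]`.  A measure constant
#' across blocks contributes 0 for every block (flagged).
#'
#' @param measures_by_block blocks x measures numeric matrix or data.frame
#'   (>= 2 blocks).
#' @return per-block score in `[0, 1]`.
#' @export
composite_score <- function(measures_by_block) {
  m <- as.matrix(measures_by_block)
  if (nrow(m) < 2) stop("need at least 2 blocks for min-max normalization")
  norm <- apply(m, 2, function(col) {
    rng <- range(col)
    if (diff(rng) == 0) {
      flag_note("constant measure across blocks; contributes 0")
      rep(0, length(col))
    } else (col - rng[1]) / diff(rng)
  })
  agg <- 1 - rowMeans(norm)
  rng <- range(agg)
  if (diff(rng) == 0) return(rep(0.5, nrow(m)))
  (agg - rng[1]) / diff(rng)
}
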