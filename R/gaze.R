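# ---- pupil series container ----------------------------------------------

#' Construct a pupil diameter series
#'
#' @param diameter pupil diameter (mm); gaps as `NaN`/`NA`.
#' @param fs sampling rate (Hz).
#' @param valid optional validity mask; defaults to finite samples.
#' @return object of class `pupil_series`.
#' @export
pupil_series <- function(diameter, fs, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(diameter)
  structure(list(diameter = as.numeric(diameter), fs = fs,
                 valid = valid & is.finite(diameter)),
            class = "pupil_series")
}

#' Extract the pupil series of a gaze block
#' @param block a `gaze_block`.
#' @return a `pupil_series`.
#' @export
as_pupil_series <- function(block) {
  pupil_series(block$pupil_mm, block$fs)
}

# runs of FALSE in a logical vector -> matrix of (start, end)
invalid_runs <- function(valid) {
  r <- rle(!valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Interpolate blink gaps with a padded cubic spline
#'
#' Each invalid run is extended by `pad_ms` on both sides and refilled by
#' a cubic spline through the flanking valid samples.  Gaps longer than
#' `max_gap_ms` are left masked (excluded from downstream statistics);
#' gaps touching the series boundary are filled with the nearest valid
#' value and flagged.
#'
#' @param series a `pupil_series`.
#' @param pad_ms padding around each gap (ms).
#' @param max_gap_ms maximum tolerated gap length (ms).
#' @param n_flank number of valid samples used on each side of a gap.
#' @return interpolated `pupil_series`.
#' @export
interpolate_gaps <- function(series, pad_ms = 50, max_gap_ms = 500,
                             n_flank = 10) {
  x <- series$diameter
  valid <- series$valid
  n <- length(x)
  pad <- round(pad_ms / 1000 * series$fs)
  runs <- invalid_runs(valid)
  if (!nrow(runs)) return(series)
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, "start"]; b <- runs[k, "end"]
    gap_ms <- (b - a + 1) / series$fs * 1000
    if (gap_ms > max_gap_ms) next
    a2 <- max(1L, a - pad); b2 <- min(n, b + pad)
    left <- which(valid[seq_len(max(a2 - 1L, 0L))])
    right_all <- which(valid); right <- right_all[right_all > b2]
    if (!length(left) || !length(right)) {
      # boundary gap: nearest-valid fill
      src <- if (length(right)) right[1] else tail(left, 1)
      if (length(src)) {
        x[a2:b2] <- x[src]; valid[a2:b2] <- TRUE
        flag_note("boundary gap filled with nearest valid value")
      }
      next
    }
    anchors <- c(tail(left, n_flank), head(right, n_flank))
    sf <- splinefun(anchors, x[anchors], method = "natural")
    fill <- a2:b2
    x[fill] <- sf(fill)
    valid[fill] <- TRUE
  }
  pupil_series(x, series$fs, valid)
}

#' Rolling median filter
#'
#' Centred rolling median applied independently within each contiguous
#' valid segment; edges use shrunken windows.
#'
#' @param series a `pupil_series`.
#' @param window_ms window length (ms).
#' @return filtered `pupil_series`.
#' @export
median_roll <- function(series, window_ms = 20) {
  x <- series$diameter
  k <- max(1L, round(window_ms / 1000 * series$fs))
  if (k %% 2 == 0) k <- k + 1L
  runs <- invalid_runs(!series$valid)          # runs of VALID samples
  for (j in seq_len(nrow(runs))) {
    idx <- runs[j, "start"]:runs[j, "end"]
    kk <- min(k, if (length(idx) %% 2 == 0) length(idx) - 1L else length(idx))
    if (kk >= 3)
      x[idx] <- runmed(x[idx], kk, endrule = "median")
  }
  pupil_series(x, series$fs, series$valid)
}

#' Mask physiologically implausible pupil samples
#'
#' Samples outside `[lo, hi]` mm are masked (not clamped).
#'
#' @param series a `pupil_series`.
#' @param lo,hi physiological bounds (mm).
#' @return masked `pupil_series`.
#' @export
clip_physiological <- function(series, lo = 1, hi = 9) {
  x <- series$diameter
  bad <- series$valid & (x < lo | x > hi)
  x[bad] <- NaN
  pupil_series(x, series$fs, series$valid & !bad)
}

#' Standard pupil preprocessing chain
#'
#' Gap interpolation, rolling-median filtering, then physiological
#' masking, in that fixed order.
#'
#' @param series a `pupil_series` (or `gaze_block`).
#' @inheritParams interpolate_gaps
#' @inheritParams median_roll
#' @inheritParams clip_physiological
#' @return preprocessed `pupil_series`.
#' @export
preprocess_pupil <- function(series, pad_ms = 50, max_gap_ms = 500,
                             window_ms = 20, lo = 1, hi = 9) {
  if (inherits(series, "gaze_block")) series <- as_pupil_series(series)
  s <- interpolate_gaps(series, pad_ms, max_gap_ms)
  s <- median_roll(s, window_ms)
  clip_physiological(s, lo, hi)
}

#' Median pupil diameter during fixations
#'
#' @param series a `pupil_series`.
#' @param fixations data.frame with `onset_s` and `offset_s`.
#' @return median diameter (mm) over valid samples inside fixations.
#' @export
median_pupil_fixations <- function(series, fixations) {
  t <- (seq_along(series$diameter) - 1) / series$fs
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(fixations)))
    inside <- inside | (t >= fixations$onset_s[i] &
                          t <= fixations$offset_s[i])
  use <- inside & series$valid
  if (!any(use)) stop("no valid samples inside fixations")
  median(series$diameter[use])
}

# ---- Index of Pupillary Activity -----------------------------------------

# Symlet-16 decomposition filter bank (standard published coefficients)
sym16_dec_lo <- c(
  6.230006701220761e-06, -3.113556407621969e-06, -1.0943147929529757e-04,
  2.8078582128442894e-05, 8.523547108047095e-04, -1.084456223089688e-04,
  -3.8809122526038786e-03, 7.182119788317892e-04, 1.2666731659857348e-02,
  -3.1265171722710075e-03, -3.1051202843553064e-02, 4.869274404904607e-03,
  3.2333091610663785e-02, -6.698304907021778e-02, -3.4574228416972504e-02,
  3.9712293362064416e-01, 7.565249878756971e-01, 4.7534280601152273e-01,
  -5.4040601387606135e-02, -1.5959219218520598e-01, 3.072113906330156e-02,
  7.803785290341991e-02, -3.510275068374009e-03, -2.4952758046290123e-02,
  1.359844742484172e-03, 6.9377611308027096e-03, -2.2211647621176323e-04,
  -1.3387206066921965e-03, 3.656592483348223e-05, 1.6545679579108483e-04,
  -5.396483179315242e-06, -1.0797982104319795e-05)
sym16_dec_hi <- rev(sym16_dec_lo) * rep_len(c(-1, 1), 32)

# one DWT analysis step with symmetric extension; returns the
# downsampled filtered series
dwt_step <- function(x, filt) {
  l <- length(filt)
  ext <- c(rev(x[seq_len(min(l - 1, length(x)))]),
           x,
           rev(x)[seq_len(min(l - 1, length(x)))])
  y <- stats::convolve(ext, rev(filt), type = "open")
  # central part aligned with the original samples
  y <- y[(l - 1 + 1):(l - 1 + length(x) + l - 1)]
  y[seq(2, length(y), by = 2)]
}

# IPA of one gap-free segment: count of thresholded modulus maxima of the
# level-2 Symlet-16 detail coefficients.  Coefficients inside the filter
# support at the segment boundaries are excluded (symmetric-extension
# kinks), and the universal threshold is floored at numerical-leakage
# scale so that noiseless smooth signals yield zero events.
ipa_segment_count <- function(x) {
  a1 <- dwt_step(x, sym16_dec_lo)
  d2 <- dwt_step(a1, sym16_dec_hi)
  n <- length(d2)
  trim <- length(sym16_dec_lo) / 2
  if (n < 2 * trim + 3) return(0L)
  m <- abs(d2)
  sigma <- mad(d2, constant = 1) / 0.6745
  lambda <- max(sigma * sqrt(2 * log(n)), 1e-8 * diff(range(x)))
  core <- (trim + 1):(n - trim)
  is_max <- m[core] >= m[core - 1] & m[core] > m[core + 1]
  sum(is_max & m[core] > lambda)
}

#' Index of Pupillary Activity
#'
#' Counts abrupt discontinuities in the pupil diameter signal as
#' thresholded modulus maxima of the level-2 Symlet-16 wavelet detail
#' coefficients (hard universal threshold
#' \eqn{\lambda = \hat\sigma \sqrt{2 \ln n}} with the MAD noise estimate),
#' expressed in events per second.  Segments separated by masked runs are
#' processed independently and their counts summed; the rate denominator
#' is the total valid duration.
#'
#' @param series a `pupil_series` (preprocessed; remaining masked runs
#'   split the computation).
#' @param min_segment_s shortest segment processed (s).
#' @return events per second.
#' @export
ipa <- function(series, min_segment_s = 1) {
  fs <- series$fs
  runs <- invalid_runs(!series$valid)          # valid runs
  if (!nrow(runs)) stop("no valid samples")
  min_len <- max(round(min_segment_s * fs), 4L * length(sym16_dec_lo))
  count <- 0L; dur <- 0
  for (j in seq_len(nrow(runs))) {
    idx <- runs[j, "start"]:runs[j, "end"]
    if (length(idx) < min_len) next
    count <- count + ipa_segment_count(series$diameter[idx])
    dur <- dur + length(idx) / fs
  }
  if (dur == 0) stop("series shorter than the wavelet filter support")
  count / dur
}

# ---- fixation / blink measures -------------------------------------------

#' Duration-weighted RMS gaze dispersion
#'
#' Centroid = duration-weighted mean fixation position; dispersion =
#' square root of the duration-weighted mean squared distance of
#' fixations from the centroid.
#'
#' @param fixations data.frame with `x`, `y`, `duration_s`.
#' @return RMS dispersion (screen units); a single fixation yields 0 with
#'   a flag.
#' @export
gaze_dispersion <- function(fixations) {
  if (nrow(fixations) == 0) stop("no fixations")
  if (nrow(fixations) == 1) {
    flag_note("single fixation: dispersion is 0 by definition")
    return(0)
  }
  d <- fixations$duration_s
  if (any(d <= 0)) stop("fixation durations must be positive")
  cx <- sum(d * fixations$x) / sum(d)
  cy <- sum(d * fixations$y) / sum(d)
  sqrt(sum(d * ((fixations$x - cx)^2 + (fixations$y - cy)^2)) / sum(d))
}

#' Blink rate
#'
#' @param blink_events data.frame of blink events (one row each), or an
#'   integer count.
#' @param duration_s block duration (s), > 0.
#' @return blinks per second.
#' @export
blink_rate <- function(blink_events, duration_s) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  n <- if (is.data.frame(blink_events)) nrow(blink_events)
       else as.numeric(blink_events)
  n / duration_s
}

#' Baseline correction
#'
#' Subtracts the baseline-block value from the experimental-block value.
#'
#' @param value,baseline_value finite numbers.
#' @return `value - baseline_value`.
#' @export
baseline_correct <- function(value, baseline_value) {
  if (!all(is.finite(value)) || !all(is.finite(baseline_value)))
    stop("values must be finite")
  value - baseline_value
}

#' All four gaze measures of one block
#'
#' Runs the preprocessing chain and returns gaze dispersion, blink rate,
#' median pupil diameter during fixations, and the IPA.
#'
#' @param block a `gaze_block`.
#' @return named list of the four measures.
#' @export
gaze_metrics <- function(block) {
  s <- preprocess_pupil(block)
  list(dispersion = gaze_dispersion(block$fixations),
       blink_rate = blink_rate(block$blinks, block$duration_s),
       pupil_median = median_pupil_fixations(s, block$fixations),
       ipa = ipa(s))
}
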