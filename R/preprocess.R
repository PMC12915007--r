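#' Construct an epoch set
#'
#' @param data numeric array, epochs x channels x samples.
#' @param fs sampling rate (Hz).
#' @param onsets epoch onset times (s), strictly increasing.
#' @param condition optional condition label (recycled per epoch).
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, onsets = NULL, condition = NA_character_) {
  stopifnot(length(dim(data)) == 3L)
  n_ep <- dim(data)[1]
  if (is.null(onsets)) onsets <- seq_len(n_ep) - 1
  if (n_ep > 1 && any(diff(onsets) <= 0))
    stop("epoch onsets must be strictly increasing")
  structure(list(data = data, fs = fs, onsets = as.numeric(onsets),
                 condition = rep_len(condition, max(n_ep, 1L))[seq_len(n_ep)]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

n_epochs <- function(es) dim(es$data)[1]

subset_epochs <- function(es, idx) {
  epoch_set(es$data[idx, , , drop = FALSE], es$fs, es$onsets[idx],
            es$condition[idx])
}

#' Segment a continuous block into fixed-length epochs
#'
#' Windows start at 0 and advance by `length_s - overlap_s`; a trailing
#' partial window is discarded.  A block shorter than one epoch yields an
#' empty set with a warning.
#'
#' @param block channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param length_s epoch length (s), > 0.
#' @param overlap_s overlap between consecutive epochs (s), >= 0 and
#'   < `length_s`.
#' @param condition optional condition label attached to every epoch.
#' @return an `epoch_set`.
#' @export
segment_epochs <- function(block, fs, length_s, overlap_s = 0,
                           condition = NA_character_) {
  stopifnot(is.matrix(block))
  stopifnot_scalar(length_s, "length_s", lo = 1e-12)
  if (overlap_s < 0 || overlap_s >= length_s)
    stop("`overlap_s` must be in [0, length_s)")
  n <- ncol(block)
  len <- round(length_s * fs)
  step <- round((length_s - overlap_s) * fs)
  if (n < len) {
    warning("block shorter than one epoch; returning empty set")
    return(epoch_set(array(0, c(0, nrow(block), len)), fs, numeric(0)))
  }
  starts <- seq(1L, n - len + 1L, by = step)
  data <- array(0, c(length(starts), nrow(block), len))
  for (i in seq_along(starts))
    data[i, , ] <- block[, starts[i]:(starts[i] + len - 1L)]
  epoch_set(data, fs, onsets = (starts - 1L) / fs, condition = condition)
}

#' Reject epochs exceeding an amplitude threshold
#'
#' An epoch is dropped when its rejection statistic (absolute maximum by
#' default, peak-to-peak optionally) exceeds the threshold on any channel
#' of a group.  Channel groups with per-group thresholds mirror mixed
#' sensor types (e.g. magnetometers vs gradiometers); the default is a
#' single group.
#'
#' @param epochs an `epoch_set`.
#' @param threshold positive threshold, one value per channel group.
#' @param stat `"absmax"` or `"ptp"`.
#' @param groups optional integer vector (length = channels) assigning each
#'   channel to a group `1..length(threshold)`.
#' @return list with `epochs` (retained) and `rejected` (logical mask over
#'   the input epochs, `TRUE` = dropped).
#' @export
reject_amplitude <- function(epochs, threshold, stat = c("absmax", "ptp"),
                             groups = NULL) {
  stat <- match.arg(stat)
  if (any(threshold <= 0)) stop("`threshold` must be positive")
  d <- dim(epochs$data)
  if (is.null(groups)) groups <- rep(1L, d[2])
  if (length(threshold) == 1L) threshold <- rep(threshold, max(groups))
  rejected <- logical(d[1])
  for (i in seq_len(d[1])) {
    ep <- epochs$data[i, , , drop = TRUE]
    if (is.null(dim(ep))) ep <- matrix(ep, nrow = d[2])
    s <- if (stat == "absmax") apply(abs(ep), 1, max)
         else apply(ep, 1, function(v) diff(range(v)))
    rejected[i] <- any(s > threshold[groups])
  }
  if (all(rejected))
    stop("all epochs rejected by amplitude threshold",
         if (!is.na(epochs$condition[1]))
           sprintf(" in block '%s'", epochs$condition[1]) else "")
  list(epochs = subset_epochs(epochs, !rejected), rejected = rejected)
}

# summed pairwise absolute difference of matched-rank onsets across
# conditions, over the first `m` ranks of each sorted onset list
onset_match_cost <- function(onset_list, m) {
  srt <- lapply(onset_list, function(o) sort(o)[seq_len(m)])
  total <- 0
  k <- length(srt)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    total <- total + sum(abs(srt[[i]] - srt[[j]]))
  total
}

#' Equalize epoch counts across conditions
#'
#' Greedily drops surplus epochs: at each step the removal that most
#' reduces the summed pairwise difference of matched-rank onset times
#' across conditions is applied (ties broken by dropping the later-onset
#' epoch), until every condition holds exactly the minimum count.
#'
#' @param epoch_sets named list of `epoch_set`, one per condition, each
#'   non-empty.
#' @return list of `epoch_set` with equal counts.
#' @export
equalize_counts <- function(epoch_sets) {
  if (length(epoch_sets) < 2L) stop("need at least two conditions")
  counts <- vapply(epoch_sets, n_epochs, 1L)
  if (any(counts == 0L)) stop("every condition must be non-empty")
  m <- min(counts)
  keep <- lapply(epoch_sets, function(es) seq_len(n_epochs(es)))
  repeat {
    counts <- vapply(keep, length, 1L)
    if (all(counts == m)) break
    best <- NULL; best_cost <- Inf; best_onset <- -Inf
    for (ci in which(counts > m)) {
      ons <- epoch_sets[[ci]]$onsets
      for (drop_i in keep[[ci]]) {
        trial <- keep
        trial[[ci]] <- setdiff(trial[[ci]], drop_i)
        onsets <- Map(function(es, k) es$onsets[k], epoch_sets, trial)
        cost <- onset_match_cost(onsets, m)
        o <- ons[drop_i]
        if (cost < best_cost - 1e-12 ||
            (abs(cost - best_cost) <= 1e-12 && o > best_onset)) {
          best_cost <- cost; best <- list(ci, drop_i); best_onset <- o
        }
      }
    }
    keep[[best[[1]]]] <- setdiff(keep[[best[[1]]]], best[[2]])
  }
  out <- Map(subset_epochs, epoch_sets, keep)
  names(out) <- names(epoch_sets)
  out
}

#' Zero-phase band-pass FIR filter
#'
#' Linear-phase windowed (Hamming) FIR design, applied by zero-padded
#' forward convolution with exact group-delay compensation.  The design
#' order targets a transition band of `trans_hz` and a stop-band
#' attenuation of at least 40 dB.
#'
#' @param block channels x samples matrix (a vector is treated as one
#'   channel).
#' @param fs sampling rate (Hz).
#' @param lo_hz,hi_hz band edges, `0 < lo < hi < fs/2`.
#' @param trans_hz transition bandwidth (Hz).
#' @return filtered block, same shape as the input.
#' @export
bandpass_fir <- function(block, fs, lo_hz, hi_hz, trans_hz = 2) {
  vec <- is.null(dim(block))
  if (vec) block <- matrix(block, nrow = 1)
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs / 2))
    stop("need 0 < lo_hz < hi_hz < fs/2")
  n_tap <- ceiling(3.3 * fs / trans_hz)
  if (n_tap %% 2 == 0) n_tap <- n_tap + 1L      # odd length, type-I linear phase
  b <- signal::fir1(n_tap - 1L, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  delay <- (n_tap - 1L) / 2L
  n <- ncol(block)
  out <- t(apply(block, 1, function(x) {
    # full convolution with implicit zero padding; y[t] = sum_j b[j] x[t-j+1]
    y <- stats::convolve(x, rev(b), type = "open")
    y[(delay + 1L):(delay + n)]        # compensate the linear-phase delay
  }))
  if (vec) out[1, ] else out
}
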