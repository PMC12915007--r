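#' DICS spatial filters for a band cross-spectrum
#'
#' Per vertex \eqn{v}: \eqn{w_v = (l_v' S_r^{-1} l_v)^{-1} l_v' S_r^{-1}}
#' with \eqn{S_r = Re(CSD) + reg \cdot mean(diag) \cdot I}, all quantities
#' in pre-whitened sensor space.  Filters satisfy the unit-gain property
#' `w_v l_v = 1` exactly.
#'
#' @param csd complex sensors x sensors band CSD (unwhitened sensor space).
#' @param gain sensors x sources lead field (unwhitened).
#' @param whitener optional `whitener`; `NULL` for identity.
#' @param reg_fraction diagonal-loading fraction of the mean CSD diagonal.
#' @return object of class `dics_filters`: `w` (sources x rank matrix),
#'   `whitener`, `reg_fraction`.
#' @export
dics_filters <- function(csd, gain, whitener = NULL, reg_fraction = 0.05) {
  if (is.null(whitener))
    whitener <- structure(list(w = diag(nrow(csd)), rank = nrow(csd)),
                          class = "whitener")
  wm <- whitener$w
  s <- Re(wm %*% csd %*% t(wm))
  l <- wm %*% gain
  sr <- s + reg_fraction * mean(diag(s)) * diag(nrow(s))
  sinv <- tryCatch(solve(sr), error = function(e)
    stop("regularized CSD is singular; increase `reg_fraction`"))
  a <- sinv %*% l                       # rank x sources
  denom <- colSums(l * a)               # l_v' S^-1 l_v
  if (any(abs(denom) < 1e-300)) stop("degenerate lead-field column")
  w <- t(a) / denom                     # sources x rank
  structure(list(w = w, whitener = whitener, reg_fraction = reg_fraction),
            class = "dics_filters")
}

#' DICS source power
#'
#' \eqn{P_v = Re(w_v CSD w_v^H)} in the filters' whitened space.
#'
#' @param filters a `dics_filters`.
#' @param csd complex sensors x sensors band CSD (unwhitened sensor space).
#' @return numeric per-vertex power vector.
#' @export
dics_power <- function(filters, csd) {
  wm <- filters$whitener$w
  sw <- wm %*% csd %*% t(wm)
  w <- filters$w
  p <- Re(rowSums((w %*% sw) * Conj(w)))
  pmax(p, 0)
}

#' Baseline-relative change of source power
#'
#' `(P_cond - P_base) / P_base` per vertex.
#'
#' @param power_condition,power_baseline per-vertex power vectors on the
#'   same grid.
#' @return per-vertex relative change (>= -1 for non-negative power).
#' @export
relative_change <- function(power_condition, power_baseline) {
  if (length(power_condition) != length(power_baseline))
    stop("vertex sets differ")
  zero <- which(power_baseline == 0)
  if (length(zero))
    stop("zero baseline power at vertices: ",
         paste(head(zero, 10), collapse = ", "))
  (power_condition - power_baseline) / power_baseline
}

#' Minimum-norm inverse operator
#'
#' \eqn{M = R L' (L R L' + \lambda^2 I)^{-1}} in pre-whitened sensor space,
#' with a diagonal depth-weighted source prior
#' \eqn{R_{vv} \propto \lVert l_v \rVert^{-2\gamma}} (weighting exponent
#' \eqn{\gamma}), the prior trace-scaled so that \eqn{\lambda^2 = 1/SNR^2}
#' acts on a unit-signal-power scale.  With three orientations per source
#' the tangential components are down-weighted by the loose factor and
#' estimates are combined by their norm.
#'
#' @param gain sensors x (orientations * sources) lead field; columns of a
#'   source are contiguous.
#' @param noise_cov sensor noise covariance (or a `whitener`).
#' @param snr assumed amplitude signal-to-noise ratio; the regularization
#'   is `1/snr^2`.
#' @param depth_exponent depth-weighting exponent (0 disables).
#' @param orientations 1 (fixed, default) or 3.
#' @param loose loose-orientation weighting of tangential components
#'   (used only when `orientations = 3`).
#' @return object of class `inverse_operator`: `m` (sources*orientations x
#'   rank), `whitener`, `snr`, `depth_exponent`, `orientations`.
#' @export
minimum_norm_operator <- function(gain, noise_cov, snr = 3,
                                  depth_exponent = 0.8, orientations = 1,
                                  loose = 0.2) {
  if (snr <= 0) stop("`snr` must be positive")
  wh <- if (inherits(noise_cov, "whitener")) noise_cov
        else compute_whitener(noise_cov)
  g <- wh$w %*% gain
  n_col <- ncol(g)
  if (n_col %% orientations != 0)
    stop("gain columns not a multiple of `orientations`")
  n_src <- n_col / orientations
  src_of_col <- rep(seq_len(n_src), each = orientations)
  col_norm2 <- colSums(g^2)
  depth2 <- vapply(seq_len(n_src),
                   function(v) sum(col_norm2[src_of_col == v]), 0)
  r <- (depth2)^(-depth_exponent)
  r <- rep(r, each = orientations)
  if (orientations == 3) {
    ori_w <- rep(c(1, loose, loose), n_src)   # first column = normal
    r <- r * ori_w
  }
  r <- r * n_col / sum(colSums(g^2) * r)      # trace scaling
  grg <- g %*% (r * t(g))
  lambda2 <- 1 / snr^2
  m <- (r * t(g)) %*% solve(grg + lambda2 * diag(nrow(g)))
  structure(list(m = m, whitener = wh, snr = snr,
                 depth_exponent = depth_exponent,
                 orientations = orientations, loose = loose,
                 n_sources = n_src),
            class = "inverse_operator")
}

#' Apply an inverse operator to sensor data
#'
#' @param op an `inverse_operator`.
#' @param data sensors x samples matrix (or a sensor vector).
#' @param combine for 3-orientation operators, combine orientations by
#'   their norm (default) or return raw components.
#' @return sources x samples matrix (or vector).
#' @export
apply_inverse <- function(op, data, combine = c("norm", "none")) {
  combine <- match.arg(combine)
  vec <- is.null(dim(data))
  if (vec) data <- matrix(data, ncol = 1)
  est <- op$m %*% (op$whitener$w %*% data)
  if (op$orientations == 3 && combine == "norm") {
    n_src <- op$n_sources
    out <- matrix(0, n_src, ncol(est))
    for (v in seq_len(n_src)) {
      rows <- ((v - 1) * 3 + 1):(v * 3)
      out[v, ] <- sqrt(colSums(est[rows, , drop = FALSE]^2))
    }
    est <- out
  }
  if (vec) est[, 1] else est
}

#' Source band power from epochs through an inverse operator
#'
#' Applies the minimum-norm operator to each epoch, computes per-vertex
#' multitaper (DPSS) band power, and averages over epochs.
#'
#' @param epochs an `epoch_set`.
#' @param inverse_op an `inverse_operator`.
#' @param band_center band centre frequency (Hz).
#' @param bandwidth multitaper bandwidth and band window (Hz).
#' @return per-vertex mean band power.
#' @export
source_band_power <- function(epochs, inverse_op, band_center, bandwidth = 2) {
  d <- dim(epochs$data)
  if (band_center + bandwidth / 2 >= epochs$fs / 2)
    stop("band extends beyond Nyquist")
  acc <- NULL
  for (e in seq_len(d[1])) {
    x <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = d[2])
    src <- apply_inverse(inverse_op, x)
    r <- mt_psd_matrix(src, epochs$fs, bandwidth)
    bp <- band_power(r$freqs, r$power, band_center, bandwidth)
    acc <- if (is.null(acc)) bp else acc + bp
  }
  if (d[1] == 0) return(rep(0, inverse_op$n_sources))
  acc / d[1]
}
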