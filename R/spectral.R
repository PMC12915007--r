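#' Morlet-wavelet cross-spectral density
#'
#' Complex Morlet decomposition of each epoch followed by averaging of the
#' per-time-point outer products of channel coefficients.  Edge samples
#' inside the wavelet half-support are excluded.
#'
#' @param epochs an `epoch_set`.
#' @param freqs frequencies (Hz).
#' @param n_cycles wavelet cycles (Morlet width).
#' @return object of class `cross_spectrum`: `freqs`, complex `csd`
#'   (channels x channels x frequencies), `n_epochs`.
#' @export
morlet_csd <- function(epochs, freqs = 1:42, n_cycles = 3) {
  d <- dim(epochs$data)
  n_ep <- d[1]; n_ch <- d[2]; n <- d[3]
  fs <- epochs$fs
  len_s <- n / fs
  bad <- freqs[n_cycles / freqs > len_s]
  if (length(bad))
    stop("frequencies below the resolvable limit for this epoch length: ",
         paste(bad, collapse = ", "))
  csd <- array(complex(real = 0), c(n_ch, n_ch, length(freqs)))
  for (fi in seq_along(freqs)) {
    f <- freqs[fi]
    sigma_t <- n_cycles / (2 * pi * f)
    half <- min(floor((n - 1) / 2), round(5 * sigma_t * fs))
    tt <- (-half:half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sqrt(sum(Mod(w)^2))
    nfft <- stats::nextn(n + length(w) - 1, 2)
    wf <- fft(c(w, complex(real = rep(0, nfft - length(w)))))
    valid <- (half + 1):(n - half)
    acc <- matrix(complex(real = 0), n_ch, n_ch)
    n_t <- 0L
    for (e in seq_len(n_ep)) {
      x <- epochs$data[e, , , drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, nrow = n_ch)
      xf <- mvfft(rbind(t(x), matrix(0, nfft - n, n_ch)))
      conv <- mvfft(xf * wf, inverse = TRUE) / nfft
      coef <- t(conv[half + valid, , drop = FALSE])   # channels x valid times
      acc <- acc + coef %*% Conj(t(coef))
      n_t <- n_t + length(valid)
    }
    m <- acc / n_t
    csd[, , fi] <- (m + Conj(t(m))) / 2              # enforce Hermitian
  }
  structure(list(freqs = freqs, csd = csd, n_epochs = n_ep),
            class = "cross_spectrum")
}

#' Average a cross-spectrum over a narrow band
#'
#' Mean CSD over the frequency bins inside the closed window
#' `center +/- bandwidth/2`; this is the band CSD handed to the DICS
#' beamformer.
#'
#' @param cs a `cross_spectrum`.
#' @param center band centre (Hz).
#' @param bandwidth window width (Hz).
#' @return complex channels x channels matrix.
#' @export
csd_band <- function(cs, center, bandwidth = 2) {
  idx <- which(cs$freqs >= center - bandwidth / 2 &
                 cs$freqs <= center + bandwidth / 2)
  if (!length(idx)) stop("no CSD frequencies inside the requested band")
  m <- apply(cs$csd[, , idx, drop = FALSE], c(1, 2), mean)
  (m + Conj(t(m))) / 2
}

# ---- DPSS multitaper ------------------------------------------------------

# discrete prolate spheroidal sequences via the standard symmetric
# tridiagonal formulation; cached by (n, nw)
.dpss_cache <- new.env(parent = emptyenv())
dpss_tapers <- function(n, w, k) {
  key <- sprintf("%d_%.8f_%d", n, w, k)
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  t0 <- 0:(n - 1)
  dg <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  od <- t0[-1] * (n - t0[-1]) / 2
  m <- diag(dg)
  m[cbind(1:(n - 1), 2:n)] <- od
  m[cbind(2:n, 1:(n - 1))] <- od
  ev <- eigen(m, symmetric = TRUE)
  h <- ev$vectors[, seq_len(k), drop = FALSE]
  # fix sign: symmetric tapers positive mean, antisymmetric positive slope
  for (j in seq_len(k)) {
    s <- sum(h[, j])
    if (abs(s) > 1e-8) { if (s < 0) h[, j] <- -h[, j] }
    else if (h[2, j] - h[1, j] < 0) h[, j] <- -h[, j]
  }
  .dpss_cache[[key]] <- h
  h
}

# multitaper PSD of a series x samples matrix; one-sided, Parseval scaled
mt_psd_matrix <- function(x, fs, bandwidth = 2) {
  n <- ncol(x)
  w <- (bandwidth / 2) / fs
  k <- max(1L, floor(2 * n * w) - 1L)
  if (2 * n * w < 1.5)
    stop("epochs too short for the requested multitaper bandwidth")
  h <- dpss_tapers(n, w, k)
  n_half <- floor(n / 2) + 1L
  psd <- matrix(0, nrow(x), n_half)
  for (j in seq_len(k)) {
    xf <- mvfft(t(x) * h[, j])          # samples x series
    psd <- psd + t(Mod(xf[seq_len(n_half), , drop = FALSE])^2) / fs
  }
  psd <- psd / k
  # one-sided: double everything except DC (and Nyquist when n even)
  dbl <- rep(2, n_half); dbl[1] <- 1
  if (n %% 2 == 0) dbl[n_half] <- 1
  psd <- sweep(psd, 2, dbl, "*")
  list(freqs = (seq_len(n_half) - 1) * fs / n, power = psd, n_tapers = k)
}

#' Multitaper power spectral density
#'
#' DPSS-tapered periodogram averaged across tapers and epochs.  Scaling is
#' Parseval-consistent: the PSD integrated over frequency approximates the
#' signal variance.
#'
#' @param epochs an `epoch_set`.
#' @param bandwidth spectral bandwidth (Hz); the taper count is
#'   `floor(2 N W) - 1`.
#' @return object of class `spectrum_set`: `freqs`, `power` (series x
#'   frequency, linear units), `n_tapers`.
#' @export
multitaper_psd <- function(epochs, bandwidth = 2) {
  d <- dim(epochs$data)
  acc <- NULL
  for (e in seq_len(d[1])) {
    x <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = d[2])
    r <- mt_psd_matrix(x, epochs$fs, bandwidth)
    acc <- if (is.null(acc)) r$power else acc + r$power
  }
  if (d[1] == 0) stop("empty epoch set")
  structure(list(freqs = r$freqs, power = acc / d[1], n_tapers = r$n_tapers,
                 fs = epochs$fs),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d series x %d frequencies (%.2f-%.2f Hz)\n",
              nrow(x$power), length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

# ---- aperiodic (1/f) parametrization -------------------------------------

# robust line fit of log10 power vs log10 frequency: OLS, then refit on the
# points closest to the initial line (small positive residuals)
robust_aperiodic_line <- function(log_f, log_p, percentile = 0.025) {
  fit <- stats::lm.fit(cbind(1, log_f), log_p)
  flat <- log_p - cbind(1, log_f) %*% fit$coefficients
  flat[flat < 0] <- 0
  thr <- quantile(flat, percentile)
  mask <- flat <= thr
  if (sum(mask) >= 2)
    fit <- stats::lm.fit(cbind(1, log_f)[mask, , drop = FALSE], log_p[mask])
  c(offset = fit$coefficients[[1]], exponent = -fit$coefficients[[2]])
}

gaussian_shape <- function(f, ctr, hgt, sd) hgt * exp(-(f - ctr)^2 / (2 * sd^2))

#' Fit an aperiodic (1/f) model with Gaussian peaks
#'
#' Iterative parametrization of a power spectrum in log10-power space:
#' a robust line fit over log10 frequency gives the initial aperiodic
#' component; Gaussian peaks are then extracted from the residual (largest
#' first, width clipped to the limits, stopping at the detection thresholds
#' or the peak budget); finally the aperiodic line is refit on the
#' peak-subtracted spectrum.  Knee-less ("fixed") mode only.
#'
#' @param freqs frequencies (Hz), strictly increasing.
#' @param power linear power values, all positive.
#' @param fit_range length-2 frequency range used for fitting.
#' @param peak_width_limits Gaussian FWHM-style width limits (Hz); the
#'   Gaussian SD is bounded by `peak_width_limits / 2`.
#' @param max_peaks maximum number of peaks.
#' @param min_peak_height absolute detection threshold (log10 units).
#' @param peak_threshold relative detection threshold (residual SDs).
#' @return object of class `aperiodic_model` with `offset`, `exponent`,
#'   `peaks` (data.frame: center_hz, height, width_hz), `r2`, `mae`,
#'   `freqs`, and the fitted log10 `model` values.
#' @export
fit_aperiodic <- function(freqs, power, fit_range = range(freqs),
                          peak_width_limits = c(2, 6), max_peaks = 7,
                          min_peak_height = 0.0, peak_threshold = 1.0) {
  sel <- freqs >= fit_range[1] & freqs <= fit_range[2]
  f <- freqs[sel]; p <- power[sel]
  if (length(f) < 10) stop("need at least 10 frequency points in fit range")
  if (any(p <= 0)) stop("power values must be positive for the log transform")
  log_f <- log10(f); log_p <- log10(p)

  ap <- robust_aperiodic_line(log_f, log_p)
  resid <- log_p - (ap["offset"] - ap["exponent"] * log_f)
  sd_bounds <- peak_width_limits / 2
  peaks <- list()
  work <- resid
  for (k in seq_len(max_peaks)) {
    i <- which.max(work)
    hgt <- work[i]
    # 1e-6 log-power floor guards against extracting machine-noise ripples
    if (hgt < max(min_peak_height, 1e-6) ||
        hgt <= peak_threshold * sd(work)) break
    ctr <- f[i]
    # half-height crossing on each side gives the width guess
    half <- hgt / 2
    li <- i; while (li > 1 && work[li] > half) li <- li - 1
    ri <- i; while (ri < length(f) && work[ri] > half) ri <- ri + 1
    fwhm <- max(f[ri] - f[li], diff(range(f)) / length(f))
    sd_g <- min(max(fwhm / 2.355, sd_bounds[1]), sd_bounds[2])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        w ~ h * exp(-(x - c0)^2 / (2 * s^2)),
        data = list(w = work, x = f),
        start = list(h = hgt, c0 = ctr, s = sd_g),
        lower = c(0, max(min(f), ctr - 2 * sd_g), sd_bounds[1]),
        upper = c(2 * hgt, min(max(f), ctr + 2 * sd_g), sd_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 50))),
      error = function(e) NULL)
    prm <- if (is.null(fit)) c(h = hgt, c0 = ctr, s = sd_g) else coef(fit)
    peaks[[k]] <- prm
    work <- work - gaussian_shape(f, prm[["c0"]], prm[["h"]], prm[["s"]])
  }
  peak_df <- if (length(peaks)) {
    data.frame(center_hz = vapply(peaks, `[[`, 0, "c0"),
               height = vapply(peaks, `[[`, 0, "h"),
               width_hz = 2 * vapply(peaks, `[[`, 0, "s"))
  } else data.frame(center_hz = numeric(0), height = numeric(0),
                    width_hz = numeric(0))

  peak_sum <- rep(0, length(f))
  for (prm in peaks)
    peak_sum <- peak_sum + gaussian_shape(f, prm[["c0"]], prm[["h"]], prm[["s"]])
  fit2 <- stats::lm.fit(cbind(1, log_f), log_p - peak_sum)
  offset <- fit2$coefficients[[1]]
  exponent <- -fit2$coefficients[[2]]
  model_log <- offset - exponent * log_f + peak_sum
  ss_res <- sum((log_p - model_log)^2)
  ss_tot <- sum((log_p - mean(log_p))^2)
  structure(list(offset = offset, exponent = exponent, peaks = peak_df,
                 r2 = 1 - ss_res / ss_tot, mae = mean(abs(log_p - model_log)),
                 freqs = f, model = model_log,
                 aperiodic_log = offset - exponent * log_f),
            class = "aperiodic_model")
}

#' @export
print.aperiodic_model <- function(x, ...) {
  cat(sprintf("<aperiodic_model> offset %.3f, exponent %.3f, %d peak(s), R2 %.3f\n",
              x$offset, x$exponent, nrow(x$peaks), x$r2))
  invisible(x)
}

#' Subtract the aperiodic component in linear space
#'
#' `residual(f) = power(f) - 10^aperiodic(f)`.  Residuals may be negative
#' and are deliberately not clipped.
#'
#' @param freqs frequency grid the model was fitted on.
#' @param power linear power on that grid.
#' @param model an `aperiodic_model`.
#' @return numeric residual (periodic) power.
#' @export
subtract_aperiodic <- function(freqs, power, model) {
  if (length(freqs) != length(model$freqs) ||
      max(abs(freqs - model$freqs)) > 1e-9)
    stop("frequency grid does not match the fitted model")
  power - 10^model$aperiodic_log
}

#' Detect individual band peaks from fitted aperiodic models
#'
#' Per band, the fitted Gaussian peak with the largest height whose centre
#' lies inside the band's cutoff range; when a band has no such peak the
#' band midpoint is used and flagged.  Given several models (e.g. one per
#' sensor), per-band peaks are averaged across them.
#'
#' @param models an `aperiodic_model` or a list of them.
#' @param ranges named list of band cutoff ranges (Hz).
#' @return object of class `band_scheme`: data.frame with `band`,
#'   `peak_hz`, `fallback` (fraction of models that fell back to the
#'   midpoint).
#' @export
detect_band_peaks <- function(models, ranges = band_ranges()) {
  if (inherits(models, "aperiodic_model")) models <- list(models)
  per_band <- lapply(names(ranges), function(b) {
    rng <- ranges[[b]]
    picks <- vapply(models, function(m) {
      in_band <- m$peaks$center_hz >= rng[1] & m$peaks$center_hz <= rng[2]
      if (any(in_band)) {
        cand <- m$peaks[in_band, , drop = FALSE]
        c(cand$center_hz[which.max(cand$height)], 0)
      } else c(mean(rng), 1)
    }, numeric(2))
    c(peak = mean(picks[1, ]), fallback = mean(picks[2, ]))
  })
  out <- data.frame(band = names(ranges),
                    peak_hz = vapply(per_band, `[[`, 0, "peak"),
                    fallback = vapply(per_band, `[[`, 0, "fallback"),
                    stringsAsFactors = FALSE)
  if (any(out$fallback > 0))
    flag_note("band peak fallback to midpoint for: %s",
              paste(out$band[out$fallback > 0], collapse = ", "))
  structure(out, class = c("band_scheme", "data.frame"))
}

#' Narrowband power around a centre frequency
#'
#' Mean power over the frequency bins inside the closed window
#' `center +/- bandwidth/2`.
#'
#' @param freqs frequency grid (Hz).
#' @param power power values (vector, or series x frequency matrix).
#' @param center band centre (Hz); the window must lie inside the grid.
#' @param bandwidth window width (Hz).
#' @return scalar (vector input) or per-series vector.
#' @export
band_power <- function(freqs, power, center, bandwidth = 2) {
  if (center - bandwidth / 2 < min(freqs) || center + bandwidth / 2 > max(freqs))
    stop("band window extends outside the spectrum range")
  idx <- which(freqs >= center - bandwidth / 2 & freqs <= center + bandwidth / 2)
  if (!length(idx)) stop("no frequency bins inside the band window")
  if (is.matrix(power)) rowMeans(power[, idx, drop = FALSE])
  else mean(power[idx])
}
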