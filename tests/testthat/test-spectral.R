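test_that("Morlet CSD is Hermitian PSD with coherent/incoherent structure", {
  set.seed(1)
  n <- 500; fs <- 100
  x <- rnorm(n)
  # two identical channels: coherence 1
  dat <- array(0, c(4, 2, n))
  for (e in 1:4) { v <- rnorm(n); dat[e, 1, ] <- v; dat[e, 2, ] <- v }
  cs <- morlet_csd(epoch_set(dat, fs), freqs = c(5, 10, 20))
  for (fi in 1:3) {
    m <- cs$csd[, , fi]
    expect_lt(max(abs(m - Conj(t(m)))), 1e-12)
    expect_true(all(Re(diag(m)) >= 0))
    coh <- Mod(m[1, 2]) / sqrt(Re(m[1, 1]) * Re(m[2, 2]))
    expect_gt(coh, 0.999)
    ev <- eigen(m, symmetric = FALSE, only.values = TRUE)$values
    expect_gt(min(Re(ev)), -1e-10)      # positive semidefinite
  }
})

test_that("independent channels have low Morlet coherence", {
  set.seed(2)
  dat <- array(rnorm(100 * 2 * 300), c(100, 2, 300))
  cs <- morlet_csd(epoch_set(dat, 100), freqs = c(10, 20))
  for (fi in 1:2) {
    m <- cs$csd[, , fi]
    expect_lt(Mod(m[1, 2]) / sqrt(Re(m[1, 1]) * Re(m[2, 2])), 0.1)
  }
})

test_that("unresolvable Morlet frequencies raise an informative error", {
  e <- epoch_set(array(rnorm(200), c(1, 1, 200)), 100)   # 2 s epochs
  expect_error(morlet_csd(e, freqs = c(1, 10), n_cycles = 3), "1")
})

test_that("multitaper PSD is Parseval-consistent and localizes sinusoids", {
  set.seed(3)
  ep <- epoch_set(array(rnorm(200 * 500), c(200, 1, 500)), 100)
  ps <- multitaper_psd(ep, bandwidth = 2)
  df <- diff(ps$freqs[1:2])
  expect_lt(abs(sum(ps$power) * df - 1), 0.1)      # variance ~ 1
  t <- (0:499) / 100
  eps <- epoch_set(array(2 * sin(2 * pi * 10 * t), c(1, 1, 500)), 100)
  pss <- multitaper_psd(eps)
  idx <- pss$freqs >= 8 & pss$freqs <= 12
  expect_lt(abs(sum(pss$power[1, idx]) * df - 2), 0.1)  # a^2/2 = 2
  expect_gt(sum(pss$power[1, idx]) / sum(pss$power), 0.98)
  z <- multitaper_psd(epoch_set(array(0, c(2, 1, 500)), 100))
  expect_identical(max(z$power), 0)
})

test_that("aperiodic fit recovers offset and exponent of pure power laws", {
  f <- 1:42
  m <- fit_aperiodic(f, 10^1.2 * f^-1.5)
  expect_lt(abs(m$offset - 1.2), 0.05)
  expect_lt(abs(m$exponent - 1.5), 0.05)
  flat <- fit_aperiodic(f, rep(2, 42))
  expect_lt(abs(flat$exponent), 0.05)
  expect_error(fit_aperiodic(f, c(-1, rep(1, 41))), "positive")
  expect_error(fit_aperiodic(1:5, rep(1, 5)), "10 frequency points")
})

test_that("aperiodic fit isolates a single Gaussian peak", {
  f <- 1:42
  p <- 10^1.2 * f^-1.5 * 10^(0.5 * exp(-(f - 10)^2 / (2 * 1.5^2)))
  m <- fit_aperiodic(f, p)
  expect_identical(nrow(m$peaks), 1L)
  expect_lt(abs(m$peaks$center_hz - 10), 0.5)
  expect_lt(abs(m$offset - 1.2), 0.05)
  expect_lt(abs(m$exponent - 1.5), 0.05)
  # reported R^2 equals its definition recomputed independently
  log_p <- log10(p)
  ss_res <- sum((log_p - m$model)^2)
  ss_tot <- sum((log_p - mean(log_p))^2)
  expect_equal(m$r2, 1 - ss_res / ss_tot, tolerance = 1e-12)
})

test_that("exponent recovery over random spectra meets the error budget", {
  set.seed(7)
  f <- seq(1, 42, by = 0.5)
  errs_clean <- errs_noisy <- numeric(100)
  for (i in 1:100) {
    off <- runif(1, 0, 2); chi <- runif(1, 0.5, 2.5)
    p <- 10^off * f^-chi
    errs_clean[i] <- abs(fit_aperiodic(f, p)$exponent - chi)
    pn <- p * (1 + rnorm(length(f), 0, 0.1))
    pn[pn <= 0] <- min(p) * 1e-3
    errs_noisy[i] <- abs(fit_aperiodic(f, pn)$exponent - chi)
  }
  expect_lt(median(errs_clean), 0.05)
  expect_lt(median(errs_noisy), 0.15)
})

test_that("aperiodic subtraction inverts and isolates bumps", {
  f <- 1:42
  p <- 10^0.8 * f^-1.2
  m <- fit_aperiodic(f, p)
  r <- subtract_aperiodic(f, p, m)
  expect_lt(max(abs(r)), 0.05 * max(p))
  expect_equal(r + 10^m$aperiodic_log, p, tolerance = 1e-12)
  bump_lin <- 10^0.4 - 1
  p2 <- p * 10^(0.4 * exp(-(f - 20)^2 / (2 * 2^2)))
  m2 <- fit_aperiodic(f, p2)
  r2 <- subtract_aperiodic(f, p2, m2)
  peak_height <- r2[f == 20] / p[f == 20]
  expect_lt(abs(peak_height - bump_lin) / bump_lin, 0.1)
  expect_error(subtract_aperiodic(2:43, p, m), "grid")
})

test_that("band peaks come from fitted Gaussians with midpoint fallback", {
  f <- 1:42
  base <- 10^1 * f^-1
  bump <- function(ctr, h) 10^(h * exp(-(f - ctr)^2 / (2 * 1.5^2)))
  m_alpha <- fit_aperiodic(f, base * bump(10, 0.5))
  sch <- suppressMessages(detect_band_peaks(m_alpha))
  expect_lt(abs(sch$peak_hz[sch$band == "alpha"] - 10), 0.5)
  expect_identical(sch$fallback[sch$band == "beta"], 1)
  expect_equal(sch$peak_hz[sch$band == "beta"], 20)    # midpoint of 15-25
  expect_equal(sch$peak_hz[sch$band == "gamma"], 36)   # midpoint of 30-42

  m_two <- fit_aperiodic(f, base * bump(10, 0.5) * bump(20, 0.4))
  sch2 <- suppressMessages(detect_band_peaks(m_two))
  expect_lt(abs(sch2$peak_hz[sch2$band == "alpha"] - 10), 0.5)
  expect_lt(abs(sch2$peak_hz[sch2$band == "beta"] - 20), 0.5)

  # two separated alpha bumps: the taller one (9 Hz) wins
  bump_n <- function(ctr, h) 10^(h * exp(-(f - ctr)^2 / (2 * 0.8^2)))
  m_tall <- fit_aperiodic(f, base * bump_n(9, 0.6) * bump_n(11.5, 0.25))
  sch3 <- suppressMessages(detect_band_peaks(m_tall))
  expect_lt(abs(sch3$peak_hz[sch3$band == "alpha"] - 9), 0.6)
})

test_that("band power averages the bins inside the closed window", {
  f <- c(8, 9, 10, 11, 12)
  expect_equal(band_power(f, rep(3, 5), 10, 2), 3)
  p <- c(0, 0, 7, 0, 0)
  expect_equal(band_power(f, p, 10, 0.5), 7)
  ramp <- 1:5
  expect_equal(band_power(f, ramp, 10, 2), mean(2:4))
  expect_error(band_power(f, ramp, 13, 2), "outside")
})
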