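#' Condition table of the 2 x 3 factorial design
#'
#' Two visuo-spatial workload levels (LW, HW) crossed with three speech
#' valence levels (LV = negative, NV = neutral, HV = positive).
#'
#' @return data.frame with columns `condition`, `workload`, `valence`.
#' @export
condition_table <- function() {
  data.frame(
    condition = c("LW/LV", "LW/NV", "LW/HV", "HW/LV", "HW/NV", "HW/HV"),
    workload  = rep(c("LW", "HW"), each = 3),
    valence   = rep(c("LV", "NV", "HV"), 2),
    stringsAsFactors = FALSE)
}

#' Specify a planted condition effect on band-limited source power
#'
#' An effect is a patch of grid vertices whose narrowband oscillation
#' variance is multiplied by a per-condition gain.  Gains are multiplicative
#' power factors (1 = no change).
#'
#' @param factor one of `"workload"`, `"valence"`, `"interaction"`.
#' @param band one of `"alpha"`, `"beta"`, `"gamma"`.
#' @param vertices integer patch of grid vertex indices.
#' @param gains named numeric vector of length 6 (names = condition labels
#'   of [condition_table()]); all positive.
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(factor, band, vertices, gains) {
  factor <- match.arg(factor, c("workload", "valence", "interaction"))
  band <- match.arg(band, c("alpha", "beta", "gamma"))
  cond <- condition_table()$condition
  if (is.null(names(gains)) || !setequal(names(gains), cond))
    stop("`gains` must be named by the 6 condition labels")
  gains <- gains[cond]
  if (any(!is.finite(gains)) || any(gains <= 0))
    stop("`gains` must be positive")
  if (factor == "interaction") {
    d_lw <- gains["LW/LV"] - gains["LW/HV"]
    d_hw <- gains["HW/LV"] - gains["HW/HV"]
    if (d_lw * d_hw >= 0)
      stop("cross-over interaction spec must reverse the LV/HV ordering ",
           "between workload levels")
  }
  structure(list(factor = factor, band = band,
                 vertices = as.integer(vertices), gains = gains),
            class = "effect_spec")
}

#' Default planted effects emulating the dual-task findings
#'
#' Parietal beta increase for emotional (LV, HV) versus neutral speech;
#' workload gamma increase and beta decrease under high workload; and a
#' cross-over gamma interaction (LV > HV under LW, LV < HV under HW) at a
#' frontal patch.
#'
#' @param grid a `source_grid`.
#' @param gain multiplicative power gain of the planted effects (default
#'   1.5; the suppression direction uses 1/gain).
#' @return list of `effect_spec`.
#' @export
default_effects <- function(grid, gain = 1.5) {
  cond <- condition_table()$condition
  g1 <- setNames(rep(1, 6), cond)
  n <- grid$n_vertices
  # three well-separated deterministic patches (1-ring neighbourhoods)
  centers <- c(1L, as.integer(round(n / 2)), n)
  patch <- lapply(centers, function(cc) grid_neighbourhood(grid, cc, order = 1))

  beta_val <- g1; beta_val[c("LW/LV", "LW/HV", "HW/LV", "HW/HV")] <- gain
  gamma_wl <- g1; gamma_wl[c("HW/LV", "HW/NV", "HW/HV")] <- gain
  beta_wl  <- g1; beta_wl[c("HW/LV", "HW/NV", "HW/HV")] <- 1 / gain
  gamma_int <- g1
  gamma_int["LW/LV"] <- gain;  gamma_int["LW/HV"] <- 1 / gain
  gamma_int["HW/LV"] <- 1 / gain; gamma_int["HW/HV"] <- gain

  list(
    effect_spec("valence",  "beta",  patch[[1]], beta_val),
    effect_spec("workload", "gamma", patch[[2]], gamma_wl),
    effect_spec("workload", "beta",  patch[[2]], beta_wl),
    effect_spec("interaction", "gamma", patch[[3]], gamma_int))
}

#' Configuration of a synthetic cohort
#'
#' Defaults are sized for desk-scale validation work: 12 subjects, 64
#' sensors, a 162-vertex (ico-2) grid, 100 Hz sampling and 300 s blocks.
#'
#' @param n_subjects number of subjects.
#' @param n_sensors number of sensors.
#' @param grid_level icosahedron level of the source grid.
#' @param fs sampling rate (Hz).
#' @param block_s experimental block duration (s).
#' @param baseline_s baseline block duration (s).
#' @param empty_room_s empty-room segment duration (s).
#' @param effects list of [effect_spec()]; `NULL` = the defaults of
#'   [default_effects()]; `list()` = a null cohort.
#' @param exponent_range range the per-source aperiodic exponent is drawn
#'   from (uniformly).
#' @param osc_snr named per-band oscillation amplitude relative to the
#'   1/f background standard deviation at source level.
#' @param sensor_noise_scale sensor noise amplitude multiplier.
#' @param smoothness forward-model column smoothness, see
#'   [build_source_model()].
#' @param gaze,telemetry parameter lists, see [gaze_params()] and
#'   [telemetry_params()].
#' @param behaviour generate gaze/telemetry streams (disable for
#'   MEG-only simulations).
#' @param baselines generate per-condition sensor baseline blocks
#'   (disable for decoding-only simulations).
#' @param meg generate sensor/empty-room blocks (disable for
#'   behaviour-only simulations).
#' @return list of class `study_config`.
#' @export
study_config <- function(n_subjects = 12, n_sensors = 64, grid_level = 2,
                         fs = 100, block_s = 300, baseline_s = 60,
                         empty_room_s = 180, effects = NULL,
                         exponent_range = c(0.8, 1.6),
                         osc_snr = c(alpha = 1, beta = 1, gamma = 1),
                         sensor_noise_scale = 0.5, smoothness = 0.35,
                         gaze = gaze_params(), telemetry = telemetry_params(),
                         behaviour = TRUE, baselines = TRUE, meg = TRUE) {
  structure(list(n_subjects = n_subjects, n_sensors = n_sensors,
                 grid_level = grid_level, fs = fs, block_s = block_s,
                 baseline_s = baseline_s, empty_room_s = empty_room_s,
                 effects = effects, exponent_range = exponent_range,
                 osc_snr = osc_snr, sensor_noise_scale = sensor_noise_scale,
                 smoothness = smoothness, gaze = gaze, telemetry = telemetry,
                 behaviour = behaviour, baselines = baselines, meg = meg),
            class = "study_config")
}

# canonical band cutoff ranges (Hz)
band_ranges <- function() {
  list(alpha = c(8, 12), beta = c(15, 25), gamma = c(30, 42))
}

# squared magnitude of a 4th-order Butterworth band-pass at the FFT bin
# frequencies of an n-sample signal; squaring emulates zero-phase
# (forward-backward) application.  Cached per (n, fs, lo, hi).
.butter_cache <- new.env(parent = emptyenv())
butter_bp_mag2 <- function(n, fs, lo, hi) {
  key <- sprintf("%d_%g_%g_%g", n, fs, lo, hi)
  if (!is.null(.butter_cache[[key]])) return(.butter_cache[[key]])
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1) / n
  e <- exp(-1i * w)
  num <- Re(outer(e, seq_along(bf$b) - 1, "^") %*% bf$b)^2 +
    Im(outer(e, seq_along(bf$b) - 1, "^") %*% bf$b)^2
  den <- Re(outer(e, seq_along(bf$a) - 1, "^") %*% bf$a)^2 +
    Im(outer(e, seq_along(bf$a) - 1, "^") %*% bf$a)^2
  .butter_cache[[key]] <- as.numeric(num / den)
  .butter_cache[[key]]
}

col_unit_var <- function(x) {
  s <- sqrt(colMeans(x^2) - colMeans(x)^2)
  x / rep(s, each = nrow(x))
}

# stationary Gaussian noise synthesized in the frequency domain: complex
# white spectrum shaped by a (two-sided symmetric) amplitude profile,
# one inverse FFT; unit variance per column
shaped_noise <- function(n, shape_mat) {
  m <- ncol(shape_mat)
  nz <- which(rowSums(abs(shape_mat)) > 0)
  z <- matrix(complex(real = 0), n, m)
  z[nz, ] <- complex(real = rnorm(length(nz) * m),
                     imaginary = rnorm(length(nz) * m)) *
    shape_mat[nz, , drop = FALSE]
  col_unit_var(Re(mvfft(z, inverse = TRUE)) / n)
}

# n x m matrix of 1/f^chi background series, one column per source;
# chi is a length-m vector of exponents; unit variance per column
one_over_f_noise <- function(n, fs, chi) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)           # two-sided frequency axis
  f[1] <- f[2]                   # avoid DC blow-up
  shape <- outer(f, chi, function(fr, ch) fr^(-ch / 2))
  shaped_noise(n, shape)
}

# n x m matrix of band-limited Gaussian noise (4th-order zero-phase
# band-pass amplitude profile, applied in the frequency domain); unit
# variance per column
bandlimited_noise <- function(n, fs, lo, hi, m) {
  h2 <- butter_bp_mag2(n, fs, lo, hi)
  h2[h2 < 1e-6 * max(h2)] <- 0   # skip negligible-support bins
  shaped_noise(n, matrix(h2, n, m))
}

# simulate one sensor block: 1/f background + per-band oscillations with
# per-source gains, mixed through the forward model, plus sensor noise
simulate_sensor_block <- function(model, n, fs, chi, band_amp, gains_by_band,
                                  noise_scale) {
  n_src <- model$n_sources
  src <- one_over_f_noise(n, fs, chi)
  rng <- band_ranges()
  for (b in names(rng)) {
    amp <- band_amp[[b]]
    if (all(amp == 0)) next
    osc <- bandlimited_noise(n, fs, rng[[b]][1], rng[[b]][2], n_src)
    scale <- amp * sqrt(gains_by_band[[b]])
    src <- src + sweep(osc, 2, scale, "*")
  }
  noise <- matrix(rnorm(n * model$n_sensors), n, model$n_sensors) %*%
    chol(model$noise_cov) * noise_scale
  t(src %*% t(model$gain) + noise)          # sensors x samples
}

#' Generate a full synthetic cohort
#'
#' Produces, per subject, one sensor block per condition plus a matching
#' baseline block (all gains 1), gaze and telemetry blocks per condition,
#' an empty-room (sensor-noise-only) segment, and the ground truth needed
#' for recovery tests.  Regeneration from the same (config, seed) is
#' bit-identical.
#'
#' @param config a [study_config()].
#' @param seed master integer seed.
#' @return object of class `synthetic_study`.
#' @export
generate_experiment <- function(config, seed = 1) {
  stopifnot(inherits(config, "study_config"))
  grid <- source_grid(config$grid_level)
  effects <- if (is.null(config$effects)) default_effects(grid)
             else config$effects
  for (ef in effects) {
    if (!inherits(ef, "effect_spec")) stop("`effects` must be effect_spec objects")
    if (any(ef$vertices < 1L | ef$vertices > grid$n_vertices))
      stop("effect patch vertices outside the source grid")
  }
  seeds <- derive_seeds(seed, 2L + config$n_subjects)
  model <- build_source_model(config$n_sensors, grid, config$smoothness,
                              seed = seeds[1])
  cond <- condition_table()
  n_blk <- round(config$block_s * config$fs)
  n_bas <- round(config$baseline_s * config$fs)

  # per-condition, per-band multiplicative gain per source vertex
  gains_for <- function(cond_label) {
    g <- list(alpha = rep(1, grid$n_vertices),
              beta = rep(1, grid$n_vertices),
              gamma = rep(1, grid$n_vertices))
    for (ef in effects)
      g[[ef$band]][ef$vertices] <- g[[ef$band]][ef$vertices] *
        ef$gains[[cond_label]]
    g
  }
  unit_gains <- list(alpha = rep(1, grid$n_vertices),
                     beta = rep(1, grid$n_vertices),
                     gamma = rep(1, grid$n_vertices))

  subjects <- vector("list", config$n_subjects)
  chi_all <- matrix(NA_real_, config$n_subjects, grid$n_vertices)
  for (s in seq_len(config$n_subjects)) {
    sub_seeds <- derive_seeds(seeds[2L + s], 3L * nrow(cond) + 2L)
    chi <- with_seed(sub_seeds[1], runif(grid$n_vertices,
                                         config$exponent_range[1],
                                         config$exponent_range[2]))
    chi_all[s, ] <- chi
    blocks <- baselines <- gaze <- telemetry <- list()
    gaze_base <- telemetry_base <- list()
    for (ci in seq_len(nrow(cond))) {
      lab <- cond$condition[ci]
      wl <- cond$workload[ci]
      if (!isFALSE(config$meg))
        blocks[[lab]] <- with_seed(sub_seeds[1L + ci],
          simulate_sensor_block(model, n_blk, config$fs, chi, config$osc_snr,
                                gains_for(lab), config$sensor_noise_scale))
      if (!isFALSE(config$meg) && isTRUE(config$baselines))
        baselines[[lab]] <- with_seed(sub_seeds[1L + nrow(cond) + ci],
          simulate_sensor_block(model, n_bas, config$fs, chi, config$osc_snr,
                                unit_gains, config$sensor_noise_scale))
      if (!isTRUE(config$behaviour)) next
      bseed <- sub_seeds[1L + 2L * nrow(cond) + ci]
      bseeds <- derive_seeds(bseed, 4L)
      gp <- condition_gaze_params(config$gaze, wl)
      gp$duration_s <- config$block_s
      tp <- condition_telemetry_params(config$telemetry, wl)
      tp$duration_s <- config$block_s
      gaze[[lab]] <- generate_gaze_block(gp, seed = bseeds[1])
      telemetry[[lab]] <- generate_telemetry_block(tp, seed = bseeds[2])
      # behavioural baselines: neutral (low-workload) parameterization
      gp0 <- config$gaze; gp0$duration_s <- config$baseline_s
      tp0 <- config$telemetry; tp0$duration_s <- config$baseline_s
      gaze_base[[lab]] <- generate_gaze_block(gp0, seed = bseeds[3])
      telemetry_base[[lab]] <- generate_telemetry_block(tp0, seed = bseeds[4])
    }
    empty <- NULL
    if (!isFALSE(config$meg)) {
      n_er <- round(config$empty_room_s * config$fs)
      empty <- with_seed(sub_seeds[3L * nrow(cond) + 2L],
        t(matrix(rnorm(n_er * model$n_sensors), n_er, model$n_sensors) %*%
            chol(model$noise_cov) * config$sensor_noise_scale))
    }
    subjects[[s]] <- list(blocks = blocks, baselines = baselines,
                          gaze = gaze, telemetry = telemetry,
                          gaze_baselines = gaze_base,
                          telemetry_baselines = telemetry_base,
                          empty_room = empty)
  }
  structure(list(subjects = subjects, model = model, config = config,
                 conditions = cond, fs = config$fs,
                 ground_truth = list(effects = effects, exponents = chi_all),
                 seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d subjects, %d sensors, %d-vertex grid, %g Hz\n",
    length(x$subjects), x$model$n_sensors, x$model$grid$n_vertices, x$fs))
  cat(sprintf("  %d planted effect(s); %g s blocks\n",
              length(x$ground_truth$effects), x$config$block_s))
  invisible(x)
}

#' Simulate a factorial source-power dataset directly
#'
#' Generates a subjects x conditions x vertices array of relative-change
#' power values with additive subject offsets, i.i.d. cell noise, and
#' planted per-condition mean shifts inside effect patches.  This is the
#' dataset-level generator used to calibrate the cluster permutation test
#' (type-I error and power) without simulating sensor time series.
#'
#' @param grid a `source_grid` (supplies vertex count and adjacency).
#' @param n_subjects number of subjects.
#' @param effects list of lists with fields `vertices` and `shift` (named
#'   length-6 per-condition additive mean shift, condition order of
#'   [condition_table()]); `list()` for a null dataset.
#' @param noise_sd within-cell noise standard deviation.
#' @param subject_sd standard deviation of additive subject offsets.
#' @param seed integer seed.
#' @return a `factorial_dataset`, see [factorial_dataset()].
#' @export
simulate_factorial_dataset <- function(grid, n_subjects = 12,
                                       effects = list(), noise_sd = 1,
                                       subject_sd = 0.5, seed = 1) {
  cond <- condition_table()
  nv <- grid$n_vertices
  with_seed(seed, {
    y <- array(rnorm(n_subjects * 6 * nv, sd = noise_sd),
               dim = c(n_subjects, 6, nv))
    y <- y + array(rep(rnorm(n_subjects, sd = subject_sd), 6 * nv),
                   dim = c(n_subjects, 6, nv))
  })
  for (ef in effects) {
    shift <- ef$shift
    if (is.null(names(shift))) names(shift) <- cond$condition
    for (ci in seq_len(6))
      y[, ci, ef$vertices] <- y[, ci, ef$vertices] +
        shift[[cond$condition[ci]]]
  }
  factorial_dataset(y, grid = grid)
}

#' Planted mean-shift helper for [simulate_factorial_dataset()]
#'
#' @param factor `"workload"`, `"valence"` or `"interaction"`.
#' @param vertices patch vertex indices.
#' @param delta shift magnitude (same units as the dataset noise SD).
#' @return list with `vertices` and per-condition `shift`.
#' @export
planted_shift <- function(factor, vertices, delta = 1) {
  cond <- condition_table()
  shift <- setNames(rep(0, 6), cond$condition)
  if (factor == "workload") {
    shift[cond$workload == "HW"] <- delta
  } else if (factor == "valence") {
    shift[cond$valence %in% c("LV", "HV")] <- delta
  } else if (factor == "interaction") {
    shift[c("LW/LV", "HW/HV")] <- delta
    shift[c("LW/HV", "HW/LV")] <- -delta
  } else stop("unknown factor")
  list(vertices = as.integer(vertices), shift = shift)
}
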