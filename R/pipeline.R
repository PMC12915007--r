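#' Analysis configuration
#'
#' Collects the tunable parameters of the two headline analyses: 5 s
#' epochs for the oscillatory main-effects route, 2 s epochs and a
#' 30--42 Hz FIR band-pass for the decoding route, the permutation and
#' cross-validation settings, and the inverse-solution parameters
#' (depth 0.8; SNR 3 for patterns, 1 for power).
#'
#' @param epoch_main_s epoch length of the source-power route (s).
#' @param epoch_decode_s epoch length of the decoding route (s).
#' @param freqs Morlet/CSD frequency grid (Hz).
#' @param n_cycles Morlet cycles.
#' @param reject_threshold amplitude rejection threshold (signal units).
#' @param n_perm cluster permutations.
#' @param cluster_alpha,test_alpha clustering significance levels.
#' @param k,repeats,n_components cross-validation folds/repetitions and
#'   CSP components.
#' @param decode_band gamma band edges for the decoding FIR (Hz).
#' @param snr_patterns,snr_power minimum-norm SNR for pattern
#'   localization and source power.
#' @param depth_exponent minimum-norm depth weighting.
#' @param reg_fraction DICS diagonal loading.
#' @param roi_q ROI percentile of the grand-average pattern map.
#' @param bandwidth spectral bandwidth (Hz).
#' @param aperiodic_subtract subtract the fitted 1/f component before
#'   band power extraction.
#' @param n_boot bootstrap iterations for summary CIs.
#' @param seed master analysis seed.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(epoch_main_s = 5, epoch_decode_s = 2,
                            freqs = 1:42, n_cycles = 3,
                            reject_threshold = Inf, n_perm = 5000,
                            cluster_alpha = 0.05, test_alpha = 0.05,
                            k = 10, repeats = 3, n_components = 4,
                            decode_band = c(30, 42), snr_patterns = 3,
                            snr_power = 1, depth_exponent = 0.8,
                            reg_fraction = 0.05, roi_q = 90,
                            bandwidth = 2, aperiodic_subtract = TRUE,
                            n_boot = 5000, seed = 1) {
  structure(as.list(environment()), class = "analysis_config")
}

# epoch + reject + label one continuous block
prep_block <- function(block, fs, length_s, threshold, condition) {
  ep <- segment_epochs(block, fs, length_s, condition = condition)
  if (is.finite(threshold)) ep <- reject_amplitude(ep, threshold)$epochs
  ep
}

# per-subject individual band peaks from baseline sensor spectra
subject_band_peaks <- function(subj, fs, cfg) {
  psds <- NULL
  freqs <- NULL
  for (b in subj$baselines) {
    e <- segment_epochs(b, fs, cfg$epoch_main_s)
    if (n_epochs(e) == 0) next
    p <- multitaper_psd(e, cfg$bandwidth)
    psds <- if (is.null(psds)) p$power else psds + p$power
    freqs <- p$freqs
  }
  if (is.null(psds)) stop("no baseline epochs available for peak detection")
  sel <- freqs >= min(cfg$freqs) & freqs <= max(cfg$freqs)
  models <- lapply(seq_len(nrow(psds)), function(ch)
    fit_aperiodic(freqs[sel], psds[ch, sel]))
  suppressMessages(detect_band_peaks(models))
}

# vertex power spectrum of one block: broadband DICS filters applied per
# frequency
vertex_spectra <- function(csd_block, filters) {
  vapply(seq_along(csd_block$freqs), function(fi)
    dics_power(filters, csd_block$csd[, , fi]), numeric(nrow(filters$w)))
}

# periodic residual spectra: one aperiodic fit per vertex, subtracted in
# linear space; returns the residual matrix (vertices x frequencies)
periodic_residual_spectra <- function(freqs, spectra, max_peaks = 3) {
  t(vapply(seq_len(nrow(spectra)), function(v) {
    p <- pmax(spectra[v, ], .Machine$double.xmin)
    m <- fit_aperiodic(freqs, p, max_peaks = max_peaks)
    subtract_aperiodic(freqs, p, m)
  }, numeric(length(freqs))))
}

#' Oscillatory source-power main-effects analysis
#'
#' End-to-end: 5 s epoching, amplitude rejection, trial-count
#' equalization, Morlet CSD, pre-whitened DICS source power per condition
#' and baseline, baseline-relative change of (optionally
#' aperiodic-subtracted) individual-peak band power, and cluster
#' permutation tests of both main effects and the interaction, with
#' cluster-mean post-hoc contrasts (Wilcoxon + BH-FDR + bootstrap CIs)
#' and Spearman correlations between cluster band powers.
#'
#' @param study a `synthetic_study`.
#' @param config an [analysis_config()].
#' @return list of class `main_effects_result`: per band, the
#'   `factorial_dataset` of relative changes, the three `cluster_result`s,
#'   post-hoc tables, and the per-subject band peaks.
#' @export
run_main_effects <- function(study, config = analysis_config()) {
  fs <- study$fs
  model <- study$model
  cond <- study$conditions
  n_sub <- length(study$subjects)
  bands <- names(band_ranges())
  rel <- lapply(bands, function(b)
    array(NA_real_, c(n_sub, 6, model$n_sources)))
  names(rel) <- bands
  peaks_by_subject <- vector("list", n_sub)

  for (s in seq_len(n_sub)) {
    subj <- study$subjects[[s]]
    whit <- compute_whitener(t(subj$empty_room))
    peaks <- subject_band_peaks(subj, fs, config)
    peaks_by_subject[[s]] <- peaks

    csd_cond <- lapply(cond$condition, function(lab) {
      ep <- prep_block(subj$blocks[[lab]], fs, config$epoch_main_s,
                       config$reject_threshold, lab)
      morlet_csd(ep, config$freqs, config$n_cycles)
    })
    names(csd_cond) <- cond$condition
    csd_base <- lapply(cond$condition, function(lab) {
      ep <- prep_block(subj$baselines[[lab]], fs, config$epoch_main_s,
                       config$reject_threshold, lab)
      morlet_csd(ep, config$freqs, config$n_cycles)
    })
    names(csd_base) <- cond$condition
    # common filters from the mean broadband CSD over all blocks (shared
    # spatial filters across conditions, as in a common-CSD beamformer)
    all_csd <- c(csd_cond, csd_base)
    fspan <- range(config$freqs)
    common <- Reduce(`+`, lapply(all_csd, csd_band,
                                 center = mean(fspan),
                                 bandwidth = diff(fspan) + 1)) /
      length(all_csd)
    filt <- dics_filters(common, model$gain, whit, config$reg_fraction)
    for (ci in seq_len(6)) {
      lab <- cond$condition[ci]
      sp_c <- vertex_spectra(csd_cond[[lab]], filt)
      sp_b <- vertex_spectra(csd_base[[lab]], filt)
      if (config$aperiodic_subtract) {
        sp_c <- periodic_residual_spectra(config$freqs, sp_c)
        sp_b <- periodic_residual_spectra(config$freqs, sp_b)
      }
      for (b in bands) {
        peak <- peaks$peak_hz[peaks$band == b]
        p_c <- band_power(config$freqs, sp_c, peak, config$bandwidth)
        p_b <- band_power(config$freqs, sp_b, peak, config$bandwidth)
        p_b[p_b == 0] <- .Machine$double.eps
        rel[[b]][s, ci, ] <- (p_c - p_b) / abs(p_b)
      }
    }
  }

  seeds <- derive_seeds(config$seed, 3 * length(bands))
  out <- list()
  si <- 0
  for (b in bands) {
    ds <- factorial_dataset(rel[[b]], grid = model$grid)
    tests <- lapply(c("main_workload", "main_valence", "interaction"),
                    function(eff) {
      si <<- si + 1
      permutation_cluster_test(ds, eff, n_perm = config$n_perm,
                               cluster_alpha = config$cluster_alpha,
                               test_alpha = config$test_alpha,
                               seed = seeds[si])
    })
    names(tests) <- c("main_workload", "main_valence", "interaction")
    posthoc <- lapply(tests, function(tr)
      cluster_posthoc(ds, tr, n_boot = config$n_boot, seed = config$seed))
    out[[b]] <- list(dataset = ds, tests = tests, posthoc = posthoc)
  }
  out$band_peaks <- peaks_by_subject
  out$correlations <- cluster_power_correlations(out, bands)
  class(out) <- "main_effects_result"
  out
}

# cluster-mean post-hoc contrasts for the significant clusters of a test
cluster_posthoc <- function(dataset, test_result, n_boot = 5000, seed = 1) {
  sig <- Filter(function(cl) cl$significant, test_result$clusters)
  lapply(sig, function(cl) {
    cm <- apply(dataset$power[, , cl$vertices, drop = FALSE], c(1, 2), mean)
    colnames(cm) <- dataset$design$condition
    eff <- test_result$effect
    if (eff == "main_workload") {
      lv <- list(LW = rowMeans(cm[, dataset$design$workload == "LW"]),
                 HW = rowMeans(cm[, dataset$design$workload == "HW"]))
    } else {
      lv <- lapply(c("LV", "NV", "HV"), function(v)
        rowMeans(cm[, dataset$design$valence == v]))
      names(lv) <- c("LV", "NV", "HV")
    }
    prs <- utils::combn(names(lv), 2)
    tests <- apply(prs, 2, function(pr) {
      w <- wilcoxon_signed_rank(lv[[pr[1]]], lv[[pr[2]]])
      c(statistic = w$statistic, p = w$p)
    })
    contrasts <- data.frame(a = prs[1, ], b = prs[2, ],
                            statistic = tests["statistic", ],
                            p = tests["p", ],
                            mean_diff = apply(prs, 2, function(pr)
                              mean(lv[[pr[1]]] - lv[[pr[2]]])))
    contrasts$p_adj <- fdr_bh(contrasts$p)$adjusted
    seeds <- derive_seeds(seed, length(lv))
    cis <- Map(function(v, sd1) bootstrap_mean_ci(v, n_iter = n_boot,
                                                  bonferroni_m = length(lv),
                                                  seed = sd1),
               lv, as.list(seeds))
    list(vertices = cl$vertices, level_means = lv, contrasts = contrasts,
         level_ci = cis)
  })
}

# Spearman correlations between mean cluster powers across bands
cluster_power_correlations <- function(res, bands) {
  series <- list()
  for (b in bands) {
    for (eff in names(res[[b]]$tests)) {
      for (cl in Filter(function(c) c$significant,
                        res[[b]]$tests[[eff]]$clusters)) {
        key <- sprintf("%s_%s", b, eff)
        if (is.null(series[[key]]))
          series[[key]] <- as.numeric(
            apply(res[[b]]$dataset$power[, , cl$vertices, drop = FALSE],
                  c(1, 2), mean))
      }
    }
  }
  if (length(series) < 2) return(NULL)
  prs <- utils::combn(names(series), 2)
  data.frame(a = prs[1, ], b = prs[2, ],
             rho = apply(prs, 2, function(pr)
               spearman_corr(series[[pr[1]]], series[[pr[2]]])$rho),
             p = apply(prs, 2, function(pr)
               spearman_corr(series[[pr[1]]], series[[pr[2]]])$p))
}

#' Multiclass decoding of the workload-by-valence interaction
#'
#' End-to-end gamma-band decoding route: 30--42 Hz zero-phase FIR, 2 s
#' epochs, trial-count equalization over the four emotional-speech by
#' workload conditions, per-subject CSP+LDA repeated stratified
#' cross-validation, Haufe pattern extraction, minimum-norm pattern
#' localization (SNR 3), F1-weighted grand-average pattern map, and
#' 90th-percentile ROI contrasts of minimum-norm gamma source power
#' (SNR 1).
#'
#' @param study a `synthetic_study`.
#' @param config an [analysis_config()].
#' @param gamma_center gamma band-power centre frequency (Hz).
#' @return list of class `decoding_pipeline_result` with per-subject
#'   `decoding` results, the grand-average `pattern_map`, and the ROI
#'   `contrasts`.
#' @export
run_interaction_decoding <- function(study, config = analysis_config(),
                                     gamma_center = 36) {
  fs <- study$fs
  model <- study$model
  classes <- c("LW/LV", "LW/HV", "HW/LV", "HW/HV")
  n_sub <- length(study$subjects)
  seeds <- derive_seeds(config$seed, n_sub)
  decodings <- vector("list", n_sub)
  maps <- vector("list", n_sub)
  power_arr <- NULL

  for (s in seq_len(n_sub)) {
    subj <- study$subjects[[s]]
    whit <- compute_whitener(t(subj$empty_room))
    sets <- lapply(classes, function(lab) {
      filt <- bandpass_fir(subj$blocks[[lab]], fs, config$decode_band[1],
                           config$decode_band[2])
      prep_block(filt, fs, config$epoch_decode_s, config$reject_threshold,
                 lab)
    })
    names(sets) <- classes
    sets <- equalize_counts(sets)
    all_data <- abind3(lapply(sets, function(e) e$data))
    ep <- epoch_set(all_data, fs,
                    condition = rep(classes, vapply(sets, n_epochs, 1L)))
    labels <- ep$condition
    dec <- crossval_decode(ep, labels, k = config$k,
                           repeats = config$repeats,
                           n_components = config$n_components,
                           n_boot = config$n_boot, seed = seeds[s])
    decodings[[s]] <- dec

    inv_pat <- minimum_norm_operator(model$gain, whit,
                                     snr = config$snr_patterns,
                                     depth_exponent = config$depth_exponent)
    maps[[s]] <- localize_patterns(dec$patterns, inv_pat)

    inv_pow <- minimum_norm_operator(model$gain, whit,
                                     snr = config$snr_power,
                                     depth_exponent = config$depth_exponent)
    if (is.null(power_arr))
      power_arr <- array(NA_real_, c(n_sub, length(classes),
                                     model$n_sources),
                         dimnames = list(NULL, classes, NULL))
    for (ci in seq_along(classes)) {
      raw_ep <- prep_block(subj$blocks[[classes[ci]]], fs,
                           config$epoch_decode_s, config$reject_threshold,
                           classes[ci])
      power_arr[s, ci, ] <- source_band_power(raw_ep, inv_pow,
                                              gamma_center,
                                              config$bandwidth)
    }
  }
  f1s <- vapply(decodings, `[[`, 0, "mean_f1")
  grand <- weighted_grand_average(maps, f1s)
  contrasts <- percentile_roi_contrast(grand, power_arr, q = config$roi_q,
                                       seed = config$seed)
  structure(list(decoding = decodings, f1 = f1s, grand_pattern = grand,
                 roi_contrasts = contrasts,
                 confusion = Reduce(`+`, lapply(decodings, `[[`,
                                                "confusion"))),
            class = "decoding_pipeline_result")
}

# bind epoch arrays along the first (epoch) dimension
abind3 <- function(lst) {
  d <- dim(lst[[1]])
  n <- sum(vapply(lst, function(x) dim(x)[1], 1L))
  out <- array(NA_real_, c(n, d[2], d[3]))
  at <- 0L
  for (x in lst) {
    k <- dim(x)[1]
    if (k) out[at + seq_len(k), , ] <- x
    at <- at + k
  }
  out
}

#' Gaze and driving behavioural analysis
#'
#' Computes the four gaze measures and the five driving measures plus the
#' composite score per subject and condition, applies baseline
#' correction, and tests the workload and valence contrasts with Wilcoxon
#' signed-rank tests (BH-FDR over measures) and bootstrap mean CIs.
#'
#' @param study a `synthetic_study`.
#' @param config an [analysis_config()].
#' @return list of class `behaviour_result` with `measures` (tidy
#'   data.frame), `contrasts`, and `score` per block.
#' @export
run_behavioural <- function(study, config = analysis_config()) {
  cond <- study$conditions
  n_sub <- length(study$subjects)
  rows <- list()
  for (s in seq_len(n_sub)) {
    subj <- study$subjects[[s]]
    drv <- matrix(NA_real_, 6, 5)
    for (ci in seq_len(6)) {
      lab <- cond$condition[ci]
      gm <- suppressMessages(gaze_metrics(subj$gaze[[lab]]))
      gb <- suppressMessages(gaze_metrics(subj$gaze_baselines[[lab]]))
      dm <- driving_measures(subj$telemetry[[lab]])
      drv[ci, ] <- unlist(dm)
      for (m in names(gm))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = lab, workload = cond$workload[ci],
          valence = cond$valence[ci], measure = m,
          value = baseline_correct(gm[[m]], gb[[m]]), raw = gm[[m]])
      for (m in names(dm))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = lab, workload = cond$workload[ci],
          valence = cond$valence[ci], measure = m, value = dm[[m]],
          raw = dm[[m]])
    }
    score <- suppressMessages(composite_score(drv))
    for (ci in seq_len(6))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, condition = cond$condition[ci],
        workload = cond$workload[ci], valence = cond$valence[ci],
        measure = "driving_score", value = score[ci], raw = score[ci])
  }
  measures <- do.call(rbind, rows)

  contrast_one <- function(m) {
    d <- measures[measures$measure == m, ]
    hw <- aggregate(value ~ subject, d[d$workload == "HW", ], mean)$value
    lw <- aggregate(value ~ subject, d[d$workload == "LW", ], mean)$value
    w <- wilcoxon_signed_rank(hw, lw)
    data.frame(measure = m, contrast = "HW-LW", statistic = w$statistic,
               p = w$p, mean_diff = mean(hw - lw))
  }
  mm <- unique(measures$measure)
  contrasts <- do.call(rbind, lapply(mm, contrast_one))
  contrasts$p_adj <- fdr_bh(contrasts$p)$adjusted
  structure(list(measures = measures, contrasts = contrasts),
            class = "behaviour_result")
}
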