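# shared fixture builders; everything is generated in code at test time

fixture_grid <- function(level = 2) source_grid(level)

# small MEG-only cohort for pipeline-level tests
fixture_meg_config <- function(n_subjects = 6, effects = list(), ...) {
  study_config(n_subjects = n_subjects, n_sensors = 24, grid_level = 2,
               block_s = 30, baseline_s = 20, empty_room_s = 30,
               behaviour = FALSE, effects = effects, ...)
}

# balanced 4-class epochs with no class-dependent structure
fixture_null_epochs <- function(n_per_class = 40, n_ch = 24, n_samp = 100,
                                seed = 1) {
  n_ep <- 4 * n_per_class
  dat <- oscidual:::with_seed(seed,
    array(rnorm(n_ep * n_ch * n_samp), c(n_ep, n_ch, n_samp)))
  list(epochs = epoch_set(dat, fs = 50),
       labels = rep(c("a", "b", "c", "d"), each = n_per_class))
}

# 4-class epochs whose classes modulate the variance of latent sources
fixture_separable_epochs <- function(n_per_class = 40, n_ch = 24,
                                     n_samp = 100, gain = 6, noise = 0.5,
                                     seed = 1) {
  n_ep <- 4 * n_per_class
  labels <- rep(1:4, each = n_per_class)
  dat <- oscidual:::with_seed(seed, {
    mix <- matrix(rnorm(n_ch * 4), n_ch, 4)
    d <- array(0, c(n_ep, n_ch, n_samp))
    for (i in seq_len(n_ep)) {
      s <- matrix(rnorm(4 * n_samp), 4, n_samp)
      s[labels[i], ] <- s[labels[i], ] * gain
      d[i, , ] <- mix %*% s + matrix(rnorm(n_ch * n_samp) * noise,
                                     n_ch, n_samp)
    }
    d
  })
  list(epochs = epoch_set(dat, fs = 50),
       labels = paste0("c", labels))
}

# brute-force two-factor within-subject ANOVA via explicit loops
brute_force_rm_anova <- function(y) {
  # y: subjects x 6 x 1 slice as subjects x cells matrix
  n <- nrow(y)
  a_of <- rep(1:2, each = 3); b_of <- rep(1:3, 2)
  m <- mean(y)
  m_s <- rowMeans(y)
  m_a <- sapply(1:2, function(i) mean(y[, a_of == i]))
  m_b <- sapply(1:3, function(j) mean(y[, b_of == j]))
  m_ab <- outer(1:2, 1:3, Vectorize(function(i, j)
    mean(y[, a_of == i & b_of == j])))
  m_as <- sapply(1:2, function(i) rowMeans(y[, a_of == i]))
  m_bs <- sapply(1:3, function(j) rowMeans(y[, b_of == j]))
  ss_a <- 3 * n * sum((m_a - m)^2)
  ss_b <- 2 * n * sum((m_b - m)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, 3)) -
                      outer(rep(1, 2), m_b) + m)^2)
  ss_as <- 3 * sum((m_as - outer(m_s, rep(1, 2)) -
                      outer(rep(1, n), m_a) + m)^2)
  ss_bs <- 2 * sum((m_bs - outer(m_s, rep(1, 3)) -
                      outer(rep(1, n), m_b) + m)^2)
  ss_abs <- 0
  for (s in 1:n) for (c in 1:6) {
    i <- a_of[c]; j <- b_of[c]
    ss_abs <- ss_abs + (y[s, c] - m_ab[i, j] - m_as[s, i] - m_bs[s, j] +
                          m_a[i] + m_b[j] + m_s[s] - m)^2
  }
  c(main_workload = (ss_a / 1) / (ss_as / (n - 1)),
    main_valence = (ss_b / 2) / (ss_bs / (2 * (n - 1))),
    interaction = (ss_ab / 2) / (ss_abs / (2 * (n - 1))))
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
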