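test_that("multiclass CSP recovers class-discriminative latent sources", {
  fx <- fixture_separable_epochs(n_per_class = 30, seed = 1)
  csp <- fit_multiclass_csp(fx$epochs, fx$labels, n_components = 4)
  expect_identical(dim(csp$filters), c(4L, 24L))
  feats <- csp_features(fx$epochs, csp)
  lda <- lda_fit(feats, fx$labels)
  acc <- mean(lda_predict(lda, feats) == fx$labels)
  expect_gt(acc, 0.95)
})

test_that("CSP component scores vanish for identical class distributions", {
  fx <- fixture_null_epochs(n_per_class = 30, seed = 2)
  csp <- fit_multiclass_csp(fx$epochs, fx$labels, n_components = 4)
  # projected log-variance dispersion across classes stays tiny
  expect_lt(max(csp$scores), 0.05)
})

test_that("permuting class labels leaves the CSP filter set unchanged", {
  fx <- fixture_separable_epochs(n_per_class = 20, seed = 3)
  csp1 <- fit_multiclass_csp(fx$epochs, fx$labels, n_components = 4)
  relab <- c(c1 = "c3", c2 = "c4", c3 = "c1", c4 = "c2")[fx$labels]
  csp2 <- fit_multiclass_csp(fx$epochs, relab, n_components = 4)
  # same span: each filter of model 1 matches one of model 2 up to sign
  match_corr <- apply(csp1$filters, 1, function(w)
    max(abs(cor(w, t(csp2$filters)))))
  expect_true(all(match_corr > 0.999))
})

test_that("CSP features obey the log-variance scaling law", {
  fx <- fixture_null_epochs(n_per_class = 10, seed = 4)
  csp <- fit_multiclass_csp(fx$epochs, fx$labels, n_components = 3)
  f1 <- csp_features(fx$epochs, csp)
  doubled <- fx$epochs; doubled$data <- doubled$data * 2
  f2 <- csp_features(doubled, csp)
  expect_equal(f2 - f1, matrix(log(4), nrow(f1), ncol(f1)),
               tolerance = 1e-10)
  const <- epoch_set(array(1, c(1, 24, 100)), 50)
  expect_error(csp_features(const, csp), "zero-variance")
})

test_that("LDA separates Gaussians and matches the Fisher direction", {
  set.seed(5)
  n <- 300
  x <- rbind(matrix(rnorm(n * 2), ncol = 2),
             sweep(matrix(rnorm(n * 2), ncol = 2), 2, c(4, 2), `+`))
  lab <- rep(c("a", "b"), each = n)
  m <- lda_fit(x, lab)
  expect_gt(mean(lda_predict(m, x) == lab), 0.95)
  fisher <- solve(cov(x[lab == "a", ]) / 2 + cov(x[lab == "b", ]) / 2,
                  colMeans(x[lab == "b", ]) - colMeans(x[lab == "a", ]))
  w <- m$weights["b", ] - m$weights["a", ]
  angle <- acos(abs(sum(w * fisher)) /
                  sqrt(sum(w^2) * sum(fisher^2))) * 180 / pi
  expect_lt(angle, 5)
  expect_error(lda_fit(x, rep("a", 2 * n)), "single class")
})

test_that("cross-validation bookkeeping produces k x repeats partitions", {
  fx <- fixture_null_epochs(n_per_class = 20, n_ch = 8, n_samp = 50,
                            seed = 6)
  dec <- crossval_decode(fx$epochs, fx$labels, k = 10, repeats = 3,
                         n_boot = 200, seed = 7)
  expect_identical(dec$n_folds, 30L)
  expect_length(dec$fold_f1, 30L)
  # pooled confusion: every epoch tested once per repeat
  expect_equal(sum(dec$confusion), 3 * 80)
  expect_equal(unname(rowSums(dec$confusion)), rep(60, 4))
  expect_error(crossval_decode(fx$epochs, fx$labels, k = 30), "reduce")
})

test_that("decoding is deterministic per seed and near chance under the null", {
  fx <- fixture_null_epochs(n_per_class = 20, n_ch = 12, n_samp = 60,
                            seed = 8)
  d1 <- crossval_decode(fx$epochs, fx$labels, k = 5, repeats = 1,
                        n_boot = 100, seed = 9)
  d2 <- crossval_decode(fx$epochs, fx$labels, k = 5, repeats = 1,
                        n_boot = 100, seed = 9)
  expect_identical(d1$fold_f1, d2$fold_f1)
  expect_identical(d1$confusion, d2$confusion)
  expect_gt(d1$mean_f1, 0.05)
  expect_lt(d1$mean_f1, 0.45)
})

test_that("strongly separable data decode nearly perfectly", {
  fx <- fixture_separable_epochs(n_per_class = 20, seed = 10)
  dec <- crossval_decode(fx$epochs, fx$labels, k = 5, repeats = 1,
                         n_boot = 100, seed = 11)
  expect_gt(dec$mean_f1, 0.9)
})

test_that("Haufe patterns recover mixing vectors and closed forms", {
  set.seed(12)
  n_ch <- 16; a <- rnorm(n_ch)
  dat <- array(0, c(60, n_ch, 80))
  lab <- rep(c("x", "y"), each = 30)
  for (i in 1:60) {
    s <- rnorm(80) * if (lab[i] == "x") 3 else 1
    dat[i, , ] <- a %o% s + matrix(rnorm(n_ch * 80) * 0.3, n_ch, 80)
  }
  ep <- epoch_set(dat, 50)
  csp <- fit_multiclass_csp(ep, lab, n_components = 2)
  pat <- haufe_patterns(csp, ledoit_wolf_cov(ep)$sigma)
  expect_gt(max(abs(cor(pat, a))), 0.9)
  # W orthonormal, Sigma = I: A = W'
  w <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:2]
  expect_equal(haufe_patterns(t(w), diag(5)), w, tolerance = 1e-12)
  # invariance to filter rescaling (up to column scale)
  sigma <- crossprod(matrix(rnorm(100), 20, 5)) / 20 + diag(5)
  wf <- matrix(rnorm(10), 2, 5)
  a1 <- haufe_patterns(wf, sigma)
  a2 <- haufe_patterns(diag(c(2, 5)) %*% wf, sigma)
  expect_gt(min(abs(diag(cor(a1, a2)))), 1 - 1e-10)
})

test_that("pattern localization peaks at the generating vertex", {
  sm <- build_source_model(32, 2, seed = 13)
  inv <- minimum_norm_operator(sm$gain, sm$noise_cov, snr = 3,
                               depth_exponent = 0.8)
  v <- 77L
  pm <- localize_patterns(cbind(sm$gain[, v], 0 * sm$gain[, 1]), inv)
  expect_true(which.max(pm$values[, 1]) %in% c(v, sm$grid$adjacency[[v]]))
  expect_identical(max(pm$values[, 2]), 0)
  expect_error(localize_patterns(matrix(0, 5, 1), inv), "channel")
})

test_that("F1-weighted grand average normalizes and rescales correctly", {
  maps <- list(matrix(1:6, 3), matrix(c(2, 0, 4, 6, 1, 3), 3))
  ga <- weighted_grand_average(maps, c(0.5, 0.5))
  plain <- (maps[[1]] + maps[[2]]) / 2
  expect_equal(ga$values,
               (plain - min(plain)) / diff(range(plain)))
  expect_equal(sum(ga$weights), 1)
  # degenerate weights: single subject dominates
  ga2 <- weighted_grand_average(maps, c(1, 0))
  m1 <- maps[[1]]
  expect_equal(ga2$values, (m1 - min(m1)) / diff(range(m1)))
  expect_error(weighted_grand_average(list(matrix(1, 2, 2),
                                           matrix(1, 2, 2)), c(1, 1)),
               "constant")
})

test_that("percentile ROI contrast selects the top vertices and tests pairs", {
  set.seed(14)
  nv <- 50
  pattern <- runif(nv)
  pow <- array(rnorm(8 * 4 * nv), c(8, 4, nv),
               dimnames = list(NULL, c("LW/LV", "LW/HV", "HW/LV", "HW/HV"),
                               NULL))
  rc <- percentile_roi_contrast(pattern, pow, q = 90, seed = 1)
  expect_identical(length(rc$roi), sum(pattern > quantile(pattern, 0.9)))
  expect_identical(nrow(rc$contrasts), 6L)
  # q = 0: ROI is everything, means equal global means
  rc0 <- percentile_roi_contrast(pattern, pow, q = 0, seed = 1)
  expect_equal(length(rc0$roi), nv)
  expect_equal(rc0$roi_means[, 1],
               rowMeans(pow[, 1, ]), tolerance = 1e-12)
  # uniform map: error by default, full-vertex fallback on request
  expect_error(percentile_roi_contrast(rep(1, nv), pow, q = 90),
               "ill-defined")
  rcu <- percentile_roi_contrast(rep(1, nv), pow, q = 90,
                                 uniform = "all", seed = 1)
  expect_equal(length(rcu$roi), nv)
})
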