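test_that("rmANOVA F maps match brute-force and aov oracles", {
  set.seed(1)
  n <- 8; nv <- 4
  y <- array(rnorm(n * 6 * nv), c(n, 6, nv))
  res <- rm_anova_F(y)
  ct <- condition_table()
  for (v in seq_len(nv)) {
    bf <- brute_force_rm_anova(y[, , v])
    expect_equal(unname(res$F[, v]), unname(bf), tolerance = 1e-8)
    df <- data.frame(y = as.numeric(y[, , v]),
                     s = factor(rep(1:n, 6)),
                     w = factor(rep(ct$workload, each = n)),
                     a = factor(rep(ct$valence, each = n)))
    fit <- summary(aov(y ~ w * a + Error(s / (w * a)), data = df))
    expect_equal(unname(res$F["main_workload", v]),
                 fit[["Error: s:w"]][[1]]["w", "F value"], tolerance = 1e-8)
    expect_equal(unname(res$F["main_valence", v]),
                 fit[["Error: s:a"]][[1]]["a", "F value"], tolerance = 1e-8)
    expect_equal(unname(res$F["interaction", v]),
                 fit[["Error: s:w:a"]][[1]]["w:a", "F value"],
                 tolerance = 1e-8)
  }
})

test_that("rmANOVA degenerate inputs behave as contracted", {
  # identical data in every condition: F ~ 0 everywhere
  y <- array(rep(rnorm(5), 6 * 3), c(5, 6, 3))
  r <- rm_anova_F(y)
  expect_lt(max(r$F[is.finite(r$F)], 0), 1e-10)
  # additive subject offsets only: absorbed by the subject term
  y2 <- array(0, c(6, 6, 2))
  offs <- rnorm(6)
  for (s in 1:6) y2[s, , ] <- offs[s]
  y2 <- y2 + array(rnorm(length(y2), sd = 1e-8), dim(y2))
  r2 <- rm_anova_F(y2)
  expect_lt(max(r2$F), 10)   # no systematic effect despite huge offsets
  expect_error(rm_anova_F(array(0, c(2, 6, 1))), "3 subjects")
})

test_that("spatial clustering equals an igraph components oracle", {
  g <- fixture_grid(2)
  set.seed(3)
  for (rep_i in 1:5) {
    f <- rexp(g$n_vertices)
    thr <- quantile(f, 0.8)
    cl <- spatial_clusters(f, g$adjacency, thr)
    supra <- which(f > thr)
    ig <- igraph::graph_from_adj_list(g$adjacency, mode = "all")
    sub <- igraph::induced_subgraph(ig, supra)
    comp <- igraph::components(sub)
    expect_equal(length(cl), comp$no)
    oracle_masses <- sort(vapply(seq_len(comp$no), function(k)
      sum(f[supra[comp$membership == k]]), 0), decreasing = TRUE)
    expect_equal(vapply(cl, `[[`, 0, "mass"), oracle_masses,
                 tolerance = 1e-12)
  }
  # hand cases
  f0 <- rep(0, g$n_vertices); f0[5] <- 10
  expect_identical(spatial_clusters(f0, g$adjacency, 1)[[1]]$vertices, 5L)
  f2 <- rep(0, g$n_vertices); f2[c(5, 150)] <- 10
  expect_identical(length(spatial_clusters(f2, g$adjacency, 1)), 2L)
  expect_identical(length(spatial_clusters(rep(0, g$n_vertices),
                                           g$adjacency, 1)), 0L)
})

test_that("permutation cluster test finds planted effects, not null ones", {
  g <- fixture_grid(2)
  ds0 <- simulate_factorial_dataset(g, n_subjects = 12, seed = 10)
  r0 <- permutation_cluster_test(ds0, "main_valence", n_perm = 200,
                                 seed = 11)
  expect_true(all(vapply(r0$clusters, `[[`, 0, "p") > 0))
  patch <- oscidual:::grid_neighbourhood(g, 40, 1)
  ds1 <- simulate_factorial_dataset(
    g, n_subjects = 12,
    effects = list(planted_shift("workload", patch, 1)), seed = 12)
  r1 <- permutation_cluster_test(ds1, "main_workload", n_perm = 200,
                                 seed = 13)
  sig <- Filter(function(cl) cl$significant, r1$clusters)
  expect_gt(length(sig), 0)
  expect_gt(length(intersect(sig[[1]]$vertices, patch)), 0)
  # identical data in all conditions: no suprathreshold vertices
  yk <- array(rep(rnorm(12 * 162), each = 1), c(12, 6, 162))
  for (ci in 2:6) yk[, ci, ] <- yk[, 1, ]
  rk <- permutation_cluster_test(factorial_dataset(yk, g), "interaction",
                                 n_perm = 100, seed = 14)
  expect_identical(length(rk$clusters), 0L)
  expect_warning(permutation_cluster_test(ds0, "interaction", n_perm = 50,
                                          seed = 1), "coarse")
})

test_that("restricted permutation scheme is also valid on planted data", {
  g <- fixture_grid(2)
  patch <- oscidual:::grid_neighbourhood(g, 40, 1)
  ds <- simulate_factorial_dataset(
    g, n_subjects = 12,
    effects = list(planted_shift("workload", patch, 1)), seed = 21)
  r <- permutation_cluster_test(ds, "main_workload", n_perm = 200,
                                scheme = "factor", seed = 22)
  sig <- Filter(function(cl) cl$significant, r$clusters)
  expect_gt(length(sig), 0)
})

test_that("Wilcoxon signed-rank matches its exact and approximate oracles", {
  # n = 5, all positive: one-sided p = 1/32 by sign-pattern enumeration
  w <- wilcoxon_signed_rank(2:6, rep(0, 5), "greater")
  expect_equal(w$p, 1 / 32)
  expect_identical(w$method, "exact")
  # agreement with stats::wilcox.test where both are defined
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }
  # large-n normal approximation against wilcox.test(correct = TRUE)
  set.seed(6)
  x <- rnorm(40); y <- rnorm(40)
  ours <- wilcoxon_signed_rank(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # degenerate and symmetric inputs
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "degenerate")
  d <- c(3, -3, 2, -2, 1.5, -1.5)
  ws <- wilcoxon_signed_rank(d, rep(0, 6))
  expect_gt(ws$p, 0.9)
})

test_that("BH-FDR equals the brute-force step-up definition", {
  brute_bh <- function(p, alpha) {
    m <- length(p); o <- order(p)
    ok <- which(p[o] <= seq_len(m) * alpha / m)
    rej <- logical(m)
    if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
    rej
  }
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.5))
  expect_identical(r$rejected, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdr_bh(rep(1, 5))$rejected, rep(FALSE, 5))
  expect_identical(fdr_bh(0.04)$rejected, TRUE)
  set.seed(8)
  for (n in 1:8) {
    for (rep_i in 1:25) {
      p <- round(runif(n), 3)
      expect_identical(fdr_bh(p)$rejected, brute_bh(p, 0.05))
    }
  }
})

test_that("bootstrap CI behaves at the degenerate and nested cases", {
  b <- bootstrap_mean_ci(rep(2.5, 10), n_iter = 200, seed = 1)
  expect_equal(c(b$mean, b$lower, b$upper), rep(2.5, 3))
  set.seed(2)
  v <- rnorm(30)
  b1 <- bootstrap_mean_ci(v, n_iter = 2000, seed = 3)
  b2 <- bootstrap_mean_ci(v, n_iter = 2000, bonferroni_m = 2, seed = 3)
  expect_lte(b2$lower, b1$lower)
  expect_gte(b2$upper, b1$upper)
  expect_error(bootstrap_mean_ci(c(1, 2)), "3 values")
})

test_that("bootstrap CI coverage is near nominal", {
  set.seed(4)
  cover <- vapply(1:200, function(i) {
    v <- rnorm(40)
    b <- bootstrap_mean_ci(v, n_iter = 400, seed = i)
    b$lower <= 0 && b$upper >= 0
  }, TRUE)
  expect_gt(mean(cover), 0.88)
})

test_that("Spearman correlation is rank-invariant with sane p-values", {
  x <- c(0.3, 1.8, 2.2, 3.9, 5.1, 6.4)
  expect_equal(spearman_corr(x, x)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  expect_equal(spearman_corr(x, x^3)$rho, 1)
  set.seed(9)
  a <- rnorm(30); b <- a + rnorm(30)
  ours <- spearman_corr(a, b)
  ref <- suppressWarnings(cor.test(a, b, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 6), x), "constant")
})
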