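#' Factorial source-power dataset
#'
#' Container for per-subject, per-condition, per-vertex power (typically
#' baseline-relative change) under the 2 x 3 within-subject design.
#'
#' @param power numeric array subjects x 6 conditions x vertices; the
#'   condition order is that of [condition_table()].
#' @param grid optional `source_grid` supplying the adjacency.
#' @return object of class `factorial_dataset`.
#' @export
factorial_dataset <- function(power, grid = NULL) {
  stopifnot(length(dim(power)) == 3L)
  if (dim(power)[2] != 6L) stop("need exactly 6 conditions (2 x 3 design)")
  if (any(!is.finite(power))) stop("missing cells are not allowed")
  structure(list(power = power, design = condition_table(), grid = grid),
            class = "factorial_dataset")
}

#' @export
print.factorial_dataset <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<factorial_dataset> %d subjects x 6 conditions x %d vertices\n",
              d[1], d[3]))
  invisible(x)
}

# degrees of freedom of the three within-subject effects
rm_anova_dfs <- function(n_subjects) {
  list(main_workload = c(1, n_subjects - 1),
       main_valence = c(2, 2 * (n_subjects - 1)),
       interaction = c(2, 2 * (n_subjects - 1)))
}

#' Per-vertex repeated-measures two-factor ANOVA F maps
#'
#' Classical within-subject sums-of-squares decomposition of the 2
#' (workload) x 3 (valence) design, computed for every vertex at once.
#' Each effect's F is its mean square over the corresponding
#' effect-by-subject interaction mean square.
#'
#' @param dataset a `factorial_dataset` (or bare subjects x 6 x vertices
#'   array).
#' @return list with `F` (3 x vertices matrix, rows `main_workload`,
#'   `main_valence`, `interaction`), `dfs`, and `zero_error` (logical
#'   3 x vertices flag where the error variance vanished and F was set to
#'   +Inf).
#' @export
rm_anova_F <- function(dataset) {
  y <- if (inherits(dataset, "factorial_dataset")) dataset$power else dataset
  d <- dim(y); n <- d[1]; nv <- d[3]
  if (n < 3) stop("need at least 3 subjects")
  x <- matrix(y, n * 6L, nv)              # row = subject + (cell-1)*n
  s_idx <- rep(seq_len(n), 6L)
  c_idx <- rep(seq_len(6L), each = n)
  a_of_c <- rep(1:2, each = 3L)           # workload level per cell
  b_of_c <- rep(1:3, times = 2L)          # valence level per cell
  a_idx <- a_of_c[c_idx]
  b_idx <- b_of_c[c_idx]
  sa_idx <- (a_idx - 1L) * n + s_idx
  sb_idx <- (b_idx - 1L) * n + s_idx

  m <- colMeans(x)
  m_s <- rowsum(x, s_idx) / 6
  m_c <- rowsum(x, c_idx) / n
  m_a <- rowsum(x, a_idx) / (3 * n)
  m_b <- rowsum(x, b_idx) / (2 * n)
  m_sa <- rowsum(x, sa_idx) / 3
  m_sb <- rowsum(x, sb_idx) / 2

  ctr <- function(mat) sweep(mat, 2, m)
  ss_a <- 3 * n * colSums(ctr(m_a)^2)
  ss_b <- 2 * n * colSums(ctr(m_b)^2)
  ss_as <- 3 * colSums((m_sa - m_a[rep(1:2, each = n), , drop = FALSE] -
                          m_s[rep(seq_len(n), 2L), , drop = FALSE] +
                          rep(1, 2 * n) %o% m)^2)
  ss_bs <- 2 * colSums((m_sb - m_b[rep(1:3, each = n), , drop = FALSE] -
                          m_s[rep(seq_len(n), 3L), , drop = FALSE] +
                          rep(1, 3 * n) %o% m)^2)
  ss_ab <- n * colSums((m_c - m_a[a_of_c, , drop = FALSE] -
                          m_b[b_of_c, , drop = FALSE] +
                          rep(1, 6) %o% m)^2)
  resid <- x - m_c[c_idx, , drop = FALSE] - m_sa[sa_idx, , drop = FALSE] -
    m_sb[sb_idx, , drop = FALSE] + m_a[a_idx, , drop = FALSE] +
    m_b[b_idx, , drop = FALSE] + m_s[s_idx, , drop = FALSE] -
    rep(1, 6 * n) %o% m
  ss_abs <- colSums(resid^2)

  dfs <- rm_anova_dfs(n)
  f <- rbind(
    main_workload = (ss_a / dfs$main_workload[1]) /
      (ss_as / dfs$main_workload[2]),
    main_valence = (ss_b / dfs$main_valence[1]) /
      (ss_bs / dfs$main_valence[2]),
    interaction = (ss_ab / dfs$interaction[1]) /
      (ss_abs / dfs$interaction[2]))
  err <- rbind(main_workload = ss_as, main_valence = ss_bs,
               interaction = ss_abs)
  eff_ss <- rbind(ss_a, ss_b, ss_ab)
  # relative tolerance: exact ties across conditions leave only float dust
  tol <- matrix(1e-20 * (colSums(x^2) + .Machine$double.xmin),
                3, nv, byrow = TRUE)
  zero_error <- err < tol
  f[zero_error & eff_ss >= tol] <- Inf
  f[zero_error & eff_ss < tol] <- 0
  list(F = f, dfs = dfs, zero_error = zero_error)
}

#' Connected suprathreshold clusters of a statistic map
#'
#' Connected components of the suprathreshold vertex set under the grid
#' adjacency; cluster mass is the sum of the statistic inside a component.
#'
#' @param stat_map per-vertex statistic values.
#' @param adjacency neighbour list (one integer vector per vertex), e.g.
#'   `grid$adjacency`.
#' @param threshold cluster-forming threshold (>= 0); vertices with
#'   `stat > threshold` enter clusters.
#' @return list of clusters, each with `vertices` and `mass`, ordered by
#'   decreasing mass.
#' @export
spatial_clusters <- function(stat_map, adjacency, threshold) {
  if (threshold < 0) stop("`threshold` must be >= 0")
  supra <- which(stat_map > threshold)
  if (!length(supra)) return(list())
  in_set <- logical(length(stat_map))
  in_set[supra] <- TRUE
  visited <- logical(length(stat_map))
  clusters <- list()
  for (v0 in supra) {
    if (visited[v0]) next
    comp <- integer(0)
    stack <- v0
    visited[v0] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- adjacency[[v]]
      nb <- nb[in_set[nb] & !visited[nb]]
      visited[nb] <- TRUE
      stack <- c(stack, nb)
    }
    clusters[[length(clusters) + 1L]] <-
      list(vertices = sort(comp), mass = sum(stat_map[comp]))
  }
  clusters[order(-vapply(clusters, `[[`, 0, "mass"))]
}

# per-subject cell-label permutation index (rows of the n*6 data matrix)
permute_rows <- function(n, scheme, effect) {
  perm6 <- matrix(0L, n, 6L)
  if (scheme == "full") {
    for (s in seq_len(n)) perm6[s, ] <- sample.int(6L)
  } else {
    # restricted: permute only the tested factor's levels within the other
    a_of_c <- rep(1:2, each = 3L); b_of_c <- rep(1:3, times = 2L)
    for (s in seq_len(n)) {
      p <- seq_len(6L)
      if (effect == "main_workload") {
        swap <- sample(c(TRUE, FALSE), 3L, replace = TRUE)
        for (j in 1:3) if (swap[j]) {
          cells <- which(b_of_c == j)
          p[cells] <- rev(p[cells])
        }
      } else {
        for (i in 1:2) {
          cells <- which(a_of_c == i)
          p[cells] <- cells[sample.int(3L)]
        }
      }
      perm6[s, ] <- p
    }
  }
  # row index: subject s, new cell c takes data from old cell perm6[s, c]
  idx <- integer(n * 6L)
  for (c in 1:6) idx[(c - 1L) * n + seq_len(n)] <-
      (perm6[, c] - 1L) * n + seq_len(n)
  idx
}

#' Cluster-based permutation test for a factorial effect
#'
#' The observed F map of the requested effect is thresholded at the
#' parametric F quantile (`1 - cluster_alpha` at the effect's degrees of
#' freedom), suprathreshold vertices are clustered by adjacency, and each
#' observed cluster mass is compared against the permutation null of
#' maximum cluster masses obtained by re-labelling the six condition cells
#' within each subject (full 6-cell shuffles by default, one-sided on
#' large F).
#'
#' @param dataset a `factorial_dataset` with a grid (or pass `adjacency`).
#' @param effect `"main_workload"`, `"main_valence"` or `"interaction"`.
#' @param n_perm number of permutations.
#' @param cluster_alpha per-vertex cluster-forming alpha.
#' @param test_alpha cluster significance level.
#' @param scheme `"full"` (default) or `"factor"` (restricted shuffles of
#'   the tested factor's levels).
#' @param adjacency optional neighbour list overriding `dataset$grid`.
#' @param seed integer seed.
#' @return object of class `cluster_result`: `effect`, `threshold`,
#'   `clusters` (vertices, mass, p), `n_perm`, `max_null` (the null
#'   distribution), `seed`.
#' @export
permutation_cluster_test <- function(dataset, effect, n_perm = 5000,
                                     cluster_alpha = 0.05,
                                     test_alpha = 0.05,
                                     scheme = c("full", "factor"),
                                     adjacency = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  effect <- match.arg(effect,
                      c("main_workload", "main_valence", "interaction"))
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")
  if (is.null(adjacency)) {
    if (is.null(dataset$grid)) stop("no adjacency available")
    adjacency <- dataset$grid$adjacency
  }
  y <- dataset$power
  d <- dim(y); n <- d[1]; nv <- d[3]
  dfs <- rm_anova_dfs(n)[[effect]]
  threshold <- qf(1 - cluster_alpha, dfs[1], dfs[2])

  obs_f <- rm_anova_F(dataset)$F[effect, ]
  obs_clusters <- spatial_clusters(obs_f, adjacency, threshold)

  x <- matrix(y, n * 6L, nv)
  max_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- permute_rows(n, scheme, effect)
    yp <- array(x[idx, , drop = FALSE], dim = d)
    fp <- rm_anova_F(yp)$F[effect, ]
    cl <- spatial_clusters(fp, adjacency, threshold)
    if (length(cl)) cl[[1]]$mass else 0
  }, 0))

  clusters <- lapply(obs_clusters, function(cl) {
    cl$p <- (1 + sum(max_null >= cl$mass)) / (1 + n_perm)
    cl$significant <- cl$p < test_alpha
    cl
  })
  structure(list(effect = effect, threshold = threshold,
                 clusters = clusters, n_perm = n_perm,
                 max_null = max_null, cluster_alpha = cluster_alpha,
                 test_alpha = test_alpha, scheme = scheme, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> effect %s: %d cluster(s), threshold F=%.2f\n",
              x$effect, length(x$clusters), x$threshold))
  for (cl in x$clusters)
    cat(sprintf("  %d vertices, mass %.1f, p = %.4f%s\n",
                length(cl$vertices), cl$mass, cl$p,
                if (cl$significant) " *" else ""))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped, absolute differences mid-ranked; the
#' exact null distribution is used for n <= 12 without ties, otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y paired numeric vectors.
#' @param alternative `"two_sided"`, `"greater"` (x > y) or `"less"`.
#' @return list with `statistic` (V, sum of positive-difference ranks),
#'   `p`, `n` (pairs used), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y,
                                 alternative = c("two_sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate pairs: all differences are zero")
  if (n < 5) stop("need at least 5 non-zero pairs")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 12 && !ties) {
    p <- switch(alternative,
      greater = stats::psignrank(v - 1, n, lower.tail = FALSE),
      less = stats::psignrank(v, n),
      two_sided = {
        if (v > n * (n + 1) / 4)
          min(1, 2 * stats::psignrank(v - 1, n, lower.tail = FALSE))
        else min(1, 2 * stats::psignrank(v, n))
      })
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z_num <- v - mu
    cc <- switch(alternative, two_sided = sign(z_num) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z_num - cc) / sqrt(sigma2)
    p <- switch(alternative,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two_sided = 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE)))
    p <- min(1, p)
    method <- "normal approximation"
  }
  list(statistic = v, p = p, n = n, method = method)
}

#' Benjamini--Hochberg FDR correction
#'
#' Step-up procedure; adjusted p-values via [stats::p.adjust()].
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return list with `rejected` (logical mask) and `adjusted` p-values.
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- p.adjust(p_values, method = "BH")
  list(rejected = adj <= alpha & !is.na(adj), adjusted = adj)
}

#' Percentile bootstrap mean and confidence interval
#'
#' Resamples the input values (subjects) with replacement; interval
#' percentiles are Bonferroni-scaled when several intervals are displayed
#' together.
#'
#' @param values numeric vector (n >= 3).
#' @param n_iter bootstrap iterations.
#' @param alpha nominal two-sided level.
#' @param bonferroni_m number of simultaneous intervals.
#' @param seed integer seed.
#' @return list with `mean`, `lower`, `upper`.
#' @export
bootstrap_mean_ci <- function(values, n_iter = 5000, alpha = 0.05,
                              bonferroni_m = 1, seed = 1) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  tail_p <- (alpha / bonferroni_m) / 2
  boots <- with_seed(seed, vapply(seq_len(n_iter), function(i)
    mean(values[sample.int(n, n, replace = TRUE)]), 0))
  qs <- quantile(boots, c(tail_p, 1 - tail_p), names = FALSE)
  list(mean = mean(values), lower = qs[1], upper = qs[2])
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranked data with a t-approximation p-value.
#'
#' @param x,y numeric vectors (n >= 5).
#' @return list with `rho` and `p` (two-sided).
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (n < 5) stop("need at least 5 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input")
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(abs(tt), n - 2, lower.tail = FALSE))
}
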