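# ---- multiclass CSP -------------------------------------------------------

# Ledoit-Wolf covariance of the concatenated epochs of one class
class_covariance <- function(epochs, idx) {
  d <- dim(epochs$data)
  x <- matrix(aperm(epochs$data[idx, , , drop = FALSE], c(3, 1, 2)),
              length(idx) * d[3], d[2])
  ledoit_wolf_cov(x)$sigma
}

#' Fit multiclass common spatial patterns
#'
#' Whitened approximate joint diagonalization: the Ledoit--Wolf class
#' covariances are whitened by the grand-average covariance and jointly
#' diagonalized by Jacobi rotations; components are ranked by the
#' between-class dispersion (variance) of their projected log-variances
#' and the top `n_components` retained.  A one-vs-rest variant is
#' available via `method = "ovr"`.
#'
#' @param epochs an `epoch_set` (band-pass filtered sensor epochs).
#' @param labels class label per epoch (4 classes in the standard design).
#' @param n_components number of spatial filters retained.
#' @param method `"ajd"` (default) or `"ovr"`.
#' @return object of class `csp_model`: `filters` (components x channels),
#'   `scores`, `class_covs`, `classes`.
#' @export
fit_multiclass_csp <- function(epochs, labels, n_components = 4,
                               method = c("ajd", "ovr")) {
  method <- match.arg(method)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  d <- dim(epochs$data)
  for (cl in classes)
    if (sum(labels == cl) < 2 * n_components)
      stop("class '", cl, "' has fewer than 2*n_components epochs")
  covs <- lapply(classes, function(cl)
    class_covariance(epochs, which(labels == cl)))
  c_all <- Reduce(`+`, covs) / length(covs)
  ev <- eigen(c_all, symmetric = TRUE)
  keep <- ev$values > 1e-10 * max(ev$values)
  if (sum(keep) < n_components)
    stop("rank-deficient grand covariance; reduce the channel count")
  p <- diag(1 / sqrt(ev$values[keep]), sum(keep)) %*%
    t(ev$vectors[, keep, drop = FALSE])
  wcovs <- lapply(covs, function(cc) p %*% cc %*% t(p))

  if (method == "ajd") {
    arr <- array(unlist(wcovs), c(nrow(p), nrow(p), length(wcovs)))
    jd <- rjd_cpp(as.numeric(arr), nrow(p), length(wcovs))
    w_all <- t(jd$v) %*% p                 # rotated whitening = all filters
  } else {
    vecs <- lapply(seq_along(classes), function(i) {
      e <- eigen(wcovs[[i]], symmetric = TRUE)
      e$vectors[, c(1, ncol(e$vectors)), drop = FALSE]
    })
    w_all <- t(do.call(cbind, vecs)) %*% p
  }
  # rank by dispersion of projected log-variances across classes
  scores <- apply(w_all, 1, function(w) {
    lv <- vapply(covs, function(cc) log(drop(w %*% cc %*% w)), 0)
    var(lv)
  })
  ord <- order(-scores)
  sel <- ord[seq_len(min(n_components, nrow(w_all)))]
  structure(list(filters = w_all[sel, , drop = FALSE],
                 scores = scores[sel], classes = classes,
                 class_covs = covs, method = method,
                 n_components = length(sel)),
            class = "csp_model")
}

#' Log-variance CSP features
#'
#' Feature = log of the per-epoch variance of each component's projected
#' time course.
#'
#' @param epochs an `epoch_set`.
#' @param model a fitted `csp_model`.
#' @return epochs x components feature matrix.
#' @export
csp_features <- function(epochs, model) {
  d <- dim(epochs$data)
  w <- model$filters
  feats <- matrix(0, d[1], nrow(w))
  for (e in seq_len(d[1])) {
    x <- epochs$data[e, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = d[2])
    v <- apply(w %*% x, 1, var)
    if (any(v <= 0)) stop("zero-variance component projection in epoch ", e)
    feats[e, ] <- log(v)
  }
  feats
}

# ---- regularized LDA ------------------------------------------------------

#' Fit linear discriminant analysis with Ledoit--Wolf covariance
#'
#' Shared within-class covariance estimated with Ledoit--Wolf shrinkage on
#' the class-centred data; discriminant weights from the least-squares
#' (normal-equation) solution `w_k = Sigma^{-1} mu_k`.
#'
#' @param features samples x features matrix.
#' @param labels class per sample (>= 2 classes).
#' @return object of class `lda_model`.
#' @export
lda_fit <- function(features, labels) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training data contain a single class")
  mus <- t(vapply(classes, function(cl)
    colMeans(features[labels == cl, , drop = FALSE]),
    numeric(ncol(features))))
  centred <- features
  for (cl in classes)
    centred[labels == cl, ] <- sweep(features[labels == cl, , drop = FALSE],
                                     2, mus[cl, ])
  sigma <- ledoit_wolf_cov(centred)$sigma
  priors <- as.numeric(table(factor(labels, classes))) / length(labels)
  w <- t(solve(sigma, t(mus)))                     # classes x features
  b <- -0.5 * rowSums(w * mus) + log(priors)
  structure(list(weights = w, bias = b, classes = classes, sigma = sigma,
                 means = mus),
            class = "lda_model")
}

#' Predict classes from a fitted LDA model
#'
#' @param model an `lda_model`.
#' @param features samples x features matrix.
#' @return character vector of predicted class labels.
#' @export
lda_predict <- function(model, features) {
  scores <- features %*% t(model$weights) +
    matrix(model$bias, nrow(features), length(model$bias), byrow = TRUE)
  model$classes[max.col(scores, ties.method = "first")]
}

# ---- cross-validated decoding --------------------------------------------

macro_f1 <- function(truth, pred, classes) {
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  mean(f1)
}

# stratified fold assignment: per class, shuffled indices dealt round-robin
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

#' Repeated stratified cross-validated CSP+LDA decoding
#'
#' Stratified k-fold cross-validation with `repeats` repetitions
#' (`k * repeats` train/test partitions).  CSP and LDA are fitted on
#' training folds only; evaluation uses the macro-averaged F1 score, a
#' pooled confusion matrix, and a percentile bootstrap CI over the fold
#' scores.  Haufe activation patterns are derived per fold from the
#' training-data Ledoit--Wolf sensor covariance and averaged across folds.
#'
#' @param epochs an `epoch_set`.
#' @param labels class label per epoch; every class needs at least `k`
#'   epochs.
#' @param k folds per repetition.
#' @param repeats repetitions.
#' @param n_components CSP components.
#' @param n_boot bootstrap iterations for the F1 CI.
#' @param seed integer seed (fold assignment and bootstrap).
#' @return object of class `decoding_result`: `fold_f1`, `mean_f1`, `ci`,
#'   `confusion` (classes x classes counts, rows = truth), `patterns`
#'   (channels x components, fold-averaged), `filters`, `n_folds`, `seed`.
#' @export
crossval_decode <- function(epochs, labels, k = 10, repeats = 3,
                            n_components = 4, n_boot = 5000, seed = 1) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < k))
    stop("smallest class has ", min(counts),
         " epochs; reduce `k` to at most that")
  fold_f1 <- numeric(0)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(truth = classes, pred = classes))
  pattern_acc <- NULL
  filters_last <- NULL
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      fold <- stratified_folds(labels, k)
      for (fi in seq_len(k)) {
        tr <- which(fold != fi); te <- which(fold == fi)
        ep_tr <- subset_epochs(epochs, tr)
        csp <- fit_multiclass_csp(ep_tr, labels[tr], n_components)
        f_tr <- csp_features(ep_tr, csp)
        lda <- lda_fit(f_tr, labels[tr])
        f_te <- csp_features(subset_epochs(epochs, te), csp)
        pred <- lda_predict(lda, f_te)
        fold_f1 <- c(fold_f1, macro_f1(labels[te], pred, classes))
        for (i in seq_along(te))
          confusion[labels[te[i]], pred[i]] <-
            confusion[labels[te[i]], pred[i]] + 1L
        sigma_tr <- ledoit_wolf_cov(ep_tr)$sigma
        pat <- haufe_patterns(csp, sigma_tr)
        pattern_acc <- if (is.null(pattern_acc)) pat else pattern_acc + pat
        filters_last <- csp$filters
      }
    }
  })
  n_folds <- as.integer(k) * as.integer(repeats)
  ci <- bootstrap_mean_ci(fold_f1, n_iter = n_boot,
                          seed = derive_seeds(seed, 1))
  structure(list(fold_f1 = fold_f1, mean_f1 = mean(fold_f1),
                 ci = c(lower = ci$lower, upper = ci$upper),
                 confusion = confusion,
                 patterns = pattern_acc / n_folds,
                 filters = filters_last, n_folds = n_folds,
                 classes = classes, k = k, repeats = repeats, seed = seed),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d folds, mean macro F1 %.3f [%.3f, %.3f]\n",
              x$n_folds, x$mean_f1, x$ci["lower"], x$ci["upper"]))
  invisible(x)
}

#' Haufe forward-model transformation of extraction filters
#'
#' Converts backward (extraction) filters into interpretable activation
#' patterns: `A = Sigma W' (W Sigma W')^{-1}` for filters `W`
#' (components x channels) and data covariance `Sigma`.
#'
#' @param filters a `csp_model` or a components x channels matrix.
#' @param data_covariance channels x channels covariance of the (training)
#'   data.
#' @return channels x components pattern matrix.
#' @export
haufe_patterns <- function(filters, data_covariance) {
  w <- if (inherits(filters, "csp_model")) filters$filters else filters
  gram <- w %*% data_covariance %*% t(w)
  inv <- tryCatch(solve(gram), error = function(e)
    stop("singular filter Gram matrix W Sigma W'"))
  data_covariance %*% t(w) %*% inv
}

#' Localize sensor patterns in source space
#'
#' Applies a minimum-norm inverse operator to each sensor pattern vector
#' and stores the per-vertex magnitude.
#'
#' @param patterns channels x components matrix.
#' @param inverse_op an `inverse_operator` (built at the pattern SNR,
#'   conventionally 3).
#' @return object of class `pattern_map`: `values` (vertices x
#'   components, magnitudes), `normalization`.
#' @export
localize_patterns <- function(patterns, inverse_op) {
  if (nrow(patterns) != ncol(inverse_op$whitener$w))
    stop("pattern channel dimension does not match the inverse operator")
  maps <- abs(apply_inverse(inverse_op, patterns))
  structure(list(values = maps, normalization = "raw"),
            class = "pattern_map")
}

#' F1-weighted grand average of subject pattern maps
#'
#' Weighted mean with weights `f1 / sum(f1)`, then min-max rescaled to
#' `[0, 1]`.
#'
#' @param maps_by_subject list of `pattern_map` (or vertex matrices) with
#'   identical dimensions.
#' @param f1_by_subject decoding F1 per subject (non-negative).
#' @return a `pattern_map` with `normalization = "rescaled01"` and the
#'   weight record attached.
#' @export
weighted_grand_average <- function(maps_by_subject, f1_by_subject) {
  vals <- lapply(maps_by_subject, function(m)
    if (inherits(m, "pattern_map")) m$values else m)
  dims <- vapply(vals, function(v) paste(dim(v), collapse = "x"), "")
  if (length(unique(dims)) != 1) stop("pattern maps differ in shape")
  if (any(f1_by_subject < 0) || sum(f1_by_subject) == 0)
    stop("weights must be non-negative with positive sum")
  w <- f1_by_subject / sum(f1_by_subject)
  avg <- Reduce(`+`, Map(`*`, vals, w))
  rng <- range(avg)
  if (diff(rng) == 0) stop("grand-average map is constant; cannot rescale")
  structure(list(values = (avg - rng[1]) / diff(rng),
                 normalization = "rescaled01", weights = w),
            class = "pattern_map")
}

#' Percentile-ROI condition contrasts of source band power
#'
#' The ROI is the set of vertices whose absolute pattern value exceeds the
#' q-th percentile of the map.  Per subject and condition the mean power
#' over the ROI is computed; pairwise condition contrasts use Wilcoxon
#' signed-rank tests with Benjamini--Hochberg correction, and bootstrap
#' means/CIs are attached per condition.
#'
#' @param pattern_map a `pattern_map` or per-vertex vector (component maps
#'   are combined by their maximum).
#' @param power_by_condition array subjects x conditions x vertices of
#'   source band power, with condition dimnames.
#' @param q ROI percentile (0-100); `q = 0` selects all vertices.
#' @param uniform `"error"` (default) or `"all"`: behaviour when the map
#'   is constant and the percentile ROI is ill-defined.
#' @param seed seed for the bootstrap.
#' @return list with `roi` (vertex indices), `roi_means` (subjects x
#'   conditions), `contrasts` (data.frame with pairwise tests and adjusted
#'   p), `condition_ci`.
#' @export
percentile_roi_contrast <- function(pattern_map, power_by_condition, q = 90,
                                    uniform = c("error", "all"), seed = 1) {
  uniform <- match.arg(uniform)
  v <- if (inherits(pattern_map, "pattern_map")) pattern_map$values
       else pattern_map
  if (is.matrix(v)) v <- apply(v, 1, max)
  av <- abs(v)
  if (q == 0) {
    roi <- seq_along(av)
  } else if (diff(range(av)) == 0) {
    if (uniform == "error")
      stop("uniform pattern map: percentile ROI is ill-defined")
    roi <- seq_along(av)
  } else {
    thr <- quantile(av, q / 100, names = FALSE)
    roi <- which(av > thr)
  }
  if (!length(roi)) stop("empty ROI at the requested percentile")
  d <- dim(power_by_condition)
  conds <- dimnames(power_by_condition)[[2]]
  if (is.null(conds)) conds <- paste0("cond", seq_len(d[2]))
  roi_means <- sapply(seq_len(d[2]), function(ci)
    rowMeans(power_by_condition[, ci, roi, drop = FALSE], dims = 1))
  roi_means <- matrix(roi_means, d[1], d[2], dimnames = list(NULL, conds))
  pairs <- utils::combn(conds, 2)
  tests <- apply(pairs, 2, function(pr) {
    w <- wilcoxon_signed_rank(roi_means[, pr[1]], roi_means[, pr[2]])
    c(statistic = w$statistic, p = w$p)
  })
  contrasts <- data.frame(a = pairs[1, ], b = pairs[2, ],
                          statistic = tests["statistic", ],
                          p = tests["p", ],
                          mean_diff = apply(pairs, 2, function(pr)
                            mean(roi_means[, pr[1]] - roi_means[, pr[2]])))
  contrasts$p_adj <- fdr_bh(contrasts$p)$adjusted
  seeds <- derive_seeds(seed, length(conds))
  condition_ci <- lapply(seq_along(conds), function(i)
    bootstrap_mean_ci(roi_means[, i], bonferroni_m = length(conds),
                      seed = seeds[i]))
  names(condition_ci) <- conds
  list(roi = roi, roi_means = roi_means, contrasts = contrasts,
       condition_ci = condition_ci, q = q)
}
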