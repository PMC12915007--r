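#' Ledoit--Wolf shrinkage covariance
#'
#' Analytic shrinkage of the sample covariance towards the scaled identity,
#' `(1 - s) S + s mu I`, with the optimal shrinkage intensity estimated
#' from the data (Ledoit & Wolf 2004).  Columns are centred first.
#'
#' @param x samples x variables matrix, or an `epoch_set` (epochs are
#'   concatenated along time).
#' @return list of class `lw_cov`: `sigma` (covariance), `shrinkage`,
#'   `mu`, `n`.
#' @export
ledoit_wolf_cov <- function(x) {
  if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    x <- matrix(aperm(x$data, c(3, 1, 2)), d[1] * d[3], d[2])
  }
  stopifnot(is.matrix(x))
  n <- nrow(x); p <- ncol(x)
  if (n < 2) stop("need at least 2 samples")
  x <- sweep(x, 2, colMeans(x))
  s <- crossprod(x) / n
  mu <- sum(diag(s)) / p
  d2 <- sum((s - diag(mu, p))^2) / p
  # sum_t ||x_t x_t' - S||_F^2 = sum_t (x_t' x_t)^2 - n ||S||_F^2
  q <- sum(rowSums(x^2)^2)
  b_bar2 <- (q / n - sum(s^2)) / (n * p)
  b2 <- min(b_bar2, d2)
  shrink <- if (d2 > 0) b2 / d2 else 0
  sigma <- (1 - shrink) * s + shrink * diag(mu, p)
  structure(list(sigma = sigma, shrinkage = shrink, mu = mu, n = n),
            class = "lw_cov")
}

#' Spatial pre-whitener from a noise covariance
#'
#' `W = Lambda^{-1/2} U'` from the eigendecomposition of the (regularized)
#' noise covariance, restricted to eigenvalues above `rank_tolerance`
#' relative to the largest.  Raw noise data are first shrunk with
#' [ledoit_wolf_cov()].
#'
#' @param noise either a symmetric covariance matrix or a samples x
#'   sensors noise data matrix (e.g. an empty-room recording, transposed).
#' @param rank_tolerance relative eigenvalue cutoff.
#' @return object of class `whitener`: `w` (rank x sensors matrix),
#'   `rank`, `cov`.
#' @export
compute_whitener <- function(noise, rank_tolerance = 1e-10) {
  if (is.matrix(noise) && nrow(noise) == ncol(noise) &&
      isSymmetric(unname(noise), tol = 1e-8)) {
    cov <- (noise + t(noise)) / 2
  } else if (is.matrix(noise)) {
    if (nrow(noise) == ncol(noise))
      stop("square non-symmetric input: pass a symmetric covariance or a ",
           "samples x sensors data matrix")
    cov <- ledoit_wolf_cov(noise)$sigma
  } else stop("`noise` must be a matrix")
  ev <- eigen(cov, symmetric = TRUE)
  keep <- ev$values > rank_tolerance * max(ev$values)
  if (!any(keep)) stop("noise covariance numerically zero")
  w <- diag(1 / sqrt(ev$values[keep]), sum(keep)) %*%
    t(ev$vectors[, keep, drop = FALSE])
  structure(list(w = w, rank = sum(keep), cov = cov), class = "whitener")
}
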