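#' Build an abstract forward (source) model on a sphere
#'
#' Constructs the known linear mapping from source amplitudes to sensor
#' measurements used by the simulator and by the beamformer/inverse tests.
#' The gain matrix is deliberately abstract: each source column is a
#' Gaussian-kernel mixture of i.i.d. sensor loadings of its grid
#' neighbourhood, so that neighbouring sources project similarly (spatially
#' smooth columns) without any head-geometry modelling.  A
#' diagonal-plus-low-rank sensor noise covariance is attached for the
#' empty-room analogue and for pre-whitening.
#'
#' @param n_sensors number of sensors (>= 16).
#' @param grid a `source_grid`, or an integer icosahedron level.
#' @param smoothness kernel width (chordal distance on the unit sphere)
#'   controlling how correlated neighbouring gain columns are; 0 gives
#'   independent columns.
#' @param noise_rank rank of the shared (low-rank) part of the sensor noise
#'   covariance.
#' @param seed integer seed; the model is deterministic per (config, seed).
#' @return object of class `source_model`: list with `gain`
#'   (sensors x sources), `grid`, `noise_cov` (sensors x sensors),
#'   `n_sensors`, `n_sources`.
#' @export
build_source_model <- function(n_sensors = 64, grid = 2, smoothness = 0.35,
                               noise_rank = 3, seed = 1) {
  stopifnot_scalar(n_sensors, "n_sensors", lo = 16)
  if (!inherits(grid, "source_grid")) grid <- source_grid(grid)
  n_src <- grid$n_vertices
  if (n_src < 50) stop("source grid must have at least 50 vertices")

  with_seed(seed, {
    z <- matrix(rnorm(n_sensors * n_src), n_sensors, n_src)
    if (smoothness > 0) {
      d2 <- as.matrix(dist(grid$positions))^2
      k <- exp(-d2 / (2 * smoothness^2))
      gain <- z %*% k
    } else {
      gain <- z
    }
    # unit-norm columns: sources contribute on a comparable scale
    gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/")
    if (n_sensors >= n_src && qr(gain)$rank < n_src) {
      flag_note("degenerate gain rank; regenerating with fresh draw")
      z <- matrix(rnorm(n_sensors * n_src), n_sensors, n_src)
      gain <- if (smoothness > 0) z %*% k else z
      gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/")
    }
    f <- matrix(rnorm(n_sensors * noise_rank), n_sensors, noise_rank)
    noise_cov <- diag(runif(n_sensors, 0.5, 1.5)) +
      0.2 * tcrossprod(f) / noise_rank
  })

  structure(list(gain = gain, grid = grid, noise_cov = noise_cov,
                 n_sensors = n_sensors, n_sources = n_src,
                 smoothness = smoothness, seed = seed),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> %d sensors x %d sources (smoothness %.2f)\n",
              x$n_sensors, x$n_sources, x$smoothness))
  invisible(x)
}
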