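#' Subdivide an icosahedron into a spherical triangle mesh
#'
#' Recursive edge-midpoint subdivision of the regular icosahedron, with the
#' new vertices projected back onto the unit sphere.  Level \eqn{k} yields
#' \eqn{10 \cdot 4^k + 2} vertices; level 5 gives the 10,242-vertex grid
#' commonly used as a per-hemisphere cortical source space.
#'
#' @param level non-negative integer subdivision level (at most 7).
#' @return list with `vertices` (n x 3 matrix of unit-norm coordinates) and
#'   `faces` (m x 3 integer matrix of 1-based vertex indices).
#' @examples
#' m <- subdivide_icosahedron(2)
#' nrow(m$vertices)  # 162
#' @export
subdivide_icosahedron <- function(level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level < 0 || level != round(level))
    stop("`level` must be a single non-negative integer")
  if (level > 7) stop("`level` > 7 refused (mesh would be very large)")

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))

  for (lev in seq_len(level)) {
    n_v <- nrow(v)
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    edges <- t(apply(edges, 1, sort))
    key <- paste(edges[, 1], edges[, 2])
    uniq <- !duplicated(key)
    ue <- edges[uniq, , drop = FALSE]
    mid_index <- match(key, key[uniq]) + n_v
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    n_f <- nrow(f)
    m12 <- mid_index[seq_len(n_f)]
    m23 <- mid_index[n_f + seq_len(n_f)]
    m13 <- mid_index[2L * n_f + seq_len(n_f)]
    f <- rbind(
      cbind(f[, 1], m12, m13),
      cbind(f[, 2], m23, m12),
      cbind(f[, 3], m13, m23),
      cbind(m12, m23, m13))
  }
  list(vertices = v, faces = f)
}

#' Build a spherical source grid with mesh adjacency
#'
#' Wraps [subdivide_icosahedron()] into the grid object used throughout the
#' pipeline: unit-sphere dipole positions plus the symmetric, irreflexive
#' neighbour relation induced by the mesh edges (the adjacency over which
#' spatial clusters are formed).
#'
#' @param level icosahedron subdivision level.
#' @return object of class `source_grid`: list with `positions` (n x 3),
#'   `adjacency` (list of integer neighbour vectors, one per vertex),
#'   `n_vertices`, and `faces`.
#' @export
source_grid <- function(level = 2) {
  mesh <- subdivide_icosahedron(level)
  n <- nrow(mesh$vertices)
  edges <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)],
                 mesh$faces[, c(1, 3)])
  adj <- vector("list", n)
  es <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  es <- unique(es)
  for (i in seq_len(nrow(es))) {
    a <- es[i, 1]; b <- es[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(x) sort(unique(x)))
  structure(list(positions = mesh$vertices, adjacency = adj,
                 n_vertices = n, faces = mesh$faces, level = level),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d vertices (ico level %s), %d faces\n",
              x$n_vertices, x$level, nrow(x$faces)))
  invisible(x)
}

# vertices within `order` mesh steps of `center` (center included);
# used to define effect patches and localization neighbourhoods
grid_neighbourhood <- function(grid, center, order = 1) {
  reached <- as.integer(center)
  frontier <- as.integer(center)
  for (k in seq_len(order)) {
    frontier <- setdiff(unique(unlist(grid$adjacency[frontier])), reached)
    if (!length(frontier)) break
    reached <- c(reached, frontier)
  }
  sort(reached)
}
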