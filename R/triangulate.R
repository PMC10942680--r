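#' Delaunay triangulation of scattered core positions
#'
#' Builds a Delaunay triangulation by incremental (Bowyer-Watson) insertion.
#' Points are inserted in Morton (z-order) spatial order, which is fully
#' deterministic for a given point set: calibrating twice on identical input
#' yields identical tables. Exactly co-circular quadruples are resolved
#' deterministically by insertion order.
#'
#' @param positions two-column matrix of point coordinates (x, y).
#' @return integer matrix with one row per triangle, the three columns
#'   indexing rows of `positions` (counter-clockwise order).
#' @examples
#' set.seed(1)
#' p <- cbind(runif(20), runif(20))
#' tri <- triangulate_points(p)
#' @export
triangulate_points <- function(positions) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L) stop("'positions' must have two columns (x, y)")
  n <- nrow(positions)
  if (n < 3L) stop("need at least 3 points to triangulate")
  if (!all(is.finite(positions))) stop("non-finite point coordinates")
  tri <- cpp_delaunay(positions[, 1], positions[, 2])
  if (nrow(tri) == 0L) stop("points are collinear; no triangulation exists")
  tri
}

#' Barycentric interpolation tables for a regular reconstruction grid
#'
#' For every pixel of a regular grid, finds the enclosing Delaunay triangle
#' and records the three vertex indices and barycentric coordinates. This is
#' the one-time calibration that makes per-frame de-pixelated reconstruction
#' a single sparse weighted sum.
#'
#' @param positions two-column matrix of point coordinates.
#' @param tri triangle index matrix from [triangulate_points()].
#' @param x0,y0 coordinates of the first grid pixel centre.
#' @param dx,dy grid pixel pitch (same units as `positions`).
#' @param nx,ny grid dimensions (columns, rows).
#' @return list with `tri_id` (integer, 0 for pixels outside the hull),
#'   `verts` (n-pixel x 3 vertex indices) and `bary` (n-pixel x 3 weights);
#'   pixels are linearised column-major with rows = y, matching
#'   `matrix(v, nrow = ny)`.
#' @export
grid_bary_tables <- function(positions, tri, x0, dx, nx, y0, dy, ny) {
  positions <- as.matrix(positions)
  cpp_grid_bary(positions[, 1], positions[, 2], tri,
                x0, dx, as.integer(nx), y0, dy, as.integer(ny),
                tol = 1e-12)
}
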