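#' Regular voxel grid
#'
#' Defines an isotropic voxel lattice in head (mm) coordinates. Voxel indices
#' are 0-based; the world coordinate of the center of voxel `(i, j, k)` is
#' `origin + spacing * c(i, j, k)`. Potentials live on the *nodes* (voxel
#' corners): node `(p, q, r)` with `p` in `0:nx` sits at
#' `origin + spacing * c(p, q, r) - spacing / 2`.
#'
#' @param shape integer triple `(nx, ny, nz)` of voxel counts, each >= 3.
#' @param spacing isotropic voxel edge length in mm (> 0).
#' @param origin mm coordinate of the center of voxel `(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 3L),
            length(spacing) == 1L, spacing > 0,
            length(origin) == 3L, all(is.finite(origin)))
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels @ %g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' World coordinates of voxel centers
#'
#' @param grid a [voxel_grid()].
#' @param ijk integer matrix (n x 3) of 0-based voxel indices (a vector is
#'   taken as one voxel).
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_center <- function(grid, ijk) {
  ijk <- rbind(ijk)
  sweep(ijk * grid$spacing, 2L, grid$origin, `+`)
}

#' World coordinates of grid nodes
#'
#' Nodes are voxel corners, indexed 0-based with `p` in `0:nx` (and similarly
#' for q, r).
#'
#' @inheritParams voxel_center
#' @param pqr integer matrix (n x 3) of 0-based node indices.
#' @return n x 3 matrix of mm coordinates.
#' @export
node_coord <- function(grid, pqr) {
  pqr <- rbind(pqr)
  sweep(pqr * grid$spacing, 2L, grid$origin - grid$spacing / 2, `+`)
}

# node grid dimensions (nodes = voxels + 1 along each axis)
node_dims <- function(grid) grid$shape + 1L

# linear (1-based, column-major) index of 0-based node triples
node_linear <- function(grid, pqr) {
  pqr <- rbind(pqr)
  nd <- node_dims(grid)
  1L + pqr[, 1] + nd[1] * (pqr[, 2] + nd[2] * pqr[, 3])
}

# inverse of node_linear: 0-based node triples
node_triple <- function(grid, lin) {
  nd <- node_dims(grid)
  lin0 <- lin - 1L
  cbind(lin0 %% nd[1],
        (lin0 %/% nd[1]) %% nd[2],
        lin0 %/% (nd[1] * nd[2]))
}

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    abs(a$spacing - b$spacing) < tol &&
    max(abs(a$origin - b$origin)) < tol
}
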