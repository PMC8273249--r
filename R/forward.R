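#' Solver configuration
#'
#' Settings shared by the SOR and multigrid solvers. Convergence is declared
#' when the relative residual `||b - A phi|| / ||b||` drops below `tol`.
#'
#' @param tol relative residual tolerance (default 1e-6).
#' @param max_iter iteration cap (SOR sweeps or multigrid cycles). Defaults to
#'   20000 for SOR and 200 for multigrid when `NULL`.
#' @param sor_omega relaxation factor for stand-alone SOR, in `[1, 2)`.
#' @param mg_levels number of multigrid levels; `NULL` coarsens by 2 until the
#'   smallest node dimension falls below 8.
#' @param mg_pre,mg_post smoothing sweeps before/after coarse correction.
#' @param mg_smooth_omega relaxation factor of the multigrid SOR smoother
#'   (Gauss-Seidel at 1; default 1.4).
#' @return A `solver_config` list.
#' @export
solver_config <- function(tol = 1e-6, max_iter = NULL, sor_omega = 1.9,
                          mg_levels = NULL, mg_pre = 2L, mg_post = 2L,
                          mg_smooth_omega = 1.4) {
  stopifnot(tol > 0, tol < 1, sor_omega >= 1, sor_omega < 2,
            is.null(mg_levels) || mg_levels >= 1,
            mg_pre >= 1, mg_post >= 0,
            mg_smooth_omega >= 1, mg_smooth_omega < 2)
  structure(list(tol = tol, max_iter = max_iter, sor_omega = sor_omega,
                 mg_levels = if (is.null(mg_levels)) NULL else as.integer(mg_levels),
                 mg_pre = as.integer(mg_pre), mg_post = as.integer(mg_post),
                 mg_smooth_omega = mg_smooth_omega),
            class = "solver_config")
}

#' Edge conductances of the SPFD discretization
#'
#' Every lattice edge between two adjacent nodes gets the conductance
#' `S = sigma_bar * h` (cubic voxels: cross-section `h^2` over length `h`),
#' where `sigma_bar` is the arithmetic mean of the conductivities of the up
#' to four voxels sharing the edge, with air and out-of-grid voxels entering
#' as 0 over a fixed denominator of 4. Edges fully surrounded by air get 0,
#' which realizes the insulating (pure Neumann) scalp boundary.
#'
#' @param sigma a `conductivity_volume`.
#' @return An `edge_conductance` object: per-axis conductance arrays (`Sx`,
#'   `Sy`, `Sz`, siemens), the nodal diagonal `diag` (sum of incident edge
#'   conductances), node dimensions `nd`, and the grid.
#' @export
edge_conductances <- function(sigma) {
  sh <- sigma$grid$shape
  nx <- sh[1]; ny <- sh[2]; nz <- sh[3]
  h <- sigma$grid$spacing * 1e-3  # mm -> m
  s <- sigma$sigma

  pad_mean4 <- function(a, d1, d2) {
    # a padded with one zero layer on both sides of dims d1 and d2; returns
    # the mean of the 4 voxels flanking each edge of the remaining axis
    dp <- dim(a); dp[d1] <- dp[d1] + 2L; dp[d2] <- dp[d2] + 2L
    P <- array(0, dim = dp)
    idx <- lapply(dim(a), seq_len)
    idx[[d1]] <- idx[[d1]] + 1L; idx[[d2]] <- idx[[d2]] + 1L
    P[idx[[1]], idx[[2]], idx[[3]]] <- a
    sl <- function(o1, o2) {
      i <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
      i[[d1]] <- seq_len(dim(a)[d1] + 1L) + o1
      i[[d2]] <- seq_len(dim(a)[d2] + 1L) + o2
      P[i[[1]], i[[2]], i[[3]]]
    }
    (sl(0L, 0L) + sl(1L, 0L) + sl(0L, 1L) + sl(1L, 1L)) / 4
  }

  Sx <- pad_mean4(s, 2L, 3L) * h  # dims (nx, ny+1, nz+1)
  Sy <- pad_mean4(s, 1L, 3L) * h  # dims (nx+1, ny, nz+1)
  Sz <- pad_mean4(s, 1L, 2L) * h  # dims (nx+1, ny+1, nz)

  nd <- c(nx + 1L, ny + 1L, nz + 1L)
  D <- array(0, dim = nd)
  D[1:nx, , ] <- D[1:nx, , ] + Sx; D[2:(nx + 1), , ] <- D[2:(nx + 1), , ] + Sx
  D[, 1:ny, ] <- D[, 1:ny, ] + Sy; D[, 2:(ny + 1), ] <- D[, 2:(ny + 1), ] + Sy
  D[, , 1:nz] <- D[, , 1:nz] + Sz; D[, , 2:(nz + 1)] <- D[, , 2:(nz + 1)] + Sz

  structure(list(Sx = Sx, Sy = Sy, Sz = Sz, diag = D, nd = nd,
                 grid = sigma$grid),
            class = "edge_conductance")
}

#' Assemble the sparse SPFD operator
#'
#' Explicit sparse form of the nodal Kirchhoff balance, one row per node:
#' `sum_n S_n phi_n - (sum_n S_n) phi_0 = rhs_0`. Air nodes give empty rows.
#' The operator is symmetric with zero row sums (constants span the
#' nullspace); callers solving with it must pin a reference node or deflate.
#' Intended for small grids and as the direct-solver cross-check; large
#' solves go through the matrix-free [solve_sor()] / [solve_multigrid()].
#'
#' @param S an `edge_conductance` object.
#' @return A `Matrix::dgCMatrix` over all grid nodes (column-major node
#'   order).
#' @export
assemble_system <- function(S) {
  nd <- S$nd
  if (spfd_n_components(S$Sx, S$Sy, S$Sz, S$diag, nd) > 1L)
    stop("head region has more than one connected component; potential is undefined between components")
  tri <- function(arr, axis) {
    w <- which(arr > 0)
    if (!length(w)) return(NULL)
    pqr <- arrayInd(w, dim(arr)) - 1L
    i <- 1L + pqr[, 1] + nd[1] * (pqr[, 2] + nd[2] * pqr[, 3])
    step <- c(1L, nd[1], nd[1] * nd[2])[axis]
    cbind(i = i, j = i + step, x = arr[w])
  }
  t3 <- rbind(tri(S$Sx, 1L), tri(S$Sy, 2L), tri(S$Sz, 3L))
  n <- prod(nd)
  dg <- which(S$diag > 0)
  Matrix::sparseMatrix(
    i = c(t3[, "i"], t3[, "j"], dg),
    j = c(t3[, "j"], t3[, "i"], dg),
    x = c(t3[, "x"], t3[, "x"], -S$diag[dg]),
    dims = c(n, n))
}

#' Current dipole source
#'
#' A one-edge current dipole: current `I` leaves the medium at the negative
#' pole node and re-enters at the positive pole one lattice edge away along
#' `axis`, giving dipole moment `I * h` (A m).
#'
#' @param node 0-based `(p, q, r)` index of the negative pole node.
#' @param axis one of `"+x" "-x" "+y" "-y" "+z" "-z"`.
#' @param current dipole current in amperes (default 1 mA).
#' @return A `dipole_source` object.
#' @export
dipole_source <- function(node, axis = "+z", current = 1e-3) {
  axis <- match.arg(axis, c("+x", "-x", "+y", "-y", "+z", "-z"))
  stopifnot(length(node) == 3L, current != 0)
  structure(list(node = as.integer(node), axis = axis, current = current),
            class = "dipole_source")
}

axis_unit <- function(axis) {
  sgn <- if (substr(axis, 1, 1) == "-") -1L else 1L
  d <- match(substr(axis, 2, 2), c("x", "y", "z"))
  u <- integer(3); u[d] <- sgn
  list(u = u, dim = d, sign = sgn)
}

new_source_term <- function(grid, nodes, currents, meta = list()) {
  stopifnot(abs(sum(currents)) < 1e-15 * max(abs(currents)))
  structure(list(grid = grid, nodes = as.integer(nodes),
                 currents = currents, meta = meta),
            class = "source_term")
}

# dense injected-current array over nodes
densify_rhs <- function(src) {
  if (is.array(src)) return(src)
  nd <- node_dims(src$grid)
  b <- array(0, dim = nd)
  for (t in seq_along(src$nodes))  # loop: duplicate node indices must accumulate
    b[src$nodes[t]] <- b[src$nodes[t]] + src$currents[t]
  b
}

node_in_gray <- function(gm, pqr) {
  # a node counts as gray when at least one of its up-to-8 adjacent voxels is
  # gray matter
  sh <- dim(gm$mask)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    v <- pqr - c(di, dj, dk)
    if (all(v >= 0) && all(v < sh) && gm$mask[v[1] + 1, v[2] + 1, v[3] + 1])
      return(TRUE)
  }
  FALSE
}

#' Nodal source term of a one-edge dipole
#'
#' `+I` at the positive pole node, `-I` at the negative pole node; all other
#' entries zero (quasi-static equivalent-current realization of the charge
#' source).
#'
#' @param d a [dipole_source()].
#' @param grid the [voxel_grid()] the solve runs on.
#' @param gm optionally a `gm_index`; when given, both pole nodes must touch
#'   gray matter.
#' @return A `source_term`.
#' @export
dipole_source_term <- function(d, grid, gm = NULL) {
  ax <- axis_unit(d$axis)
  n_neg <- d$node
  n_pos <- d$node + ax$u
  nd <- node_dims(grid)
  if (any(n_neg < 0) || any(n_pos < 0) || any(n_neg >= nd) || any(n_pos >= nd))
    stop("dipole pole node outside the grid")
  if (!is.null(gm) && !(node_in_gray(gm, n_neg) && node_in_gray(gm, n_pos)))
    stop("dipole pole node outside gray matter")
  new_source_term(grid,
                  nodes = node_linear(grid, rbind(n_pos, n_neg)),
                  currents = c(d$current, -d$current),
                  meta = list(kind = "edge_dipole", dipole = d))
}

#' Nodal source term of a voxel-centered dipole
#'
#' Distributes `-I/4` over the four corner nodes of the voxel face on the
#' negative side of `axis` and `+I/4` over the opposite face. This is the
#' exact discrete adjoint of the voxel-center field extraction used for the
#' lead-field matrix, so the resulting scalp potentials equal the lead-field
#' column of `(voxel, axis)` times the moment `I * h` up to solver tolerance;
#' its nominal location is the voxel center.
#'
#' @param grid a [voxel_grid()].
#' @param voxel 0-based voxel index triple.
#' @param axis as in [dipole_source()].
#' @param current dipole current in amperes.
#' @param gm optionally a `gm_index`; the voxel must then be gray matter.
#' @return A `source_term`.
#' @export
voxel_dipole_term <- function(grid, voxel, axis = "+z", current = 1e-3,
                              gm = NULL) {
  ax <- axis_unit(axis)
  voxel <- as.integer(voxel)
  stopifnot(all(voxel >= 0), all(voxel < grid$shape))
  if (!is.null(gm) && !gm$mask[voxel[1] + 1, voxel[2] + 1, voxel[3] + 1])
    stop("dipole voxel outside gray matter")
  off <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  lo <- off[off[, ax$dim] == 0, , drop = FALSE]
  hi <- off[off[, ax$dim] == 1, , drop = FALSE]
  if (ax$sign < 0) { tmp <- lo; lo <- hi; hi <- tmp }
  nodes <- rbind(sweep(hi, 2, voxel, `+`), sweep(lo, 2, voxel, `+`))
  new_source_term(grid,
                  nodes = node_linear(grid, nodes),
                  currents = c(rep(current / 4, 4), rep(-current / 4, 4)),
                  meta = list(kind = "voxel_dipole", voxel = voxel,
                              axis = axis, current = current))
}

#' Electrode-pair injection source
#'
#' `+I` at the active electrode's scalp node and `-I` at the ground
#' electrode's node: the reciprocal excitation used to build one lead-field
#' row.
#'
#' @param montage an `electrode_montage`.
#' @param active_idx index of the active electrode in montage order.
#' @param current injected current in amperes (default 1 mA; the lead field
#'   divides it out).
#' @param ground ground electrode index (default: the montage's ground).
#' @return A `source_term`.
#' @export
electrode_pair_source <- function(montage, active_idx, current = 1e-3,
                                  ground = montage$ground) {
  stopifnot(active_idx >= 1, active_idx <= length(montage$names))
  if (active_idx == ground) stop("active electrode equals the ground electrode")
  new_source_term(montage$grid,
                  nodes = c(montage$node_index[active_idx],
                            montage$node_index[ground]),
                  currents = c(current, -current),
                  meta = list(kind = "electrode_pair",
                              active = montage$names[active_idx],
                              ground = montage$names[ground]))
}

new_spfd_solution <- function(phi, grid, iterations, residual, history, method) {
  structure(list(phi = phi, grid = grid, iterations = iterations,
                 residual = residual, residual_history = history,
                 method = method),
            class = "spfd_solution")
}

#' @export
print.spfd_solution <- function(x, ...) {
  cat(sprintf("<spfd_solution> %s: %d iterations, relative residual %.3g\n",
              x$method, x$iterations, x$residual))
  invisible(x)
}

deflate <- function(phi, head) { phi[head] <- phi[head] - mean(phi[head]); phi }

#' Solve the SPFD system with successive over-relaxation
#'
#' Plain SOR iteration on the nodal system. The pure-Neumann nullspace
#' (constant potentials) is handled by zero-mean deflation over head nodes;
#' use [reference_potentials()] or subtract a node of your choice to fix the
#' reference.
#'
#' @param S an [edge_conductances()] object.
#' @param rhs a `source_term` or a dense injected-current node array
#'   (amperes, summing to zero).
#' @param config a [solver_config()].
#' @return An `spfd_solution` with the node potential array `phi` (volts),
#'   iteration count, final relative residual, and residual history.
#' @export
solve_sor <- function(S, rhs, config = solver_config()) {
  b <- densify_rhs(rhs)
  head <- S$diag > 0
  bn <- sqrt(sum(b^2))
  nd <- S$nd
  phi <- array(0, dim = nd)
  if (bn == 0)
    return(new_spfd_solution(phi, S$grid, 0L, 0, numeric(0), "sor"))
  max_iter <- if (is.null(config$max_iter)) 20000L else config$max_iter
  history <- numeric(0)
  for (it in seq_len(max_iter)) {
    spfd_sweep(phi, S$Sx, S$Sy, S$Sz, S$diag, b, nd, config$sor_omega, FALSE)
    phi <- deflate(phi, head)
    r <- b - spfd_apply(phi, S$Sx, S$Sy, S$Sz, S$diag, nd)
    rel <- sqrt(sum(r[head]^2)) / bn
    history <- c(history, rel)
    if (rel < config$tol)
      return(new_spfd_solution(phi, S$grid, it, rel, history, "sor"))
  }
  cond <- simpleError(sprintf(
    "SOR did not reach tol %.2g in %d sweeps (residual %.3g)",
    config$tol, max_iter, history[length(history)]))
  cond$residual_history <- history
  stop(cond)
}

# average 2x2x2 fine voxels into the factor-2 coarse conductivity (missing
# fine voxels beyond the boundary count as air)
coarsen_sigma <- function(sigma) {
  sh <- sigma$grid$shape
  nc <- as.integer(ceiling(sh / 2))
  p <- array(0, dim = 2L * nc)
  p[seq_len(sh[1]), seq_len(sh[2]), seq_len(sh[3])] <- sigma$sigma
  acc <- array(0, dim = nc)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    acc <- acc + p[seq(1 + di, 2 * nc[1], 2),
                   seq(1 + dj, 2 * nc[2], 2),
                   seq(1 + dk, 2 * nc[3], 2)]
  }
  g <- sigma$grid
  grid_c <- voxel_grid(nc, g$spacing * 2, g$origin + g$spacing / 2)
  new_conductivity_volume(grid_c, acc / 8)
}

#' Geometric multigrid hierarchy
#'
#' Coarsens the conductivity volume by factor 2 per level (coarse edge
#' conductances are re-derived from the averaged coarse conductivities, not
#' by Galerkin products) until the smallest node dimension drops below 8 or
#' `config$mg_levels` levels exist. Coarse nodes coincide with even-index
#' fine nodes.
#'
#' @param sigma a `conductivity_volume`.
#' @param config a [solver_config()].
#' @return An `mg_hierarchy`: list of `edge_conductance` levels, finest first.
#' @export
mg_hierarchy <- function(sigma, config = solver_config()) {
  levels <- list(edge_conductances(sigma))
  s <- sigma
  repeat {
    if (!is.null(config$mg_levels) && length(levels) >= config$mg_levels) break
    if (min(dim(levels[[length(levels)]]$diag)) - 1L < 8L &&
        is.null(config$mg_levels)) break
    if (min(dim(levels[[length(levels)]]$diag)) <= 4L) break
    s <- coarsen_sigma(s)
    levels <- c(levels, list(edge_conductances(s)))
  }
  structure(levels, class = "mg_hierarchy")
}

smooth_level <- function(S, phi, b, sweeps, omega, reverse) {
  for (i in seq_len(sweeps))
    spfd_sweep(phi, S$Sx, S$Sy, S$Sz, S$diag, b, S$nd, omega, reverse)
  phi
}

v_cycle <- function(hier, level, phi, b, config) {
  S <- hier[[level]]
  if (length(hier) == 1L) {
    # degenerate single-level hierarchy: pure SOR smoothing (pre forward,
    # post backward sweeps), identical iterates to solve_sor per sweep
    phi <- smooth_level(S, phi, b, config$mg_pre, config$mg_smooth_omega, FALSE)
    return(smooth_level(S, phi, b, config$mg_post, config$mg_smooth_omega, TRUE))
  }
  if (level == length(hier)) {
    # coarsest: relax hard (alternating sweep direction)
    for (i in seq_len(100L)) {
      spfd_sweep(phi, S$Sx, S$Sy, S$Sz, S$diag, b, S$nd, config$mg_smooth_omega,
                 i %% 2L == 0L)
    }
    return(deflate(phi, S$diag > 0))
  }
  phi <- smooth_level(S, phi, b, config$mg_pre, config$mg_smooth_omega, FALSE)
  r <- b - spfd_apply(phi, S$Sx, S$Sy, S$Sz, S$diag, S$nd)
  r[S$diag <= 0] <- 0
  Sc <- hier[[level + 1L]]
  rc <- mg_restrict(r, S$nd, Sc$nd)
  dim(rc) <- Sc$nd
  rc[Sc$diag <= 0] <- 0
  ec <- v_cycle(hier, level + 1L, array(0, dim = Sc$nd), rc, config)
  mg_prolong_add(phi, ec, S$diag, S$nd, Sc$nd)
  smooth_level(S, phi, b, config$mg_post, config$mg_smooth_omega, TRUE)
}

#' Solve the SPFD system with geometric multigrid
#'
#' V-cycles with SOR/Gauss-Seidel smoothing (forward sweeps before, backward
#' sweeps after the coarse correction). With `accel = "cg"` (default) the
#' symmetric V-cycle acts as the preconditioner of a conjugate-gradient
#' iteration, which is markedly more robust on the strong CSF/skull
#' conductivity contrasts; `accel = "none"` runs plain V-cycle iteration
#' (with a single level this is exactly plain SOR smoothing).
#'
#' @param hier an [mg_hierarchy()] (or a `conductivity_volume`, coarsened on
#'   the fly).
#' @param rhs as in [solve_sor()].
#' @param config a [solver_config()].
#' @param accel `"cg"` or `"none"`.
#' @return An `spfd_solution`; `iterations` counts V-cycles.
#' @examples
#' lab <- make_layered_sphere(spacing = 2, radii_mm = c(30, 26, 22, 20, 12))
#' sigma <- assign_conductivity(lab)
#' gm <- gray_matter_index(lab)
#' src <- voxel_dipole_term(sigma$grid, gm$voxel_list[100, ], "+z", gm = gm)
#' sol <- solve_multigrid(sigma, src)
#' sol$iterations; sol$residual
#' @export
solve_multigrid <- function(hier, rhs, config = solver_config(),
                            accel = c("cg", "none")) {
  accel <- match.arg(accel)
  if (inherits(hier, "conductivity_volume")) hier <- mg_hierarchy(hier, config)
  S <- hier[[1]]
  head <- S$diag > 0
  b <- densify_rhs(rhs)
  bn <- sqrt(sum(b^2))
  phi <- array(0, dim = S$nd)
  if (bn == 0)
    return(new_spfd_solution(phi, S$grid, 0L, 0, numeric(0), "multigrid"))
  max_iter <- if (is.null(config$max_iter)) 200L else config$max_iter
  history <- numeric(0)
  method <- paste0("multigrid(", accel, ")")

  if (accel == "none") {
    for (it in seq_len(max_iter)) {
      phi <- v_cycle(hier, 1L, phi, b, config)
      phi <- deflate(phi, head)
      r <- b - spfd_apply(phi, S$Sx, S$Sy, S$Sz, S$diag, S$nd)
      rel <- sqrt(sum(r[head]^2)) / bn
      history <- c(history, rel)
      if (rel < config$tol)
        return(new_spfd_solution(phi, S$grid, it, rel, history, method))
    }
  } else {
    # V-cycle-preconditioned conjugate gradients on the deflated subspace
    x <- phi
    r <- b
    r[!head] <- 0
    r <- deflate(r, head)
    p <- NULL; rz_old <- 0
    for (it in seq_len(max_iter)) {
      z <- v_cycle(hier, 1L, array(0, dim = S$nd), r, config)
      z <- deflate(z, head)
      rz <- sum(r * z)
      if (!is.finite(rz) || rz <= 0) break  # fall back below
      p <- if (is.null(p)) z else z + (rz / rz_old) * p
      Ap <- spfd_apply(p, S$Sx, S$Sy, S$Sz, S$diag, S$nd)
      pAp <- sum(p * Ap)
      if (pAp <= 0) break
      alpha <- rz / pAp
      x <- x + alpha * p
      r <- r - alpha * Ap
      r <- deflate(r, head)
      rz_old <- rz
      rel <- sqrt(sum(r[head]^2)) / bn
      history <- c(history, rel)
      if (rel < config$tol) {
        x <- deflate(x, head)
        return(new_spfd_solution(x, S$grid, it, rel, history, method))
      }
    }
    # robust fallback: plain V-cycle iteration from the current iterate
    phi <- x
    for (it2 in seq_len(max_iter)) {
      phi <- v_cycle(hier, 1L, phi, b, config)
      phi <- deflate(phi, head)
      r2 <- b - spfd_apply(phi, S$Sx, S$Sy, S$Sz, S$diag, S$nd)
      rel <- sqrt(sum(r2[head]^2)) / bn
      history <- c(history, rel)
      if (rel < config$tol)
        return(new_spfd_solution(phi, S$grid, length(history), rel, history, method))
    }
  }
  cond <- simpleError(sprintf(
    "multigrid did not reach tol %.2g (residual %.3g after %d cycles)",
    config$tol, history[length(history)], length(history)))
  cond$residual_history <- history
  stop(cond)
}

# Electric field at voxel centers from node potentials: per axis, the voxel
# field is the mean of the four parallel edge differences, i.e. the central
# difference of face-averaged potentials. Returns V/m.
field_at_voxels <- function(phi, grid) {
  sh <- grid$shape
  h <- grid$spacing * 1e-3
  nx <- sh[1]; ny <- sh[2]; nz <- sh[3]
  face_avg <- function(d1, d2) {
    i0 <- list(seq_len(nx + 1L), seq_len(ny + 1L), seq_len(nz + 1L))
    a <- i0; a[[d1]] <- seq_len(dim(phi)[d1] - 1L); a[[d2]] <- seq_len(dim(phi)[d2] - 1L)
    b <- a; b[[d1]] <- a[[d1]] + 1L
    c_ <- a; c_[[d2]] <- a[[d2]] + 1L
    d_ <- b; d_[[d2]] <- c_[[d2]]
    (phi[a[[1]], a[[2]], a[[3]]] + phi[b[[1]], b[[2]], b[[3]]] +
     phi[c_[[1]], c_[[2]], c_[[3]]] + phi[d_[[1]], d_[[2]], d_[[3]]]) / 4
  }
  fa_x <- face_avg(2L, 3L)  # dims (nx+1, ny, nz)
  fa_y <- face_avg(1L, 3L)
  fa_z <- face_avg(1L, 2L)
  list(Ex = -(fa_x[2:(nx + 1), , , drop = FALSE] - fa_x[1:nx, , , drop = FALSE]) / h,
       Ey = -(fa_y[, 2:(ny + 1), , drop = FALSE] - fa_y[, 1:ny, , drop = FALSE]) / h,
       Ez = -(fa_z[, , 2:(nz + 1), drop = FALSE] - fa_z[, , 1:nz, drop = FALSE]) / h)
}

#' Current density from a potential solution
#'
#' Ohm's law per voxel: `j = sigma * E = -sigma * grad(phi)`, with the
#' gradient taken by averaging the nodal differences to voxel centers. Air
#' voxels carry zero current density.
#'
#' @param sol an `spfd_solution` (or a bare node potential array).
#' @param sigma the `conductivity_volume` of the solve.
#' @return A `current_density` object with voxel arrays `jx, jy, jz` (A/m^2).
#' @export
current_density <- function(sol, sigma) {
  phi <- if (inherits(sol, "spfd_solution")) sol$phi else sol
  stopifnot(all(dim(phi) == node_dims(sigma$grid)))
  E <- field_at_voxels(phi, sigma$grid)
  structure(list(jx = sigma$sigma * E$Ex,
                 jy = sigma$sigma * E$Ey,
                 jz = sigma$sigma * E$Ez,
                 grid = sigma$grid),
            class = "current_density")
}

#' @export
print.current_density <- function(x, ...) {
  jmag <- sqrt(x$jx^2 + x$jy^2 + x$jz^2)
  cat(sprintf("<current_density> peak |j| = %.4g A/m^2\n", max(jmag)))
  invisible(x)
}
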