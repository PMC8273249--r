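#' Build the lead-field matrix by reciprocity
#'
#' One forward solve per non-ground electrode (M - 1 in total): unit current
#' is injected across (electrode, ground), the induced electric field is read
#' at every gray-matter voxel center, and the field components divided by the
#' injection current form that electrode's row. By the reciprocity principle
#' the resulting M x 3N matrix maps a gray-matter dipole-moment vector
#' (voxel-major, x/y/z interleaved) to ground-referenced scalp potentials,
#' so `lfm_predict(L, j)` reproduces a forward solve exactly up to solver
#' tolerance. The ground electrode's row is identically zero. Row signs are
#' chosen so that `L j = phi` holds with `E = -grad(phi)` (equivalent to
#' injecting the current at the ground side).
#'
#' @param sigma a `conductivity_volume`.
#' @param montage an `electrode_montage` on the same grid.
#' @param gm a `gm_index` of the gray-matter voxels.
#' @param config a [solver_config()].
#' @param current injection current in amperes (cancels out; default 1 mA).
#' @param hier optional prebuilt [mg_hierarchy()] for `sigma` (built once here
#'   otherwise).
#' @param verbose print per-electrode solver progress.
#' @return A `leadfield` object: dense `values` (M x 3N), `col_norms`,
#'   `current`, `montage`, `gm`, `n_solves`.
#' @examples
#' \donttest{
#' lab <- make_layered_sphere(spacing = 2, radii_mm = c(30, 26, 22, 20, 12))
#' sigma <- assign_conductivity(lab)
#' gm <- gray_matter_index(lab)
#' mo <- place_montage(lab, "10-20")
#' L <- build_lfm(sigma, mo, gm)          # 20 reciprocal forward solves
#' # noise-free potentials of a gray-matter dipole localize exactly:
#' src <- voxel_dipole_term(sigma$grid, gm$voxel_list[1500, ], "+y", gm = gm)
#' phi <- reference_potentials(solve_multigrid(sigma, src), mo)
#' mp_localize(L, phi)
#' }
#' @export
build_lfm <- function(sigma, montage, gm, config = solver_config(),
                      current = 1e-3, hier = NULL, verbose = FALSE) {
  stopifnot(gm$n >= 1, same_grid(sigma$grid, montage$grid))
  if (is.null(hier)) hier <- mg_hierarchy(sigma, config)
  M <- length(montage$names)
  sh <- sigma$grid$shape
  gm_lin <- 1L + gm$voxel_list[, 1] +
    sh[1] * (gm$voxel_list[, 2] + sh[2] * gm$voxel_list[, 3])

  values <- matrix(0, nrow = M, ncol = 3L * gm$n)
  for (m in seq_len(M)) {
    if (m == montage$ground) next
    src <- electrode_pair_source(montage, m, current)
    sol <- tryCatch(solve_multigrid(hier, src, config),
                    error = function(e) stop(sprintf(
                      "forward solve failed for electrode %s: %s",
                      montage$names[m], conditionMessage(e))))
    if (verbose)
      message(sprintf("  electrode %-5s: %3d cycles, residual %.2e",
                      montage$names[m], sol$iterations, sol$residual))
    E <- field_at_voxels(sol$phi, sigma$grid)
    values[m, ] <- as.vector(rbind(-E$Ex[gm_lin], -E$Ey[gm_lin],
                                   -E$Ez[gm_lin])) / current
  }
  structure(list(values = values,
                 col_norms = sqrt(.colSums(values^2, M, 3L * gm$n)),
                 current = current,
                 montage = montage,
                 gm = gm,
                 grid = sigma$grid,
                 n_solves = M - 1L),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d electrodes x %d columns (N = %d gray voxels), %d reciprocal solves\n",
              nrow(x$values), ncol(x$values), x$gm$n, x$n_solves))
  invisible(x)
}

#' Predict scalp potentials from a sparse or dense source vector
#'
#' Computes `phi = L j`. Supply either the full 3N moment vector `j` (A m,
#' voxel-major x/y/z interleaved) or a few `cols` with `coeffs`.
#'
#' @param L a `leadfield`.
#' @param j numeric vector of length 3N, or `NULL`.
#' @param cols,coeffs column indices and moments of a sparse source.
#' @return A `scalp_potentials` vector (ground entry 0).
#' @export
lfm_predict <- function(L, j = NULL, cols = NULL, coeffs = NULL) {
  if (!is.null(j)) {
    if (length(j) != ncol(L$values))
      stop(sprintf("source vector has length %d, lead field expects %d",
                   length(j), ncol(L$values)))
    v <- drop(L$values %*% j)
  } else {
    stopifnot(length(cols) == length(coeffs), all(cols >= 1),
              all(cols <= ncol(L$values)))
    v <- drop(L$values[, cols, drop = FALSE] %*% coeffs)
  }
  structure(stats::setNames(v, L$montage$names), ground = L$montage$ground,
            class = "scalp_potentials")
}

# map a lead-field column index to (gray voxel row, axis 1..3)
col_to_voxel <- function(L, col) {
  list(voxel = (col - 1L) %/% 3L + 1L, axis = (col - 1L) %% 3L + 1L)
}
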