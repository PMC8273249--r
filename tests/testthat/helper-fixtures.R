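# Shared fixtures, built once per session and cached.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) assign(name, builder(), envir = .fx)
  get(name, envir = .fx)
}

# 30 mm five-shell sphere at 2 mm: cheap enough for unit tests
small_labels <- function() fx("small_labels", function()
  make_layered_sphere(spacing = 2, radii_mm = c(30, 26, 22, 20, 12)))

small_sigma <- function() fx("small_sigma", function()
  assign_conductivity(small_labels()))

small_gm <- function() fx("small_gm", function()
  gray_matter_index(small_labels()))

small_montage <- function() fx("small_montage", function()
  place_montage(small_labels(), "10-20"))

small_hier <- function() fx("small_hier", function()
  mg_hierarchy(small_sigma()))

small_lfm <- function() fx("small_lfm", function()
  build_lfm(small_sigma(), small_montage(), small_gm(), hier = small_hier()))

# ~16^3 single-tissue sphere for direct-solver comparisons
tiny_sigma <- function() fx("tiny_sigma", function() {
  lab <- make_layered_sphere(spacing = 2, radii_mm = c(13, 10, 8),
                             tissue_order = c("skin", "csf", "gray matter"),
                             margin = 1L)
  assign_conductivity(lab)
})

# uniform cube conductivity on an explicit grid
uniform_cube <- function(n, sigma_value = 1, spacing = 1) {
  g <- voxel_grid(rep(n, 3), spacing)
  arr <- array(sigma_value, dim = rep(n, 3))
  structure(list(grid = g, sigma = arr), class = "conductivity_volume")
}

# solve the assembled sparse system directly (node `pin` fixed to 0);
# independent of the iterative solvers
direct_solve <- function(S, rhs_term, pin = NULL) {
  A <- assemble_system(S)              # row convention: offdiag - diag
  b <- as.vector(spfdeeg:::densify_rhs(rhs_term))   # injected currents; A_phys = -A
  head <- which(as.vector(S$diag) > 0)
  if (is.null(pin)) pin <- head[1]
  keep <- setdiff(head, pin)
  phi <- numeric(prod(S$nd))
  phi[keep] <- as.vector(Matrix::solve(-A[keep, keep], b[keep]))
  array(phi, dim = S$nd)
}

# align two node potential fields up to an additive constant (over head nodes)
align_const <- function(phi, ref, head) {
  phi - mean(phi[head] - ref[head])
}
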