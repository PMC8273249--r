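test_that("edge conductances average the four flanking voxels", {
  # uniform sigma = 1 S/m, h = 1 mm: interior edge S = 1e-3 S
  cube <- uniform_cube(4, sigma_value = 1, spacing = 1)
  S <- edge_conductances(cube)
  expect_equal(S$Sx[2, 3, 3], 1e-3)
  # boundary edge flanked by 2 voxels at sigma = 2 and 2 air positions:
  # mean = (2 + 2 + 0 + 0) / 4 = 1
  cube2 <- uniform_cube(4, sigma_value = 2, spacing = 1)
  S2 <- edge_conductances(cube2)
  expect_equal(S2$Sx[2, 3, 1], (2 + 2) / 4 * 1e-3)  # bottom face edge
  # corner edge: one voxel out of four -> mean sigma / 4
  expect_equal(S2$Sx[2, 1, 1], 2 / 4 * 1e-3)
  # an all-air edge has zero conductance
  lab <- small_labels()
  sig <- small_sigma()
  S3 <- edge_conductances(sig)
  expect_equal(S3$Sx[1, 1, 1], 0)
})

test_that("assembled operator is the symmetric Kirchhoff balance", {
  cube <- uniform_cube(3, sigma_value = 0.5, spacing = 2)
  S <- edge_conductances(cube)
  A <- assemble_system(S)
  # symmetry and zero row sums (constants in the nullspace)
  expect_equal(max(abs(A - Matrix::t(A))), 0)
  expect_lt(max(abs(Matrix::rowSums(A))), 1e-16)
  # interior node of a uniform cube: standard 7-point Laplacian scaled by
  # sigma * h (h in meters)
  h <- 2e-3
  ctr <- spfdeeg:::node_linear(cube$grid, c(1, 1, 1))
  expect_equal(A[ctr, ctr], -6 * 0.5 * h)
  nb <- spfdeeg:::node_linear(cube$grid, c(2, 1, 1))
  expect_equal(A[ctr, nb], 0.5 * h)
  # hand-built 7-point Laplacian on the interior 2x2x2 node block
  interior <- t(as.matrix(expand.grid(1:2, 1:2, 1:2)))
  ids <- apply(interior, 2, function(v) spfdeeg:::node_linear(cube$grid, v))
  Ai <- as.matrix(A[ids, ids])
  ref <- matrix(0, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    d <- sum(abs(interior[, a] - interior[, b]))
    if (d == 1) ref[a, b] <- 0.5 * h
  }
  diag(ref) <- -6 * 0.5 * h
  expect_equal(Ai, ref, ignore_attr = TRUE)
})

test_that("disconnected head regions are rejected", {
  g <- voxel_grid(c(9, 3, 3), 1)
  arr <- array(0, dim = c(9, 3, 3))
  arr[1:3, , ] <- 1; arr[7:9, , ] <- 1  # two blobs separated by air
  sig <- structure(list(grid = g, sigma = arr), class = "conductivity_volume")
  expect_error(assemble_system(edge_conductances(sig)), "connected")
})

test_that("dipole and electrode-pair sources conserve charge and flip sign", {
  grid <- small_labels()$grid
  gm <- small_gm()
  d <- dipole_source(gm$voxel_list[50, ], "+y", current = 2e-3)
  s1 <- dipole_source_term(d, grid, gm = gm)
  expect_equal(sum(s1$currents), 0)
  d2 <- dipole_source(gm$voxel_list[50, ] + c(0, 1, 0), "-y", current = 2e-3)
  s2 <- dipole_source_term(d2, grid, gm = gm)
  b1 <- spfdeeg:::densify_rhs(s1); b2 <- spfdeeg:::densify_rhs(s2)
  expect_equal(b1, -b2)
  # pole outside gray matter is refused
  dbad <- dipole_source(c(1, 1, 1), "+x")
  expect_error(dipole_source_term(dbad, grid, gm = gm), "gray")
  # voxel dipole: 8 nodes at +/- I/4, zero sum
  sv <- voxel_dipole_term(grid, gm$voxel_list[50, ], "+z", current = 1e-3, gm = gm)
  expect_equal(sort(sv$currents), sort(c(rep(2.5e-4, 4), rep(-2.5e-4, 4))))
  expect_equal(sum(sv$currents), 0)
  # electrode pair
  mo <- small_montage()
  se <- electrode_pair_source(mo, 3, 1e-3)
  expect_equal(sum(se$currents), 0)
  expect_error(electrode_pair_source(mo, mo$ground), "ground")
})

test_that("SOR solves to tolerance, matches a direct factorization, and logs a monotone residual", {
  sig <- tiny_sigma()
  S <- edge_conductances(sig)
  # zero source -> zero potential, zero iterations of work needed
  z <- solve_sor(S, array(0, dim = S$nd))
  expect_true(all(z$phi == 0))
  # dipole-like injection between two interior nodes
  ctr <- (sig$grid$shape - 1L) %/% 2L
  d <- dipole_source(ctr, "+x", current = 1e-3)
  src <- dipole_source_term(d, sig$grid)
  sol <- solve_sor(S, src, solver_config(tol = 1e-8))
  expect_lt(sol$residual, 1e-8)
  head <- S$diag > 0
  ref <- direct_solve(S, src)
  ref <- align_const(ref, sol$phi, head)
  expect_lt(max(abs(sol$phi[head] - ref[head])) / max(abs(ref[head])), 1e-7)
  # residual history decreasing over checkpoint intervals (over-relaxation
  # oscillates sweep-to-sweep but must trend down)
  ck <- sol$residual_history[seq(1, length(sol$residual_history), by = 25)]
  expect_true(all(diff(ck) < 0))
  # iteration cap raises an error carrying the history
  err <- tryCatch(solve_sor(S, src, solver_config(tol = 1e-12, max_iter = 3L)),
                  error = identity)
  expect_s3_class(err, "error")
  expect_length(err$residual_history, 3L)
})

test_that("multigrid agrees with SOR and the direct solver; one level degenerates to SOR", {
  sig <- tiny_sigma()
  S <- edge_conductances(sig)
  ctr <- (sig$grid$shape - 1L) %/% 2L
  src <- dipole_source_term(dipole_source(ctr, "+z"), sig$grid)
  cfg <- solver_config(tol = 1e-7)
  head <- S$diag > 0
  ref <- direct_solve(S, src)
  for (acc in c("cg", "none")) {
    sol <- solve_multigrid(mg_hierarchy(sig, cfg), src, cfg, accel = acc)
    expect_lt(sol$residual, 1e-7)
    r2 <- align_const(ref, sol$phi, head)
    expect_lt(max(abs(sol$phi[head] - r2[head])) / max(abs(r2[head])), 1e-6)
  }
  # a one-level hierarchy with plain iteration produces the same iterates as
  # SOR at the smoother's relaxation factor (pre+post sweeps per cycle)
  cfg1 <- solver_config(tol = 1e-6, mg_levels = 1L, mg_pre = 1L, mg_post = 0L,
                        mg_smooth_omega = 1.4)
  h1 <- mg_hierarchy(sig, cfg1)
  expect_length(h1, 1L)
  sol_mg <- solve_multigrid(h1, src, cfg1, accel = "none")
  sol_sor <- solve_sor(S, src, solver_config(tol = 1e-6, sor_omega = 1.4))
  expect_identical(sol_mg$iterations, sol_sor$iterations)
  expect_equal(sol_mg$phi, sol_sor$phi, tolerance = 1e-12)
})

test_that("V-cycle count is insensitive to grid size on a uniform phantom", {
  counts <- sapply(c(16, 32), function(n) {
    cube <- uniform_cube(n, sigma_value = 1, spacing = 1)
    ctr <- rep(n %/% 2L, 3)
    src <- dipole_source_term(dipole_source(ctr, "+x"), cube$grid)
    cfg <- solver_config(tol = 1e-6)
    solve_multigrid(mg_hierarchy(cube, cfg), src, cfg, accel = "none")$iterations
  })
  expect_lte(abs(counts[2] - counts[1]), 2L)
})

test_that("solutions are linear in the source and superpose", {
  sig <- tiny_sigma()
  hier <- mg_hierarchy(sig)
  cfg <- solver_config(tol = 1e-9)
  ctr <- (sig$grid$shape - 1L) %/% 2L
  s1 <- dipole_source_term(dipole_source(ctr, "+x", current = 1e-3), sig$grid)
  s2 <- dipole_source_term(dipole_source(ctr + c(0, 2, 0), "+z", current = 1e-3), sig$grid)
  p1 <- solve_multigrid(hier, s1, cfg)$phi
  p2 <- solve_multigrid(hier, s2, cfg)$phi
  s1b <- dipole_source_term(dipole_source(ctr, "+x", current = 3e-3), sig$grid)
  p1b <- solve_multigrid(hier, s1b, cfg)$phi
  head <- hier[[1]]$diag > 0
  expect_equal(p1b[head], 3 * p1[head], tolerance = 1e-6)
  both <- spfdeeg:::densify_rhs(s1) + spfdeeg:::densify_rhs(s2)
  p12 <- solve_multigrid(hier, both, cfg)$phi
  expect_equal(p12[head], (p1 + p2)[head], tolerance = 1e-6)
})

test_that("converged solutions satisfy the nodal Kirchhoff balance", {
  sig <- tiny_sigma()
  S <- edge_conductances(sig)
  ctr <- (sig$grid$shape - 1L) %/% 2L
  src <- dipole_source_term(dipole_source(ctr, "+y"), sig$grid)
  sol <- solve_multigrid(mg_hierarchy(sig), src)
  b <- spfdeeg:::densify_rhs(src)
  r <- b - spfdeeg:::spfd_apply(sol$phi, S$Sx, S$Sy, S$Sz, S$diag, S$nd)
  expect_lt(sqrt(sum(r[S$diag > 0]^2)) / sqrt(sum(b^2)), 1e-6)
})

test_that("discrete reciprocity holds between electrode pairs and dipoles", {
  sig <- small_sigma()
  mo <- small_montage()
  gm <- small_gm()
  hier <- small_hier()
  cfg <- solver_config(tol = 1e-9)
  # potential difference at (a, ground) from a dipole equals the dipole-edge
  # potential drop from unit injection at (a, ground), scaled by currents
  a <- 7L
  inj <- solve_multigrid(hier, electrode_pair_source(mo, a, 1e-3), cfg)$phi
  node <- gm$voxel_list[200, ]
  d <- dipole_source(node, "+z", current = 2e-3)
  dip <- solve_multigrid(hier, dipole_source_term(d, sig$grid, gm = gm), cfg)$phi
  lhs <- 1e-3 * (dip[spfdeeg:::node_linear(sig$grid, mo$node_triple[a, ])] -
                 dip[spfdeeg:::node_linear(sig$grid, mo$node_triple[mo$ground, ])])
  rhs <- 2e-3 * (inj[spfdeeg:::node_linear(sig$grid, node + c(0, 0, 1))] -
                 inj[spfdeeg:::node_linear(sig$grid, node)])
  expect_equal(lhs, rhs, tolerance = 1e-5)
})

test_that("current density implements Ohm's law on the grid", {
  cube <- uniform_cube(6, sigma_value = 1, spacing = 1)
  nd <- node_dims(cube$grid)
  # constant potential -> zero current
  j0 <- current_density(array(5, dim = nd), cube)
  expect_true(all(j0$jx == 0) && all(j0$jy == 0) && all(j0$jz == 0))
  # linear ramp phi = -x (volts, x in m) with sigma = 1 -> j = (1, 0, 0)
  xs <- (0:(nd[1] - 1)) * 1e-3  # node x in meters
  phi <- array(rep(-xs, times = prod(nd[2:3])), dim = nd)
  j <- current_density(phi, cube)
  expect_equal(max(abs(j$jx - 1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(j$jy)), 0, tolerance = 1e-9)
  expect_equal(max(abs(j$jz)), 0, tolerance = 1e-9)
  # air voxels carry no current
  sig <- small_sigma()
  hier <- small_hier()
  gm <- small_gm()
  src <- voxel_dipole_term(sig$grid, gm$voxel_list[10, ], "+x", gm = gm)
  sol <- solve_multigrid(hier, src)
  jj <- current_density(sol, sig)
  air <- sig$sigma == 0
  expect_true(all(jj$jx[air] == 0))
  # net flux through a closed interior box away from the source is ~ 0
  ctr <- (sig$grid$shape + 1L) %/% 2L  # R-indexed center voxel
  vox <- gm$voxel_list[10, ] + 1L      # R index of source voxel
  lo <- ctr - 4L; hi <- ctr + 4L       # box around center, source is off-center
  expect_true(any(vox < lo) || any(vox > hi))
  h2 <- (sig$grid$spacing * 1e-3)^2
  flux <- h2 * (sum(jj$jx[hi[1], lo[2]:hi[2], lo[3]:hi[3]]) -
                sum(jj$jx[lo[1], lo[2]:hi[2], lo[3]:hi[3]]) +
                sum(jj$jy[lo[1]:hi[1], hi[2], lo[3]:hi[3]]) -
                sum(jj$jy[lo[1]:hi[1], lo[2], lo[3]:hi[3]]) +
                sum(jj$jz[lo[1]:hi[1], lo[2]:hi[2], hi[3]]) -
                sum(jj$jz[lo[1]:hi[1], lo[2]:hi[2], lo[3]]))
  expect_lt(abs(flux), 0.05 * 1e-3)  # well under the 1 mA source scale
})
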