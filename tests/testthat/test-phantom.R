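test_that("conductivity table maps all fourteen tissues to their S/m values", {
  tab <- conductivity_table()
  expect_length(tab, 14L)
  expected <- c("skin" = 0.1000, "muscle" = 0.2020, "fat" = 0.0377,
                "bone (cort.)" = 0.0200, "bone (canc.)" = 0.0756,
                "cartilage" = 0.1611, "gray matter" = 0.0275,
                "white matter" = 0.0277, "cerebellum" = 0.0475,
                "csf" = 2.0000, "humor" = 1.5000, "blood" = 0.6999,
                "mucous membrane" = 0.0004, "dura" = 0.5003)
  expect_identical(tab[names(expected)], expected)
})

test_that("layered sphere labels voxels by innermost containing shell", {
  lab <- make_layered_sphere(spacing = 2, radii_mm = c(85, 78, 72, 70, 55))
  grid <- lab$grid
  ctr_idx <- (grid$shape - 1L) / 2L
  # center voxel is white matter (innermost shell)
  expect_identical(lab$labels[ctr_idx[1] + 1, ctr_idx[2] + 1, ctr_idx[3] + 1], 5L)
  # all voxels beyond the outer radius are air
  ijk <- arrayInd(seq_along(lab$labels), dim(lab$labels)) - 1L
  r <- sqrt(rowSums(voxel_center(grid, ijk)^2))
  expect_true(all(lab$labels[r > 85] == 0L))
  expect_true(all(lab$labels[r < 55] == 5L))
})

test_that("CSF shell voxel count matches brute-force voxel-center test", {
  lab <- small_labels()  # radii 30,26,22,20,12: CSF shell 20 <= r < 22
  ijk <- arrayInd(seq_along(lab$labels), dim(lab$labels)) - 1L
  r <- sqrt(rowSums(voxel_center(lab$grid, ijk)^2))
  expect_identical(sum(lab$labels == 3L), sum(r >= 20 & r < 22))
})

test_that("degenerate sphere geometries are rejected with the shell named", {
  expect_error(make_layered_sphere(radii_mm = c(85, 86, 72, 70, 55)),
               "strictly decreasing")
  expect_error(
    make_layered_sphere(spacing = 2, radii_mm = c(30, 26, 22, 21, 12)),
    "csf.*thinner|thinner.*csf", ignore.case = TRUE)
})

test_that("assign_conductivity applies the table and zeroes air", {
  lab <- small_labels()
  sig <- assign_conductivity(lab)
  expect_equal(unique(sig$sigma[lab$labels == 3L]), 2.0000)  # CSF
  expect_equal(unique(sig$sigma[lab$labels == 4L]), 0.0275)  # gray
  expect_true(all(sig$sigma[lab$labels == 0L] == 0))
  bad <- lab
  bad$label_names[1] <- "unobtainium"
  expect_error(assign_conductivity(bad), "unobtainium")
})

test_that("homogeneous model fills the head with one value", {
  lab <- small_labels()
  hom <- make_homogeneous(lab)
  expect_equal(unique(hom$sigma[lab$labels > 0L]), 0.0275)
  expect_identical(sum(hom$sigma > 0), sum(lab$labels > 0L))
})

test_that("CSF-insert differs from homogeneous exactly on CSF voxels", {
  lab <- small_labels()
  hom <- make_homogeneous(lab)
  csf <- make_csf_insert(lab)
  expect_equal(unique(csf$sigma[lab$labels == 3L]), 2.0000)
  expect_equal(unique(csf$sigma[lab$labels == 1L]), 0.0275)  # skin stays gray-valued
  expect_identical(sum(csf$sigma != hom$sigma), sum(lab$labels == 3L))
  # without a CSF shell the model degenerates to homogeneous, with a warning
  lab2 <- make_layered_sphere(spacing = 2, radii_mm = c(20, 15),
                              tissue_order = c("skin", "gray matter"))
  lab2$label_names <- c(lab2$label_names, "99" = "csf")
  names(lab2$label_names) <- c("1", "2", "99")
  expect_warning(csf2 <- make_csf_insert(lab2), "homogeneous")
  expect_equal(csf2$sigma, make_homogeneous(lab2)$sigma)
})

test_that("segmentation-free smoothing conserves mass, reduces jumps, keeps mask", {
  lab <- small_labels()
  sig <- assign_conductivity(lab)
  mask <- head_mask(lab)
  sm <- make_segmentation_free(sig, smooth_fwhm_mm = 4)
  # identity at fwhm 0
  expect_identical(make_segmentation_free(sig, 0)$sigma, sig$sigma)
  # head mask unchanged, air untouched
  expect_identical(sm$sigma > 0, mask)
  # conductivity mass over the head approximately conserved (the boundary
  # renormalization trades exact conservation for the range guarantee)
  expect_equal(sum(sm$sigma[mask]), sum(sig$sigma[mask]), tolerance = 0.01)
  # range preserved
  expect_gte(min(sm$sigma[mask]), min(sig$sigma[mask]))
  expect_lte(max(sm$sigma[mask]), max(sig$sigma[mask]))
  # max 6-neighbor jump strictly decreases on a two-tissue phantom
  lab2 <- make_layered_sphere(spacing = 2, radii_mm = c(24, 14),
                              tissue_order = c("csf", "gray matter"))
  s2 <- assign_conductivity(lab2)
  sm2 <- make_segmentation_free(s2, smooth_fwhm_mm = 4)
  max_jump <- function(a, m) {
    mj <- 0
    for (ax in 1:3) {
      d <- dim(a)
      i1 <- lapply(d, seq_len); i1[[ax]] <- seq_len(d[ax] - 1L)
      i2 <- i1; i2[[ax]] <- i1[[ax]] + 1L
      both <- m[i1[[1]], i1[[2]], i1[[3]]] & m[i2[[1]], i2[[2]], i2[[3]]]
      dj <- abs(a[i1[[1]], i1[[2]], i1[[3]]] - a[i2[[1]], i2[[2]], i2[[3]]])
      mj <- max(mj, dj[both])
    }
    mj
  }
  m2 <- head_mask(lab2)
  expect_lt(max_jump(sm2$sigma, m2), max_jump(s2$sigma, m2))
  # fwhm -> 0 converges to the segmented input in sup norm
  errs <- sapply(c(2, 1, 0.25), function(w)
    max(abs(make_segmentation_free(s2, w)$sigma - s2$sigma)))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-6)
})

test_that("all four model variants share the head mask and grid", {
  lab <- small_labels()
  models <- list(assign_conductivity(lab), make_homogeneous(lab),
                 make_csf_insert(lab),
                 make_segmentation_free(assign_conductivity(lab)))
  masks <- lapply(models, function(m) m$sigma > 0)
  for (k in 2:4) {
    expect_identical(masks[[k]], masks[[1]])
    expect_identical(models[[k]]$grid, models[[1]]$grid)
  }
})

test_that("gray-matter index is deterministic and invertible", {
  lab <- small_labels()
  gm <- gray_matter_index(lab)
  # N equals brute-force count of gray-shell voxels
  expect_identical(gm$n, sum(lab$labels == 4L))
  expect_identical(nrow(gm$voxel_list), gm$n)
  # lexicographic in (i, j, k)
  o <- order(gm$voxel_list[, 1], gm$voxel_list[, 2], gm$voxel_list[, 3])
  expect_identical(o, seq_len(gm$n))
  # reverse map composed with voxel_list is the identity
  idx <- gm$voxel_list[c(1, 17, gm$n), , drop = FALSE] + 1L
  expect_identical(gm$reverse[cbind(idx[, 1], idx[, 2], idx[, 3])],
                   c(1L, 17L, gm$n))
  # missing gray matter errors
  lab2 <- make_layered_sphere(spacing = 2, radii_mm = c(20, 15),
                              tissue_order = c("skin", "white matter"))
  expect_error(gray_matter_index(lab2), "gray")
})
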