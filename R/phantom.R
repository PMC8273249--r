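#' Tissue conductivities (S/m)
#'
#' The default per-tissue conductivity table used by all phantom builders,
#' taken from 4-Cole-Cole dispersion values at EEG-relevant (quasi-static)
#' frequency; skin is set to 0.1 S/m as the practical whole-skin value.
#'
#' @return Named numeric vector, tissue name -> conductivity in S/m.
#' @export
conductivity_table <- function() {
  c("skin"            = 0.1000,
    "muscle"          = 0.2020,
    "fat"             = 0.0377,
    "bone (cort.)"    = 0.0200,
    "bone (canc.)"    = 0.0756,
    "cartilage"       = 0.1611,
    "gray matter"     = 0.0275,
    "white matter"    = 0.0277,
    "cerebellum"      = 0.0475,
    "csf"             = 2.0000,
    "humor"           = 1.5000,
    "blood"           = 0.6999,
    "mucous membrane" = 0.0004,
    "dura"            = 0.5003)
}

#' Layered-sphere head phantom
#'
#' Builds a synthetic multi-shell spherical head: concentric shells labeled
#' outward-in (default skin, cortical bone, CSF, gray matter, white matter),
#' voxelized on an isotropic grid. A voxel takes the label of the innermost
#' shell whose radius its center falls inside; centers beyond the outermost
#' radius are air (label 0). The grid is sized symmetrically so the sphere
#' center lies exactly on a voxel center at the world origin, which keeps the
#' phantom mirror-symmetric about all three axes.
#'
#' @param spacing voxel edge in mm (default 2; 0.5 reproduces full scale).
#' @param radii_mm strictly decreasing shell radii, outermost first
#'   (default `c(85, 78, 72, 70, 55)`).
#' @param tissue_order tissue names outermost first, same length as `radii_mm`.
#' @param margin extra air voxels beyond the outer radius on each side.
#' @return A `tissue_volume`: list with `grid`, integer `labels` array
#'   (0 = air, 1..K = shells outermost first), and `label_names`.
#' @examples
#' lab <- make_layered_sphere(spacing = 2, radii_mm = c(30, 26, 22, 20, 12))
#' sigma <- assign_conductivity(lab)   # CSF voxels at 2.0 S/m, air at 0
#' gm <- gray_matter_index(lab)
#' gm$n                                # number of gray-matter voxels
#' @export
make_layered_sphere <- function(spacing = 2,
                                radii_mm = c(85, 78, 72, 70, 55),
                                tissue_order = c("skin", "bone (cort.)", "csf",
                                                 "gray matter", "white matter"),
                                margin = 1L) {
  stopifnot(length(radii_mm) >= 2, length(tissue_order) == length(radii_mm),
            spacing > 0)
  if (any(diff(radii_mm) >= 0))
    stop("radii_mm must be strictly decreasing (outermost shell first)")
  thick <- c(-diff(radii_mm), radii_mm[length(radii_mm)])
  thin <- which(thick < spacing - 1e-9)
  if (length(thin))
    stop(sprintf("shell '%s' is thinner (%.3g mm) than one voxel at %g mm spacing",
                 tissue_order[thin[1]], thick[thin[1]], spacing))

  n_half <- ceiling(radii_mm[1] / spacing) + as.integer(margin)
  n <- 2L * n_half + 1L
  grid <- voxel_grid(c(n, n, n), spacing, origin = rep(-spacing * n_half, 3))

  ax <- spacing * (seq_len(n) - 1L - n_half)  # voxel-center coordinates
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  labels <- array(0L, dim = c(n, n, n))
  for (s in seq_along(radii_mm)) {            # innermost shell wins
    labels[r2 < radii_mm[s]^2] <- s
  }
  structure(list(grid = grid, labels = labels,
                 label_names = stats::setNames(tissue_order, seq_along(tissue_order))),
            class = "tissue_volume")
}

#' @export
print.tissue_volume <- function(x, ...) {
  cat(sprintf("<tissue_volume> %d x %d x %d voxels @ %g mm; %d head voxels, %d tissues\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], x$grid$spacing,
              sum(x$labels > 0L), length(x$label_names)))
  invisible(x)
}

#' Logical head mask (labels > 0)
#' @param labels a `tissue_volume`.
#' @return logical array over voxels.
#' @export
head_mask <- function(labels) labels$labels > 0L

new_conductivity_volume <- function(grid, sigma) {
  stopifnot(all(is.finite(sigma)), all(sigma >= 0))
  structure(list(grid = grid, sigma = sigma), class = "conductivity_volume")
}

#' @export
print.conductivity_volume <- function(x, ...) {
  hd <- x$sigma > 0
  cat(sprintf("<conductivity_volume> %d x %d x %d voxels @ %g mm; sigma in [%.4g, %.4g] S/m over %d head voxels\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3], x$grid$spacing,
              if (any(hd)) min(x$sigma[hd]) else NA, max(x$sigma), sum(hd)))
  invisible(x)
}

#' Map tissue labels to conductivities
#'
#' @param labels a `tissue_volume`.
#' @param table named conductivity vector (S/m), default [conductivity_table()].
#' @return A `conductivity_volume` with air voxels at exactly 0 S/m.
#' @export
assign_conductivity <- function(labels, table = conductivity_table()) {
  nm <- labels$label_names
  missing <- nm[!(nm %in% names(table))]
  if (length(missing))
    stop("no conductivity for label(s): ", paste(missing, collapse = ", "))
  lut <- c(0, unname(table[nm]))  # index 1 = air
  sigma <- array(lut[labels$labels + 1L], dim = dim(labels$labels))
  new_conductivity_volume(labels$grid, sigma)
}

#' Homogeneous head model
#'
#' Every head voxel gets a single conductivity (default: gray matter,
#' 0.0275 S/m); air stays 0.
#'
#' @param labels a `tissue_volume`.
#' @param sigma_value conductivity in S/m (> 0).
#' @return A `conductivity_volume`.
#' @export
make_homogeneous <- function(labels, sigma_value = 0.0275) {
  stopifnot(sigma_value > 0)
  sigma <- array(0, dim = dim(labels$labels))
  sigma[labels$labels > 0L] <- sigma_value
  new_conductivity_volume(labels$grid, sigma)
}

#' CSF-insert head model
#'
#' Homogeneous gray-matter head with the CSF compartment restored to its
#' tabulated conductivity: isolates the effect of the thin high-conductivity
#' CSF layer from all other tissue contrasts.
#'
#' @inheritParams assign_conductivity
#' @param csf_label tissue name of the CSF class (default "csf").
#' @return A `conductivity_volume`.
#' @export
make_csf_insert <- function(labels, table = conductivity_table(),
                            csf_label = "csf") {
  sigma <- make_homogeneous(labels, table[["gray matter"]])
  csf_id <- as.integer(names(labels$label_names)[labels$label_names == csf_label])
  if (!length(csf_id) || !any(labels$labels == csf_id)) {
    warning("no CSF voxels present; model degenerates to homogeneous")
    return(sigma)
  }
  sigma$sigma[labels$labels %in% csf_id] <- table[[csf_label]]
  sigma
}

#' Segmentation-free (smoothed-conductivity) head model
#'
#' Emulates a volume conductor whose conductivity varies smoothly across
#' tissue boundaries instead of jumping at segmentation edges: the input
#' conductivity is convolved with an isotropic Gaussian restricted to head
#' voxels (normalized masked convolution, so air never bleeds in). Each
#' output voxel is a convex combination of input head conductivities: the
#' head mask is unchanged and values stay within the input's head-voxel
#' range exactly; the total conductivity mass over the head is conserved
#' only approximately (boundary renormalization trades exact mass
#' conservation for the range guarantee).
#'
#' @param sigma a `conductivity_volume` (typically from [assign_conductivity()]).
#' @param smooth_fwhm_mm Gaussian full-width at half-maximum in mm (default 2;
#'   0 returns the input unchanged).
#' @return A `conductivity_volume`.
#' @export
make_segmentation_free <- function(sigma, smooth_fwhm_mm = 2) {
  stopifnot(smooth_fwhm_mm >= 0)
  if (smooth_fwhm_mm == 0) return(sigma)
  h <- sigma$grid$spacing
  sd_vox <- smooth_fwhm_mm / (2 * sqrt(2 * log(2))) / h
  half <- max(1L, ceiling(3 * sd_vox))
  kern <- stats::dnorm(seq(-half, half), sd = sd_vox)
  kern <- kern / sum(kern)

  mask <- sigma$sigma > 0
  num <- sigma$sigma
  den <- array(as.numeric(mask), dim = dim(mask))
  for (axis in 1:3) {
    num <- convolve_axis(num, kern, axis)
    den <- convolve_axis(den, kern, axis)
  }
  out <- array(0, dim = dim(mask))
  # convex combination of head-voxel conductivities: stays within the input
  # head range by construction, and air never bleeds in
  out[mask] <- num[mask] / den[mask]
  new_conductivity_volume(sigma$grid, out)
}

# separable 1-D convolution along one axis with zero padding
convolve_axis <- function(a, kern, axis) {
  d <- dim(a)
  half <- (length(kern) - 1L) / 2L
  out <- array(0, dim = d)
  for (t in seq_along(kern)) {
    off <- t - 1L - half
    w <- kern[t]
    if (w == 0) next
    src_lo <- max(1L, 1L + off); src_hi <- min(d[axis], d[axis] + off)
    if (src_lo > src_hi) next
    dst_lo <- src_lo - off; dst_hi <- src_hi - off
    idx_dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idx_src <- idx_dst
    idx_dst[[axis]] <- dst_lo:dst_hi
    idx_src[[axis]] <- src_lo:src_hi
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      w * a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  out
}

#' Gray-matter voxel index
#'
#' Enumerates the N gray-matter voxels in a deterministic lexicographic order
#' (by i, then j, then k; 0-based) and builds the forward and reverse maps
#' used to address lead-field columns.
#'
#' @param labels a `tissue_volume`.
#' @param gray_label tissue name of the gray-matter class.
#' @return A `gm_index`: `mask` (logical array), `voxel_list` (N x 3 matrix of
#'   0-based indices), `reverse` (integer array, 0 off-gray), `n`.
#' @export
gray_matter_index <- function(labels, gray_label = "gray matter") {
  gid <- as.integer(names(labels$label_names)[labels$label_names == gray_label])
  if (!length(gid)) stop("no gray-matter class in label_names")
  mask <- labels$labels %in% gid
  dim(mask) <- dim(labels$labels)
  if (!any(mask)) stop("no gray-matter voxels present")
  w <- which(mask)
  ijk <- arrayInd(w, dim(mask)) - 1L          # 0-based
  o <- order(ijk[, 1], ijk[, 2], ijk[, 3])
  ijk <- ijk[o, , drop = FALSE]
  rev <- array(0L, dim = dim(mask))
  rev[w[o]] <- seq_along(w)
  structure(list(mask = mask, voxel_list = ijk, reverse = rev,
                 n = nrow(ijk), grid = labels$grid),
            class = "gm_index")
}

#' @export
print.gm_index <- function(x, ...) {
  cat(sprintf("<gm_index> N = %d gray-matter voxels\n", x$n))
  invisible(x)
}
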