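#' Angular positions of the 10-20 / 10-10 electrode systems
#'
#' Generates electrode directions from the proportional placement scheme on
#' an idealized spherical head: the nasion-inion and ear-to-ear arcs are
#' divided in 10% steps (18 degrees). The head circumference ring (Fpz,
#' Fp1/2, ..., O1/2, Oz) sits 10% above the nasion-inion plane; interior rows
#' interpolate along great circles between the midline electrode and its ring
#' end; "9/10"-suffixed electrodes (and Nz/Iz) lie on the nasion-inion plane
#' itself. Coordinate frame: +x right, +y anterior (nasion), +z superior.
#'
#' @param system `"10-20"` (21 electrodes) or `"10-10"` (75 electrodes).
#' @return data.frame with `name` and unit direction columns `ux, uy, uz`.
#' @export
montage_directions <- function(system = c("10-10", "10-20")) {
  system <- match.arg(system)
  deg <- pi / 180
  # unit vector from inclination alpha (from vertex) and azimuth (from +y
  # nasion toward +x right)
  uvec <- function(alpha, azim)
    c(sin(alpha * deg) * sin(azim * deg),
      sin(alpha * deg) * cos(azim * deg),
      cos(alpha * deg))
  slerp <- function(a, b, f) {
    w <- acos(pmin(1, sum(a * b)))
    v <- (sin((1 - f) * w) * a + sin(f * w) * b) / sin(w)
    v / sqrt(sum(v^2))
  }

  pts <- list()
  add <- function(name, v) pts[[name]] <<- v

  # ring at 10% above the nasion-inion plane (inclination 72)
  ring_az <- c(Fpz = 0, Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
               TP8 = 108, P8 = 126, PO8 = 144, O2 = 162, Oz = 180,
               O1 = -162, PO7 = -144, P7 = -126, TP7 = -108, T7 = -90,
               FT7 = -72, F7 = -54, AF7 = -36, Fp1 = -18)
  for (nm in names(ring_az)) add(nm, uvec(72, ring_az[[nm]]))

  # midline between Fpz and Oz
  mid <- c(AFz = 54, Fz = 36, FCz = 18, Cz = 0)
  for (nm in names(mid)) add(nm, uvec(mid[[nm]], 0))
  midb <- c(CPz = 18, Pz = 36, POz = 54)
  for (nm in names(midb)) add(nm, uvec(midb[[nm]], 180))

  # interior rows: great-circle interpolation midline -> ring electrode
  rows <- list(
    F  = list(mid = "Fz",  left = "F7",  right = "F8",  f = c(0.25, 0.5, 0.75),
              lab = c("1", "3", "5")),
    FC = list(mid = "FCz", left = "FT7", right = "FT8", f = c(0.25, 0.5, 0.75),
              lab = c("1", "3", "5")),
    C  = list(mid = "Cz",  left = "T7",  right = "T8",  f = c(0.25, 0.5, 0.75),
              lab = c("1", "3", "5")),
    CP = list(mid = "CPz", left = "TP7", right = "TP8", f = c(0.25, 0.5, 0.75),
              lab = c("1", "3", "5")),
    P  = list(mid = "Pz",  left = "P7",  right = "P8",  f = c(0.25, 0.5, 0.75),
              lab = c("1", "3", "5")),
    AF = list(mid = "AFz", left = "AF7", right = "AF8", f = 0.5, lab = "3"),
    PO = list(mid = "POz", left = "PO7", right = "PO8", f = 0.5, lab = "3"))
  for (rn in names(rows)) {
    rw <- rows[[rn]]
    for (t in seq_along(rw$f)) {
      add(paste0(rn, rw$lab[t]),                        # left: odd numbers
          slerp(pts[[rw$mid]], pts[[rw$left]], rw$f[t]))
      add(paste0(rn, as.character(as.integer(rw$lab[t]) + 1L)),  # right: even
          slerp(pts[[rw$mid]], pts[[rw$right]], rw$f[t]))
    }
  }

  # nasion-inion plane (inclination 90)
  plane_az <- c(Nz = 0, F10 = 54, FT10 = 72, T10 = 90, TP10 = 108, P10 = 126,
                PO10 = 144, Iz = 180, PO9 = -144, P9 = -126, TP9 = -108,
                T9 = -90, FT9 = -72, F9 = -54)
  for (nm in names(plane_az)) add(nm, uvec(90, plane_az[[nm]]))

  sel_1020 <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T7", "C3", "Cz", "C4", "T8",
                "P7", "P3", "Pz", "P4", "P8", "O1", "Oz", "O2")
  # canonical order: anterior to posterior, left to right
  order_1010 <- c("Nz", "Fp1", "Fpz", "Fp2",
                  "AF7", "AF3", "AFz", "AF4", "AF8",
                  "F9", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "F10",
                  "FT9", "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8", "FT10",
                  "T9", "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8", "T10",
                  "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
                  "P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10",
                  "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
                  "O1", "Oz", "O2", "Iz")
  names_out <- if (system == "10-20") sel_1020 else order_1010
  u <- t(vapply(names_out, function(nm) pts[[nm]], numeric(3)))
  data.frame(name = names_out, ux = u[, 1], uy = u[, 2], uz = u[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Place an electrode montage on the phantom scalp
#'
#' Electrode directions come from the proportional angular scheme
#' ([montage_directions()]); each electrode is snapped to the scalp-surface
#' grid node (head node with an adjacent air voxel) whose direction from the
#' head centroid is closest to the electrode's.
#'
#' @param labels a `tissue_volume`.
#' @param system `"10-10"` or `"10-20"`.
#' @param ground electrode name or index used as ground/reference (default:
#'   the first electrode in canonical order).
#' @return An `electrode_montage`: `names`, snapped `positions` (mm, n x 3),
#'   linear `node_index` into the node array, `ground`, `system`, `center`
#'   (head centroid, mm), and the grid.
#' @examples
#' lab <- make_layered_sphere(spacing = 2, radii_mm = c(30, 26, 22, 20, 12))
#' mo <- place_montage(lab, "10-20")
#' mean_interelectrode_distance(mo)
#' @export
place_montage <- function(labels, system = c("10-10", "10-20"), ground = 1L) {
  system <- match.arg(system)
  dirs <- montage_directions(system)
  grid <- labels$grid
  mask <- head_mask(labels)
  if (!any(mask)) stop("empty head mask")

  ctr <- colMeans(voxel_center(grid, arrayInd(which(mask), dim(mask)) - 1L))

  surf <- surface_nodes(mask)
  pos <- node_coord(grid, surf)
  rel <- sweep(pos, 2, ctr, `-`)
  rad <- sqrt(rowSums(rel^2))
  reln <- rel / rad

  u <- as.matrix(dirs[, c("ux", "uy", "uz")])
  score <- reln %*% t(u)                       # cosine with each electrode
  node_row <- integer(nrow(u))
  for (e in seq_len(nrow(u))) {
    best <- which(score[, e] > max(score[, e]) - 1e-12)
    node_row[e] <- best[which.max(rad[best])]
  }
  if (anyDuplicated(node_row))
    stop("electrodes snapped to the same scalp node; use a finer grid spacing")

  if (is.character(ground)) ground <- match(ground, dirs$name)
  ground <- as.integer(ground)
  stopifnot(!is.na(ground), ground >= 1, ground <= nrow(u))

  structure(list(names = dirs$name,
                 positions = pos[node_row, , drop = FALSE],
                 node_index = node_linear(grid, surf[node_row, , drop = FALSE]),
                 node_triple = surf[node_row, , drop = FALSE],
                 ground = ground,
                 system = system,
                 center = ctr,
                 grid = grid),
            class = "electrode_montage")
}

# 0-based triples of nodes touching both head and non-head voxels
surface_nodes <- function(mask) {
  sh <- dim(mask)
  nd <- sh + 1L
  P <- array(FALSE, dim = sh + 2L)
  P[1L + seq_len(sh[1]), 1L + seq_len(sh[2]), 1L + seq_len(sh[3])] <- mask
  any_h <- array(FALSE, dim = nd); all_h <- array(TRUE, dim = nd)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    sl <- P[di + seq_len(nd[1]), dj + seq_len(nd[2]), dk + seq_len(nd[3])]
    any_h <- any_h | sl
    all_h <- all_h & sl
  }
  surf <- any_h & !all_h
  arrayInd(which(surf), nd) - 1L
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat(sprintf("<electrode_montage> %s system, %d electrodes, ground %s\n",
              x$system, length(x$names), x$names[x$ground]))
  invisible(x)
}

#' Mean inter-electrode distance
#'
#' Mean over electrodes of the Euclidean distance to the nearest other
#' electrode, in mm.
#'
#' @param montage an `electrode_montage` (or a bare n x 3 position matrix).
#' @return scalar mm.
#' @export
mean_interelectrode_distance <- function(montage) {
  pos <- if (inherits(montage, "electrode_montage")) montage$positions else montage
  stopifnot(nrow(pos) >= 2)
  d <- as.matrix(stats::dist(pos))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Ground-referenced scalp potentials
#'
#' Reads the node potentials at the montage electrodes and subtracts the
#' ground electrode's potential, so the ground entry is exactly 0.
#'
#' @param phi an `spfd_solution` or bare node potential array.
#' @param montage an `electrode_montage`.
#' @return A named `scalp_potentials` vector of length M (volts) with
#'   attribute `ground`.
#' @export
reference_potentials <- function(phi, montage) {
  if (inherits(phi, "spfd_solution")) phi <- phi$phi
  v <- phi[montage$node_index]
  v <- v - v[montage$ground]
  structure(stats::setNames(v, montage$names), ground = montage$ground,
            class = "scalp_potentials")
}

#' @export
print.scalp_potentials <- function(x, ...) {
  cat(sprintf("<scalp_potentials> %d electrodes, range [%.3g, %.3g] V\n",
              length(x), min(x), max(x)))
  invisible(x)
}
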