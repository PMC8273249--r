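#' Write a label or conductivity volume as NIfTI-1
#'
#' The voxel grid goes into the sform affine: `diag(spacing)` with the origin
#' (mm coordinate of voxel (0,0,0)) as offset. Label volumes are stored as
#' integers, conductivity as floating point.
#'
#' @param x a `tissue_volume` or `conductivity_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  grid <- x$grid
  arr <- if (inherits(x, "tissue_volume")) x$labels else x$sigma
  img <- RNifti::asNifti(arr)
  aff <- diag(c(rep(grid$spacing, 3), 1))
  aff[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' Spacing and origin are taken from the affine, which must be axis-aligned
#' and isotropic. Integer data become a `tissue_volume` (with
#' `label_names` supplied or defaulted to `tissue<k>`), floating-point data a
#' `conductivity_volume`.
#'
#' @param path NIfTI file.
#' @param label_names optional named character vector (label id -> tissue
#'   name) for integer volumes.
#' @return A `tissue_volume` or `conductivity_volume`.
#' @export
read_volume <- function(path, label_names = NULL) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  R3 <- aff[1:3, 1:3]
  sp <- diag(R3)
  if (max(abs(R3 - diag(sp))) > 1e-6 * max(abs(sp)))
    stop("NIfTI affine is sheared or rotated; only axis-aligned volumes are supported")
  if (max(abs(sp - sp[1])) > 1e-6 * abs(sp[1]) || sp[1] <= 0)
    stop("NIfTI affine is non-isotropic; only isotropic voxels are supported")
  arr <- as.array(img)
  if (anyNA(arr) || !all(is.finite(arr))) stop("volume contains NaN/Inf voxels")
  grid <- voxel_grid(dim(arr), sp[1], origin = aff[1:3, 4])
  dt <- RNifti::niftiHeader(img)$datatype
  if (dt %in% c(2L, 4L, 8L, 256L, 512L, 768L)) {  # integer datatypes
    labs <- array(as.integer(arr), dim = dim(arr))
    ids <- sort(setdiff(unique(as.vector(labs)), 0L))
    if (is.null(label_names))
      label_names <- stats::setNames(paste0("tissue", ids), ids)
    structure(list(grid = grid, labels = labs, label_names = label_names),
              class = "tissue_volume")
  } else {
    new_conductivity_volume(grid, array(as.numeric(arr), dim = dim(arr)))
  }
}

#' Write electrode positions as CSV
#'
#' Columns `name,x_mm,y_mm,z_mm` (plus the ground electrode flagged in a
#' `ground` column).
#'
#' @param montage an `electrode_montage`.
#' @param path output CSV path.
#' @export
write_electrodes_csv <- function(montage, path) {
  df <- data.frame(name = montage$names,
                   x_mm = montage$positions[, 1],
                   y_mm = montage$positions[, 2],
                   z_mm = montage$positions[, 3],
                   ground = seq_along(montage$names) == montage$ground)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report
#'
#' Per-trial records go to `<prefix>_trials.csv`; summary tables to
#' `<prefix>_summary.json`.
#'
#' @param report an `eval_report`.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(report, prefix) {
  f1 <- paste0(prefix, "_trials.csv")
  utils::write.csv(report$trials, f1, row.names = FALSE)
  s <- summarize_report(report)
  f2 <- paste0(prefix, "_summary.json")
  jsonlite::write_json(list(summary = s$summary, cumulative = s$cumulative,
                            seed = report$seed, n_trials = report$n_trials),
                       f2, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(f1, f2))
}

#' Write a run manifest
#'
#' Records the package version, seed, configuration, and an MD5 digest of
#' every output file, so deterministic stages can be verified to reproduce
#' bit-identical outputs.
#'
#' @param path manifest JSON path.
#' @param config list of stage configuration values.
#' @param seed integer seed used (or `NULL`).
#' @param files character vector of output files to digest.
#' @export
write_manifest <- function(path, config, seed, files) {
  digests <- as.list(tools::md5sum(files[file.exists(files)]))
  jsonlite::write_json(list(package = "spfdeeg",
                            version = as.character(utils::packageVersion("spfdeeg")),
                            seed = seed, config = config, files = digests),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
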