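#' Read a NIfTI-1 volume
#'
#' Returns a plain 3D array with the voxel spacing attached as the
#' `spacing_mm` attribute and the full affine as the `affine` attribute.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return 3D array with `spacing_mm` and `affine` attributes.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim(img)[1:3])
  out <- as_volume(a, RNifti::pixdim(img)[1:3])
  attr(out, "affine") <- unclass(RNifti::xform(img))
  out
}

#' Write a volume as NIfTI-1
#'
#' The affine is `diag(spacing)` with a fixed origin at voxel (0,0,0), the
#' convention used throughout: the voxel at 0-based index `(i,j,k)` has its
#' center at `(i,j,k) * spacing` mm. Integer-valued data round-trip exactly;
#' scalar volumes round-trip to float32 precision.
#'
#' @param x 3D array (logical volumes are written as 0/1 integers).
#' @param path output path.
#' @param spacing_mm voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing_mm = NULL) {
  s <- spacing_of(x, spacing_mm)
  a <- x
  attributes(a) <- list(dim = dim(x))
  if (is.logical(a)) a <- array(as.integer(a), dim(a))
  datatype <- if (is.integer(a)) "int32" else "float"
  attr(a, "pixdim") <- s
  RNifti::writeNifti(RNifti::asNifti(a), path, datatype = datatype)
  invisible(path)
}

#' Check that volumes share a grid
#'
#' Co-analyzed volumes must agree in array shape and, when both carry an
#' affine, in every affine entry to within `tol`.
#'
#' @param a,b volumes from [read_volume()] (or arrays with attributes).
#' @param name_a,name_b names used in error messages.
#' @param tol absolute tolerance on affine entries (default 1e-4).
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
check_grid_compatible <- function(a, b, name_a = "volume A", name_b = "volume B",
                                  tol = 1e-4) {
  check_same_grid(a, b, name_a, name_b)
  af_a <- attr(a, "affine"); af_b <- attr(b, "affine")
  if (!is.null(af_a) && !is.null(af_b)) {
    if (max(abs(af_a - af_b)) > tol)
      stop(sprintf("affine mismatch beyond %g between %s and %s", tol,
                   name_a, name_b))
  } else {
    sa <- attr(a, "spacing_mm"); sb <- attr(b, "spacing_mm")
    if (!is.null(sa) && !is.null(sb) && max(abs(sa - sb)) > tol)
      stop(sprintf("voxel spacing mismatch between %s and %s", name_a, name_b))
  }
  invisible(TRUE)
}

#' Write all phantom volumes, the truth record and the subject metadata
#'
#' Volumes go out as NIfTI-1, the truth record as JSON (voxel indices are
#' 1-based linear indices into the array), and the lesion table as CSV.
#'
#' @param phantom a [make_phantom()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- phantom$spacing_mm
  write_volume(phantom$tissue, file.path(dir, "tissue.nii.gz"), s)
  write_volume(phantom$regions, file.path(dir, "regions.nii.gz"), s)
  write_volume(phantom$lobar_wm, file.path(dir, "lobar_wm.nii.gz"), s)
  write_volume(phantom$wmh, file.path(dir, "wmh.nii.gz"), s)
  write_volume(phantom$brain, file.path(dir, "brain.nii.gz"), s)
  for (m in names(phantom$metrics))
    write_volume(phantom$metrics[[m]], file.path(dir, paste0(m, ".nii.gz")), s)
  for (c in 1:3)
    write_volume(phantom$field$dir[, , , c],
                 file.path(dir, sprintf("field_dir%d.nii.gz", c)), s)
  write_volume(phantom$field$dispersion_deg, file.path(dir, "field_dispersion.nii.gz"), s)
  truth <- list(connected_idx = which(phantom$truth$connected),
                per_lesion_idx = phantom$truth$per_lesion,
                effects = as.list(phantom$truth$effects),
                timepoint = phantom$timepoint)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(phantom$truth$lesion_table, file.path(dir, "lesions.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Serialize an ROI set with its thresholds and sizes
#'
#' ROI masks go out as NIfTI; thresholds and surface sizes go into a JSON
#' sidecar.
#'
#' @param roi_set a [threshold_roi_set()] result.
#' @param dir output directory.
#' @param prefix filename prefix (e.g. the parcel name).
#' @param spacing_mm voxel size in mm.
#' @return `dir`, invisibly.
#' @export
write_roi_set <- function(roi_set, dir, prefix = "roi", spacing_mm) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  side <- list()
  for (lev in names(roi_set$levels)) {
    l <- roi_set$levels[[lev]]
    write_volume(l$mask, file.path(dir, sprintf("%s_%s.nii.gz", prefix, lev)),
                 spacing_mm)
    side[[lev]] <- list(threshold = l$threshold, size = l$size)
  }
  jsonlite::write_json(side, file.path(dir, paste0(prefix, "_thresholds.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read or write a run configuration as YAML
#'
#' @param config a list (e.g. from [run_config()]).
#' @param path file path.
#' @return `read_run_config` returns the list; `write_run_config` returns
#'   `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  cfg <- config
  cfg$phantom <- unclass(cfg$phantom)
  cfg$phantom$group_ratio_means <- NULL   # matrices do not survive YAML cleanly
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
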