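#' Euclidean distance to the ventricles
#'
#' Exact per-voxel Euclidean distance (mm) to the nearest ventricle voxel
#' center, honoring anisotropic voxel spacing; 0 inside the ventricle mask.
#' Distances are voxel-center to voxel-center.
#'
#' @param ventricle_mask logical or 0/1 3D array.
#' @param spacing_mm voxel size in mm (length 3 or scalar); taken from the
#'   volume's `spacing_mm` attribute when omitted.
#' @return 3D numeric array of distances in mm.
#' @export
ventricle_distance_map <- function(ventricle_mask, spacing_mm = NULL) {
  s <- spacing_of(ventricle_mask, spacing_mm)
  m <- ventricle_mask != 0
  if (!any(m)) stop("ventricle mask is empty")
  d <- dim(m)
  out <- .edt_cpp(as.logical(m), as.integer(d), as.numeric(s))
  as_volume(array(out, d), s)
}

#' Classify WMH voxels as periventricular or deep
#'
#' Splits a WMH mask at a ventricular distance threshold: voxels closer than
#' `threshold_mm` are periventricular (pWMH), voxels at or beyond it are deep
#' (dWMH). The partition is exhaustive and disjoint; the boundary convention
#' (distance exactly at threshold counts as deep) is configurable only by
#' changing the threshold.
#'
#' @param wmh_mask logical/0-1 3D array of WMH voxels.
#' @param distance_map output of [ventricle_distance_map()], same grid.
#' @param threshold_mm distance threshold in mm (default 10).
#' @return list with logical arrays `pwmh` and `dwmh`.
#' @export
classify_depth <- function(wmh_mask, distance_map, threshold_mm = 10) {
  check_same_grid(wmh_mask, distance_map, "WMH mask", "distance map")
  m <- wmh_mask != 0
  list(pwmh = m & distance_map < threshold_mm,
       dwmh = m & distance_map >= threshold_mm)
}

#' Parcellate depth-classified WMH by lobe
#'
#' Intersects the pWMH/dWMH masks with the four lobar white-matter labels,
#' yielding up to eight parcels (2 depth classes x 4 lobes) plus depth and
#' grand totals. WMH voxels carrying no lobar label are excluded from the
#' eight parcels but retained in the totals.
#'
#' @param depth_masks output of [classify_depth()].
#' @param lobar_wm_labels integer 3D array, 0 = unlabeled, codes 1..4 in
#'   `lobe_names` order.
#' @param spacing_mm voxel size in mm for volume computation.
#' @param lobe_names names of the lobar codes (default [wm_lobes()]).
#' @return object of class `wmh_parcels`: list with `parcels` (named list of
#'   logical masks, names like `"dWMH_frontal"`), `totals` (masks `total`,
#'   `pWMH`, `dWMH`), `volumes_ml` (data.frame), `n_unlabeled`.
#' @export
split_by_lobe <- function(depth_masks, lobar_wm_labels, spacing_mm = NULL,
                          lobe_names = wm_lobes()) {
  s <- spacing_of(lobar_wm_labels, spacing_mm)
  check_same_grid(depth_masks$pwmh, lobar_wm_labels, "depth mask", "lobar labels")
  parcels <- list()
  for (depth in c("pWMH", "dWMH")) {
    dm <- if (depth == "pWMH") depth_masks$pwmh else depth_masks$dwmh
    for (li in seq_along(lobe_names)) {
      parcels[[paste(depth, lobe_names[li], sep = "_")]] <-
        dm & lobar_wm_labels == li
    }
  }
  total <- depth_masks$pwmh | depth_masks$dwmh
  n_unlabeled <- sum(total & lobar_wm_labels == 0)
  if (n_unlabeled > 0)
    message(n_unlabeled, " WMH voxel(s) carry no lobar label; excluded from parcels, kept in totals")
  totals <- list(total = total, pWMH = depth_masks$pwmh, dWMH = depth_masks$dwmh)
  vols <- data.frame(
    parcel = c(names(parcels), names(totals)),
    n_voxels = c(vapply(parcels, sum, 0L), vapply(totals, sum, 0L)),
    volume_ml = c(vapply(parcels, wmh_volume, 0, spacing_mm = s),
                  vapply(totals, wmh_volume, 0, spacing_mm = s)),
    row.names = NULL)
  structure(list(parcels = parcels, totals = totals, volumes_ml = vols,
                 n_unlabeled = n_unlabeled, spacing_mm = s),
            class = "wmh_parcels")
}

#' Lesion volume in milliliters
#'
#' @param mask logical/0-1 3D array.
#' @param spacing_mm voxel size in mm.
#' @return volume in mL (voxel count x voxel volume / 1000).
#' @export
wmh_volume <- function(mask, spacing_mm = NULL) {
  s <- spacing_of(mask, spacing_mm)
  sum(mask != 0) * prod(s) / 1000
}

#' Full WMH parcellation for one subject
#'
#' Convenience wrapper: distance transform, depth classification at
#' `threshold_mm`, lobar split.
#'
#' @param wmh_mask,ventricle_mask,lobar_wm_labels co-registered 3D volumes.
#' @param spacing_mm voxel size in mm.
#' @param threshold_mm pWMH/dWMH threshold (default 10 mm).
#' @return a `wmh_parcels` object (see [split_by_lobe()]).
#' @export
parcellate_wmh <- function(wmh_mask, ventricle_mask, lobar_wm_labels,
                           spacing_mm = NULL, threshold_mm = 10) {
  s <- spacing_of(wmh_mask, spacing_mm)
  dmap <- ventricle_distance_map(ventricle_mask, s)
  depth <- classify_depth(wmh_mask, dmap, threshold_mm)
  split_by_lobe(depth, lobar_wm_labels, s)
}
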