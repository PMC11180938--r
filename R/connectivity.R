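#' Voxel orientation field
#'
#' Per-voxel principal fiber direction (unit vector) plus angular dispersion
#' in degrees, defined on white matter (including the WM/GM boundary) and
#' WMH voxels. This is the substrate the probabilistic tracker samples from.
#'
#' @param dir numeric array of dim `c(nx, ny, nz, 3)`; vectors must have unit
#'   norm wherever `mask` is TRUE.
#' @param dispersion_deg scalar or 3D array of angular dispersions (degrees).
#' @param mask logical 3D array where the field is defined.
#' @return object of class `orientation_field`.
#' @export
orientation_field <- function(dir, dispersion_deg, mask) {
  d <- dim(mask)
  stopifnot(length(dim(dir)) == 4L, all(dim(dir)[1:3] == d), dim(dir)[4] == 3L)
  if (any(dispersion_deg < 0)) stop("dispersion must be >= 0")
  n <- prod(d)
  idx <- which(mask)
  nr <- sqrt(dir[idx]^2 + dir[idx + n]^2 + dir[idx + 2 * n]^2)
  if (any(abs(nr - 1) > 1e-6))
    stop("orientation vectors must have unit norm where the field is defined")
  disp <- if (length(dispersion_deg) == 1L) array(dispersion_deg, d) else dispersion_deg
  check_same_grid(disp, mask, "dispersion", "field mask")
  structure(list(dir = dir, dispersion_deg = disp, mask = mask),
            class = "orientation_field")
}

#' Tracking parameters
#'
#' Defaults follow common probabilistic-tractography practice: 5000 samples
#' per seed voxel, step size half the smallest voxel dimension, at most 2000
#' steps, and an 80 degree per-step curvature threshold.
#'
#' @param samples_per_voxel streamlines emitted per seed voxel.
#' @param step_mm step length in mm (`NULL` = 0.5 x min spacing, resolved at
#'   tracking time).
#' @param max_steps maximum steps before a streamline is discarded.
#' @param curvature_threshold_deg maximum turning angle in one step.
#' @param seed master RNG seed; each seed voxel derives its own substream,
#'   so counts do not depend on seed-mask composition or evaluation order.
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(samples_per_voxel = 5000, step_mm = NULL,
                            max_steps = 2000, curvature_threshold_deg = 80,
                            seed = 1L) {
  stopifnot(samples_per_voxel >= 1, is.null(step_mm) || step_mm > 0,
            max_steps >= 1)
  structure(list(samples_per_voxel = as.integer(samples_per_voxel),
                 step_mm = step_mm, max_steps = as.integer(max_steps),
                 curvature_threshold_deg = curvature_threshold_deg,
                 seed = as.integer(seed)), class = "tracking_params")
}

#' Probabilistic streamline tracking from a seed mask to the WM/GM boundary
#'
#' Emits `samples_per_voxel` streamlines from each seed voxel. Each starts at
#' a uniformly jittered position inside the voxel and repeatedly draws a step
#' direction from the local principal direction perturbed by the local
#' angular dispersion (sign-aligned with the previous step), advancing
#' `step_mm` per step. A streamline terminates with success on first entry
#' into a target (boundary) voxel, incrementing that voxel's count, and with
#' failure on leaving the brain mask, exceeding `max_steps`, or turning more
#' than the curvature threshold in one step. The emitted total is recorded
#' exactly: `total_streamlines = samples_per_voxel x number of seed voxels`.
#'
#' @param seed_mask logical 3D array of seed voxels (must lie in the brain
#'   and inside the orientation field).
#' @param field an [orientation_field()].
#' @param boundary_mask logical 3D array of target voxels.
#' @param brain_mask logical 3D array.
#' @param spacing_mm voxel size in mm.
#' @param params a [tracking_params()].
#' @return object of class `connectivity_map`: `counts` (3D integer array of
#'   terminations), `total_streamlines`, `n_success`, `n_failure`,
#'   `samples_per_voxel`, `n_seed_voxels`, and `probability()` accessor via
#'   `counts / total_streamlines`.
#' @export
track_streamlines <- function(seed_mask, field, boundary_mask, brain_mask,
                              spacing_mm = NULL, params = tracking_params()) {
  s <- spacing_of(seed_mask, spacing_mm)
  check_same_grid(seed_mask, boundary_mask, "seed mask", "boundary mask")
  check_same_grid(seed_mask, brain_mask, "seed mask", "brain mask")
  check_same_grid(seed_mask, field$mask, "seed mask", "orientation field")
  seeds <- which(seed_mask != 0)
  if (!length(seeds)) stop("seed mask is empty")
  if (!any(boundary_mask)) stop("boundary mask is empty")
  if (!all(field$mask[seeds]))
    stop("orientation field is undefined at ", sum(!field$mask[seeds]),
         " seed voxel(s)")
  if (!all(brain_mask[seeds])) stop("seed mask extends outside the brain mask")
  step <- if (is.null(params$step_mm)) 0.5 * min(s) else params$step_mm
  res <- .track_cpp(as.integer(seeds - 1L), as.numeric(field$dir),
                    as.numeric(field$dispersion_deg),
                    as.logical(field$mask), as.logical(boundary_mask),
                    as.logical(brain_mask), as.integer(dim(seed_mask)),
                    as.numeric(s), params$samples_per_voxel, step,
                    params$max_steps, params$curvature_threshold_deg,
                    as.numeric(params$seed))
  counts <- array(res$counts, dim(seed_mask))
  structure(list(counts = counts,
                 total_streamlines = as.numeric(params$samples_per_voxel) * length(seeds),
                 n_success = res$n_success, n_failure = res$n_failure,
                 samples_per_voxel = params$samples_per_voxel,
                 n_seed_voxels = length(seeds),
                 step_mm = step, spacing_mm = s),
            class = "connectivity_map")
}

#' Connection probability map
#'
#' @param cmap a `connectivity_map`.
#' @return 3D array of termination counts divided by the emitted total.
#' @export
probability_map <- function(cmap) cmap$counts / cmap$total_streamlines

#' Low-level connectivity ROI
#'
#' Thresholds the termination-count map at a fixed fraction of the emitted
#' streamline total: boundary voxels with
#' `count >= tau_low_percent / 100 * total_streamlines` (real-valued
#' comparison, `>=` by default) form the low-probability WMH-connected ROI.
#'
#' @param cmap a `connectivity_map`.
#' @param boundary_mask logical 3D array of target voxels.
#' @param tau_low_percent threshold as a percentage of total streamlines
#'   (default 3.08e-5 percent).
#' @param strict use `>` instead of `>=`.
#' @return logical 3D ROI mask.
#' @export
low_roi <- function(cmap, boundary_mask, tau_low_percent = 3.08e-5,
                    strict = FALSE) {
  stopifnot(cmap$total_streamlines > 0)
  cutoff <- tau_low_percent / 100 * cmap$total_streamlines
  if (strict) boundary_mask & cmap$counts > cutoff
  else boundary_mask & cmap$counts >= cutoff
}

#' Adaptive medium/high connectivity ROI
#'
#' Finds the smallest count threshold `t` (searched over the sorted distinct
#' count values within the low-level ROI) such that the surface size of
#' `{count >= t}` is at most `target_fraction` times the low-level surface
#' size, and returns the resulting ROI. Because size is non-increasing in
#' `t`, the result is the largest ROI satisfying the size bound. If the count
#' distribution is so degenerate that the first feasible threshold empties
#' the ROI, that threshold is still returned, with a warning.
#'
#' @param cmap a `connectivity_map`.
#' @param low_mask logical low-level ROI mask (from [low_roi()]).
#' @param target_fraction target size as a fraction of the low-level size
#'   (0.5 = medium, 0.25 = high).
#' @return list with `mask`, `threshold` (count units), `size`.
#' @export
adaptive_roi <- function(cmap, low_mask, target_fraction) {
  stopifnot(target_fraction > 0, target_fraction <= 1)
  low_size <- sum(low_mask)
  if (low_size == 0) stop("low-level ROI is empty")
  cnt <- cmap$counts[low_mask]
  if (target_fraction == 1)
    return(list(mask = low_mask, threshold = min(cnt), size = low_size))
  cand <- sort(unique(cnt))
  target <- target_fraction * low_size
  sizes <- vapply(cand, function(t) sum(cnt >= t), 0L)
  ok <- which(sizes <= target)
  if (!length(ok)) {        # only possible if even dropping all voxels fails
    t <- max(cand) + 1
    warning("no count threshold reaches the target size; returning empty ROI")
    return(list(mask = low_mask & FALSE, threshold = t, size = 0L))
  }
  t <- cand[ok[1]]
  mask <- low_mask & cmap$counts >= t
  if (sum(mask) == 0)
    warning("adaptive threshold search undershot to an empty ROI (degenerate count distribution)")
  list(mask = mask, threshold = t, size = sum(mask))
}

#' Build the three-level ROI set
#'
#' Applies the fixed low-level threshold, then the adaptive search for the
#' medium (50% of low surface size) and high (25%) levels. The levels are
#' nested by construction: high is a subset of medium is a subset of low.
#'
#' @param cmap a `connectivity_map`.
#' @param boundary_mask logical target mask (the "surface").
#' @param tau_low_percent fixed low-level threshold, percent of total.
#' @param fractions named fractions for the adaptive levels.
#' @return object of class `roi_set`: `levels` is a named list (`low`,
#'   `medium`, `high`) of `list(mask, threshold, size)`; `boundary` is kept
#'   for reference-ROI construction.
#' @export
threshold_roi_set <- function(cmap, boundary_mask, tau_low_percent = 3.08e-5,
                              fractions = c(medium = 0.5, high = 0.25)) {
  lowm <- low_roi(cmap, boundary_mask, tau_low_percent)
  if (!any(lowm)) stop("low-level ROI is empty; nothing to threshold")
  cutoff <- tau_low_percent / 100 * cmap$total_streamlines
  levels <- list(low = list(mask = lowm, threshold = cutoff, size = sum(lowm)))
  for (nm in names(fractions)) {
    levels[[nm]] <- adaptive_roi(cmap, lowm, fractions[[nm]])
  }
  structure(list(levels = levels, boundary = boundary_mask),
            class = "roi_set")
}

#' Per-region ROI / reference-ROI partition
#'
#' For each connectivity level and each cortical region r: `ROI_r` is the
#' ROI restricted to region r, and `rROI_r` is the region's boundary minus
#' the *full* ROI at that level (the reference cortex is everything outside
#' the WMH-connected cortex, split by region). Per region and level,
#' `ROI_r` and `rROI_r` partition the region's boundary voxels.
#'
#' @param roi_set a [threshold_roi_set()] result.
#' @param region_labels integer 3D array of cortical region codes (1-based)
#'   covering the boundary.
#' @param region_names names for the codes (default [cortical_regions()]).
#' @return object of class `roi_partition`: per level, per region, integer
#'   voxel-index vectors `roi` and `rroi`.
#' @export
define_rrois <- function(roi_set, region_labels,
                         region_names = cortical_regions()) {
  boundary <- roi_set$boundary
  out <- list()
  for (lev in names(roi_set$levels)) {
    roi <- roi_set$levels[[lev]]$mask
    per_region <- list()
    for (ri in seq_along(region_names)) {
      in_region <- boundary & region_labels == ri
      per_region[[region_names[ri]]] <- list(
        roi = which(in_region & roi),
        rroi = which(in_region & !roi))
    }
    out[[lev]] <- per_region
  }
  structure(list(levels = out, region_names = region_names),
            class = "roi_partition")
}
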