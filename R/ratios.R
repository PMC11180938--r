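#' Surface metric container
#'
#' A scalar metric sampled at the WM/GM boundary voxels: cortical thickness
#' (mm) or a reference-normalized PET uptake ratio (SUVR, unitless).
#'
#' @param data 3D numeric array; values are meaningful at boundary voxels.
#' @param boundary logical 3D array of boundary voxels.
#' @param name metric name (`thickness`, `abeta_suvr`, `tau_suvr`,
#'   `sv2a_suvr`, ...).
#' @param units `"mm"` or `"unitless"`.
#' @param timepoint `"baseline"` or `"month12"`.
#' @param spacing_mm voxel size in mm.
#' @return object of class `surface_metric`.
#' @export
surface_metric <- function(data, boundary, name, units = "unitless",
                           timepoint = "baseline", spacing_mm = NULL) {
  s <- spacing_of(data, spacing_mm)
  check_same_grid(data, boundary, "metric volume", "boundary mask")
  v <- data[boundary]
  if (any(!is.finite(v)) || any(v <= 0))
    stop("surface metric values must be finite and > 0 on the boundary")
  structure(list(data = data, boundary = boundary, name = name,
                 units = units, timepoint = timepoint, spacing_mm = s),
            class = "surface_metric")
}

#' Reference-normalized uptake (SUVR) at the boundary
#'
#' Divides tracer uptake by the mean uptake over the reference region
#' (cerebellar cortex), sampling the result at the WM/GM boundary:
#' `SUVR(v) = uptake(v) / mean(uptake over reference)`.
#'
#' @param uptake_volume 3D array of tracer uptake.
#' @param reference_mask logical 3D array (cerebellum cortex).
#' @param boundary_mask logical 3D array.
#' @param name metric name for the result.
#' @param spacing_mm voxel size in mm.
#' @return a [surface_metric()].
#' @export
suvr_map <- function(uptake_volume, reference_mask, boundary_mask,
                     name = "suvr", spacing_mm = NULL) {
  s <- spacing_of(uptake_volume, spacing_mm)
  check_same_grid(uptake_volume, reference_mask, "uptake", "reference mask")
  if (!any(reference_mask)) stop("reference mask is empty")
  ref <- mean(uptake_volume[reference_mask])
  if (!is.finite(ref) || ref <= 0)
    stop("reference region mean uptake must be positive, got ", format(ref))
  out <- uptake_volume / ref
  surface_metric(as_volume(out, s), boundary_mask, name = name,
                 units = "unitless", spacing_mm = s)
}

# adjacency (26-neighborhood) among boundary voxels, as directed edge lists
# of ordinal positions within which(boundary)
boundary_adjacency <- function(boundary, spacing_mm) {
  d <- dim(boundary)
  idx <- which(boundary)
  ord <- array(0L, d)
  ord[idx] <- seq_along(idx)
  off <- neighbor_offsets_26()
  ei <- list(); ej <- list()
  sub <- arrayInd(idx, d)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(sub, 2L, off[r, ], `+`)
    okr <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[okr, 1] + (nb[okr, 2] - 1) * d[1] + (nb[okr, 3] - 1) * d[1] * d[2]
    jo <- ord[lin]
    keep <- jo > 0L
    ei[[r]] <- which(okr)[keep]
    ej[[r]] <- jo[keep]
  }
  list(i = unlist(ei), j = unlist(ej), n = length(idx), idx = idx)
}

#' Smooth a surface metric on the boundary adjacency graph
#'
#' Iterated conservative neighbor diffusion on the 26-adjacency graph of
#' boundary voxels: each iteration exchanges a fixed fraction (1/27) of the
#' value difference along every edge, which conserves the total metric mass
#' exactly and is equivalent to one step of a symmetric graph heat kernel.
#' The iteration count is calibrated from the kernel's second moment on an
#' ideal flat 8-neighbor sheet (per-iteration, per-axis variance
#' `6 * s^2 / 27` for voxel size `s`) so that the effective Gaussian FWHM
#' (`2.355 * sigma`) approximates `fwhm_mm`.
#'
#' @param metric a [surface_metric()].
#' @param fwhm_mm target full width at half maximum in mm (default 5). A
#'   value below the voxel size yields the identity, with a warning.
#' @return smoothed [surface_metric()].
#' @export
surface_smooth <- function(metric, fwhm_mm = 5) {
  stopifnot(inherits(metric, "surface_metric"))
  s <- metric$spacing_mm
  if (fwhm_mm <= 0) return(metric)
  if (fwhm_mm < min(s)) {
    warning("fwhm_mm below voxel size; returning the metric unsmoothed")
    return(metric)
  }
  sigma2 <- (fwhm_mm / (2 * sqrt(2 * log(2))))^2
  v1 <- 6 * mean(s)^2 / 27          # per-iteration variance, flat-sheet model
  n_iter <- max(1L, as.integer(round(sigma2 / v1)))
  adj <- boundary_adjacency(metric$boundary, s)
  x <- metric$data[adj$idx]
  deg <- tabulate(adj$i, nbins = adj$n)
  w <- 1 / 27
  for (it in seq_len(n_iter)) {
    sums <- unname(rowsum(x[adj$j], adj$i, reorder = TRUE))[, 1]
    # voxels with no neighbors keep their value
    full <- numeric(adj$n)
    full[sort(unique(adj$i))] <- sums
    x <- x + w * (full - deg * x)
  }
  out <- metric$data
  out[adj$idx] <- x
  metric$data <- out
  metric
}

#' Six-region connected/unconnected metric ratios
#'
#' For each connectivity level and each cortical region r with at least
#' `min_voxels` ROI voxels and `min_voxels` reference voxels, computes
#' `ratio_r = mean(metric over ROI_r) / mean(metric over rROI_r)`. Regions
#' failing the size rule are missing. The averaged ratio is the unweighted
#' arithmetic mean of the ratios present.
#'
#' @param metric a [surface_metric()].
#' @param roi_set a [threshold_roi_set()] result (levels may be any subset of
#'   low/medium/high).
#' @param region_labels integer 3D array of cortical region codes.
#' @param min_voxels minimum ROI and rROI voxel count per region (default 10).
#' @param subject,parcel identifiers carried into the output.
#' @param region_names names for the region codes.
#' @return data.frame, one row per level: the six regional ratios, their
#'   average, and per-region ROI/rROI voxel counts.
#' @export
regional_ratios <- function(metric, roi_set, region_labels, min_voxels = 10,
                            subject = "sub-001", parcel = "total",
                            region_names = cortical_regions()) {
  stopifnot(inherits(metric, "surface_metric"))
  check_same_grid(metric$data, region_labels, "metric", "region labels")
  part <- define_rrois(roi_set, region_labels, region_names)
  rows <- lapply(names(part$levels), function(lev) {
    pr <- part$levels[[lev]]
    ratios <- stats::setNames(rep(NA_real_, length(region_names)), region_names)
    n_roi <- n_rroi <- stats::setNames(integer(length(region_names)), region_names)
    for (rn in region_names) {
      n_roi[rn] <- length(pr[[rn]]$roi)
      n_rroi[rn] <- length(pr[[rn]]$rroi)
      if (n_roi[rn] >= min_voxels && n_rroi[rn] >= min_voxels) {
        ratios[rn] <- mean(metric$data[pr[[rn]]$roi]) /
          mean(metric$data[pr[[rn]]$rroi])
      }
    }
    avg <- if (all(is.na(ratios))) NA_real_ else mean(ratios, na.rm = TRUE)
    out <- data.frame(subject = subject, parcel = parcel, level = lev,
                      metric = metric$name, timepoint = metric$timepoint,
                      t(ratios), average = avg,
                      n_regions = sum(!is.na(ratios)))
    for (rn in region_names) {
      out[[paste0("n_roi_", rn)]] <- n_roi[rn]
      out[[paste0("n_rroi_", rn)]] <- n_rroi[rn]
    }
    out
  })
  res <- do.call(rbind, rows)
  if (all(is.na(res$average)))
    warning("no region met the minimum-size rule at any level; averaged ratio missing")
  res
}

#' Follow-up ratios in baseline ROIs
#'
#' Recomputes [regional_ratios()] with the month-12 metric but the ROI set
#' identified at baseline, so longitudinal change is measured over a fixed
#' cortical footprint. Rows are keyed by (subject, parcel, level) for
#' pairing with the baseline record.
#'
#' @param baseline_roi_set baseline [threshold_roi_set()] result.
#' @param metric_month12 follow-up [surface_metric()], same grid.
#' @inheritParams regional_ratios
#' @return data.frame as in [regional_ratios()], `timepoint = "month12"`.
#' @export
longitudinal_ratio <- function(baseline_roi_set, metric_month12, region_labels,
                               min_voxels = 10, subject = "sub-001",
                               parcel = "total",
                               region_names = cortical_regions()) {
  check_same_grid(metric_month12$data, baseline_roi_set$boundary,
                  "follow-up metric", "baseline boundary")
  metric_month12$timepoint <- "month12"
  regional_ratios(metric_month12, baseline_roi_set, region_labels,
                  min_voxels = min_voxels, subject = subject, parcel = parcel,
                  region_names = region_names)
}
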