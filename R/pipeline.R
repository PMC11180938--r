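#' Run configuration
#'
#' Single object from which every pipeline stage reads its parameters; it is
#' serialized alongside the outputs so a run can be reproduced exactly.
#'
#' @param phantom a [phantom_config()] describing the synthetic subject (or
#'   `NULL` when `paths` supplies real volumes).
#' @param paths optional named list of NIfTI paths: `wmh`, `ventricles`,
#'   `lobar_wm`, `regions`, `boundary` (or `tissue`), `brain`, `field_dir1..3`,
#'   `field_dispersion`, plus metric volumes.
#' @param tracking a [tracking_params()].
#' @param tau_low_percent low-level threshold, percent of total streamlines.
#' @param fractions adaptive target fractions (medium, high).
#' @param min_voxels minimum regional ROI/rROI size for a ratio.
#' @param fwhm_mm surface smoothing FWHM applied to SUVR metrics.
#' @param depth_threshold_mm pWMH/dWMH split distance.
#' @param parcels which seed masks to track: any of the eight depth-x-lobe
#'   parcels plus `"total"`, `"pWMH"`, `"dWMH"`.
#' @param seed master seed; per-stage seeds derive from it.
#' @return object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(), paths = NULL,
                       tracking = tracking_params(),
                       tau_low_percent = 3.08e-5,
                       fractions = c(medium = 0.5, high = 0.25),
                       min_voxels = 10, fwhm_mm = 5,
                       depth_threshold_mm = 10,
                       parcels = c("dWMH", "pWMH"),
                       seed = 1L) {
  structure(list(phantom = phantom, paths = paths, tracking = tracking,
                 tau_low_percent = tau_low_percent, fractions = fractions,
                 min_voxels = min_voxels, fwhm_mm = fwhm_mm,
                 depth_threshold_mm = depth_threshold_mm,
                 parcels = parcels, seed = as.integer(seed)),
            class = "run_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$phantom)) {
    cfg <- config$phantom
    cfg$seed <- config$seed
    ph <- make_phantom(cfg)
    tc <- tissue_codes()
    list(subject = "sub-001",
         wmh = ph$wmh, ventricles = ph$tissue == tc[["ventricle"]],
         lobar_wm = ph$lobar_wm, regions = ph$regions,
         boundary = ph$tissue == tc[["wm_gm_boundary"]],
         brain = ph$brain, field = ph$field,
         cereb = ph$tissue == tc[["cerebellum_ref"]],
         metrics = ph$metrics, spacing = ph$spacing_mm, phantom = ph)
  } else {
    p <- config$paths
    need <- c("wmh", "ventricles", "lobar_wm", "regions", "boundary", "brain",
              "field_dir1", "field_dir2", "field_dir3")
    miss <- setdiff(need, names(p))
    if (length(miss))
      stop("pipeline halted at input loading: missing volume(s): ",
           paste(miss, collapse = ", "))
    vols <- lapply(p[need], read_volume)
    for (nm in need[-1]) check_grid_compatible(vols$wmh, vols[[nm]], "wmh", nm)
    d <- dim(vols$wmh)
    dir <- array(0, c(d, 3))
    dir[, , , 1] <- vols$field_dir1; dir[, , , 2] <- vols$field_dir2
    dir[, , , 3] <- vols$field_dir3
    disp <- if (!is.null(p$field_dispersion)) read_volume(p$field_dispersion)
      else array(0, d)
    mask <- sqrt(vols$field_dir1^2 + vols$field_dir2^2 + vols$field_dir3^2) > 0.5
    metric_names <- intersect(c("thickness", "abeta", "tau", "sv2a"), names(p))
    metrics <- lapply(p[metric_names], read_volume)
    list(subject = if (!is.null(p$subject)) p$subject else "sub-001",
         wmh = vols$wmh != 0, ventricles = vols$ventricles != 0,
         lobar_wm = vols$lobar_wm, regions = vols$regions,
         boundary = vols$boundary != 0, brain = vols$brain != 0,
         field = orientation_field(dir, disp, mask),
         cereb = if (!is.null(p$cerebellum)) read_volume(p$cerebellum) != 0 else NULL,
         metrics = metrics, spacing = spacing_of(vols$wmh), phantom = NULL)
  }
}

#' Run the full single-subject pipeline
#'
#' Executes parcellation (distance transform, pWMH/dWMH split, lobar split),
#' per-parcel probabilistic tractography, three-level ROI definition,
#' metric-map construction (SUVR with surface smoothing for the PET metrics),
#' and the six-region ratio computation, writing a manifest with input
#' hashes, the serialized configuration and the seed. Two runs with the same
#' config and seed produce byte-identical ratio tables.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, volumes, the ratio
#'   CSV, sidecars and the manifest are written there.
#' @return list with `ratios` (tidy data.frame), `parcels` (a
#'   `wmh_parcels`), `roi_sets` (per tracked parcel), `cmap_totals`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  inp <- load_pipeline_inputs(config)
  s <- inp$spacing

  # stage 1: WMH parcellation
  if (!any(inp$ventricles))
    stop("pipeline halted at parcellation: ventricle mask is empty")
  parcels <- parcellate_wmh(inp$wmh, inp$ventricles, inp$lobar_wm, s,
                            config$depth_threshold_mm)
  seed_masks <- c(parcels$totals, parcels$parcels)
  wanted <- intersect(config$parcels, names(seed_masks))
  wanted <- wanted[vapply(seed_masks[wanted], any, TRUE)]
  if (!length(wanted))
    stop("pipeline halted at tractography: no non-empty seed parcel selected")

  # stage 2+3: tractography and ROI definition per parcel
  roi_sets <- list(); cmaps <- list()
  for (pn in wanted) {
    tp <- config$tracking
    cm <- track_streamlines(seed_masks[[pn]], inp$field, inp$boundary,
                            inp$brain, s, tp)
    cmaps[[pn]] <- cm
    roi_sets[[pn]] <- threshold_roi_set(cm, inp$boundary,
                                        config$tau_low_percent,
                                        config$fractions)
  }

  # stage 4: surface metrics (SUVR metrics smoothed, thickness not)
  metrics <- list()
  if (!is.null(inp$metrics$thickness))
    metrics$thickness <- surface_metric(inp$metrics$thickness, inp$boundary,
                                        "thickness", units = "mm",
                                        spacing_mm = s)
  for (m in intersect(c("abeta", "tau", "sv2a"), names(inp$metrics))) {
    if (is.null(inp$cereb) || !any(inp$cereb)) next
    sm <- suvr_map(inp$metrics[[m]], inp$cereb, inp$boundary,
                   name = paste0(m, "_suvr"), spacing_mm = s)
    metrics[[m]] <- surface_smooth(sm, config$fwhm_mm)
  }

  # stage 5: ratios
  rows <- list()
  for (pn in wanted) for (mn in names(metrics)) {
    rows[[paste(pn, mn)]] <- regional_ratios(
      metrics[[mn]], roi_sets[[pn]], inp$regions,
      min_voxels = config$min_voxels, subject = inp$subject, parcel = pn)
  }
  ratios <- do.call(rbind, rows)
  rownames(ratios) <- NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("periconnect")),
    seed = config$seed,
    tau_low_percent = config$tau_low_percent,
    fractions = as.list(config$fractions),
    parcels_tracked = wanted,
    total_streamlines = lapply(cmaps, `[[`, "total_streamlines"),
    n_success = lapply(cmaps, `[[`, "n_success"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(inp$phantom)) write_phantom(inp$phantom, file.path(out_dir, "phantom"))
    for (pn in wanted)
      write_roi_set(roi_sets[[pn]], file.path(out_dir, "rois"), pn, s)
    write.csv(ratios, file.path(out_dir, "ratios.csv"), row.names = FALSE)
    write.csv(parcels$volumes_ml, file.path(out_dir, "parcel_volumes.csv"),
              row.names = FALSE)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    vol_files <- list.files(file.path(out_dir, "phantom"), full.names = TRUE)
    if (length(vol_files))
      manifest$input_hashes <- as.list(tools::md5sum(vol_files))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(ratios = ratios, parcels = parcels, roi_sets = roi_sets,
       cmaps = cmaps, metrics = metrics, manifest = manifest)
}
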