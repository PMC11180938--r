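#' Tissue label codes used by the phantom
#'
#' Integer codes of the mutually exclusive tissue classes in the phantom's
#' tissue volume. The WM/GM boundary carries its own code: boundary voxels
#' are exactly the white-matter voxels 26-adjacent to the gray-matter ribbon.
#'
#' @return named integer vector.
#' @export
tissue_codes <- function() {
  c(background = 0L, ventricle = 1L, white_matter = 2L,
    gm_ribbon = 3L, wm_gm_boundary = 4L, cerebellum_ref = 5L)
}

#' Names of the six cortical regions and four WM lobes
#' @return character vector of region names in label order.
#' @export
cortical_regions <- function() {
  c("frontal", "temporal", "parietal", "occipital", "cingulate", "insula")
}

#' @rdname cortical_regions
#' @export
wm_lobes <- function() c("frontal", "parietal", "temporal", "occipital")

#' Configuration for the synthetic brain phantom
#'
#' Defines the geometry, lesion load, planted effects and cohort structure of
#' the synthetic subject(s). Defaults describe a 64^3 grid at 2 mm isotropic
#' spacing with one deep frontal and one periventricular parietal lesion, a
#' planted 5% thickness reduction and 8% synaptic-density reduction in the
#' lesion-connected cortex, and a three-group cohort of 59/27/21
#' AD/MCI/control subjects.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing_mm numeric length-3 (or scalar) voxel size in mm.
#' @param seed integer RNG seed; identical config + seed reproduces all
#'   volumes bit-for-bit.
#' @param lesion_specs list of `list(lobe=, depth=, radius_mm=)` entries;
#'   `depth` is `"periventricular"` or `"deep"` (placement is verified
#'   against the ventricular distance transform after the fact).
#' @param metric_effects named numeric, planted connected/unconnected ratio
#'   per metric (`thickness`, `abeta`, `tau`, `sv2a`); e.g. 0.95 plants a 5%
#'   reduction in the connected cortex.
#' @param noise_sd_frac multiplicative (lognormal) voxel noise SD as a
#'   fraction of the regional mean.
#' @param annual_change named numeric `c(connected=, unconnected=)`, planted
#'   12-month thickness change in mm.
#' @param dispersion_deg angular dispersion of the orientation field
#'   (degrees) used for probabilistic tracking.
#' @param cohort_size named integer `c(AD=, MCI=, CN=)`.
#' @param group_ratio_means 4 x 3 matrix (metrics x groups) of per-group mean
#'   connected/unconnected ratios for cohort simulation.
#' @param ratio_sd between-subject SD of the ratios.
#' @param cognition_model list with `intercept`, `beta_ratio`,
#'   `ratio_metric`, `beta_age`, `beta_education`, `beta_wmh`, `residual_sd`:
#'   the linear model generating the cognitive score.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 64L),
                           spacing_mm = c(2, 2, 2),
                           seed = 1L,
                           lesion_specs = list(
                             list(lobe = "frontal", depth = "deep", radius_mm = 4),
                             list(lobe = "parietal", depth = "periventricular", radius_mm = 4)),
                           metric_effects = c(thickness = 0.95, abeta = 1.05,
                                              tau = 1.05, sv2a = 0.92),
                           noise_sd_frac = 0.05,
                           annual_change = c(connected = -0.10, unconnected = -0.01),
                           dispersion_deg = 10,
                           cohort_size = c(AD = 59L, MCI = 27L, CN = 21L),
                           group_ratio_means = NULL,
                           ratio_sd = 0.035,
                           cognition_model = list(
                             intercept = 46, beta_ratio = -37.8,
                             ratio_metric = "abeta", beta_age = -0.05,
                             beta_education = 0.3, beta_wmh = -0.05,
                             residual_sd = 5)) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(grid_shape < 8L)) stop("grid_shape must be at least 8 voxels per axis")
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  for (ls in lesion_specs) {
    if (!all(c("lobe", "depth", "radius_mm") %in% names(ls)))
      stop("each lesion spec needs lobe, depth and radius_mm")
    if (!ls$lobe %in% wm_lobes()) stop("unknown lobe: ", ls$lobe)
    if (!ls$depth %in% c("periventricular", "deep"))
      stop("depth must be 'periventricular' or 'deep'")
    if (ls$radius_mm <= 0) stop("lesion radius_mm must be > 0")
  }
  need <- c("thickness", "abeta", "tau", "sv2a")
  if (!all(need %in% names(metric_effects)))
    stop("metric_effects must name thickness, abeta, tau and sv2a")
  if (any(metric_effects <= 0)) stop("metric_effects must be > 0")
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0")
  if (any(cohort_size < 0)) stop("cohort sizes must be >= 0")
  if (is.null(group_ratio_means)) {
    group_ratio_means <- rbind(
      thickness = c(AD = 0.956, MCI = 0.962, CN = 0.970),
      abeta     = c(AD = 1.050, MCI = 1.050, CN = 1.040),
      tau       = c(AD = 1.050, MCI = 1.040, CN = 1.030),
      sv2a      = c(AD = 0.890, MCI = 0.902, CN = 0.940))
  }
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 seed = as.integer(seed), lesion_specs = lesion_specs,
                 metric_effects = metric_effects[need],
                 noise_sd_frac = noise_sd_frac,
                 annual_change = annual_change,
                 dispersion_deg = dispersion_deg,
                 cohort_size = cohort_size,
                 group_ratio_means = group_ratio_means,
                 ratio_sd = ratio_sd,
                 cognition_model = cognition_model),
            class = "phantom_config")
}

# deterministic concentric geometry shared by make_phantom and tests
phantom_geometry <- function(config) {
  d <- config$grid_shape; s <- config$spacing_mm
  extent <- (d - 1) * s
  L <- min(extent) / 2
  mid <- extent / 2
  sbar <- mean(s)
  cc <- c(mid[1], mid[2], mid[3] + 0.12 * L)   # cerebrum center, mm
  Rb <- 0.70 * L                               # outer (pial) radius
  Rv <- 0.155 * L                              # ventricle radius
  ribbon <- 2 * sbar                           # GM ribbon thickness
  Rw <- Rb - ribbon                            # WM outer radius
  Rc <- 0.16 * L                               # cerebellum radius
  ccb <- c(mid[1], mid[2], cc[3] - Rb - sbar - Rc)
  list(center = cc, r_brain = Rb, r_vent = Rv, r_wm = Rw,
       cereb_center = ccb, r_cereb = Rc, extent = extent, L = L)
}

# squared distance of every voxel center to a world point, as a 3D array
dist_to_point <- function(d, s, p) {
  dx <- ((seq_len(d[1]) - 1) * s[1] - p[1])^2
  dy <- ((seq_len(d[2]) - 1) * s[2] - p[2])^2
  dz <- ((seq_len(d[3]) - 1) * s[3] - p[3])^2
  sqrt(outer(outer(dx, dy, `+`), dz, `+`))
}

#' Generate a synthetic single-subject phantom
#'
#' Builds a concentric brain: an ellipsoidal ventricle at the center, a white
#' matter shell, a 1-3 voxel gray-matter ribbon, and a detached cerebellar
#' reference ball. The WM/GM boundary is the set of WM voxels 26-adjacent to
#' the ribbon. Six cortical regions (frontal, temporal, parietal, occipital,
#' cingulate, insula) are carved as angular sectors; cingulate and insula are
#' para-midline/lateral bands. The orientation field points along the local
#' ventricle-to-cortex radial direction so that streamlines seeded in WM
#' reach the overlying boundary. Lesions are placed per `lesion_specs` and
#' verified against the ventricular distance transform (periventricular:
#' minimum distance < 10 mm; deep: >= 10 mm). Metric volumes are regional
#' baseline x planted effect inside the true connected patch x lognormal
#' noise. The truth record holds the connected boundary patch per lesion,
#' the planted effects and the lesion table.
#'
#' @param config a [phantom_config()].
#' @return object of class `phantom`: list with elements `tissue`, `regions`,
#'   `lobar_wm`, `wmh`, `brain`, `field`, `metrics`, `truth`, `spacing_mm`,
#'   `config`, `timepoint`.
#' @export
make_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  local_seed(config$seed)
  d <- config$grid_shape; s <- config$spacing_mm
  geo <- phantom_geometry(config)
  tc <- tissue_codes()

  r <- dist_to_point(d, s, geo$center)
  rc <- dist_to_point(d, s, geo$cereb_center)

  tissue <- array(tc[["background"]], d)
  tissue[r <= geo$r_vent] <- tc[["ventricle"]]
  tissue[r > geo$r_vent & r <= geo$r_wm] <- tc[["white_matter"]]
  tissue[r > geo$r_wm & r <= geo$r_brain] <- tc[["gm_ribbon"]]
  tissue[rc <= geo$r_cereb] <- tc[["cerebellum_ref"]]

  wm <- tissue == tc[["white_matter"]]
  gm <- tissue == tc[["gm_ribbon"]]
  bnd <- adjacent_to(wm, gm)
  tissue[bnd] <- tc[["wm_gm_boundary"]]
  wm_all <- wm | bnd                      # white matter incl. boundary
  brain <- (r <= geo$r_brain) | (rc <= geo$r_cereb)

  # unit radial directions relative to the cerebrum center
  ug <- radial_directions(d, s, geo$center, r)

  cortex <- gm | bnd
  regions <- array(0L, d)
  regions[cortex] <- sector_labels(ug, cortex, six = TRUE)
  lobar_wm <- array(0L, d)
  wm_or_wmh <- wm_all
  lobar_wm[wm_or_wmh] <- sector_labels(ug, wm_or_wmh, six = FALSE)

  # orientation field on WM (incl. boundary); lesions live inside WM
  field <- orientation_field(
    dir = ug, dispersion_deg = config$dispersion_deg, mask = wm_all)

  # lesion placement
  wmh <- array(FALSE, d)
  per_lesion_idx <- list()
  lesion_rows <- list()
  lobe_count <- stats::setNames(integer(length(wm_lobes())), wm_lobes())
  vent_mask <- tissue == tc[["ventricle"]]
  dmap <- ventricle_distance_map(vent_mask, s)
  sbar <- mean(s)
  for (li in seq_along(config$lesion_specs)) {
    ls <- config$lesion_specs[[li]]
    lobe_count[ls$lobe] <- lobe_count[ls$lobe] + 1L
    ctr <- lesion_center(ls, geo, lobe_count[ls$lobe], sbar)
    lr <- dist_to_point(d, s, ctr)
    les <- (tissue == tc[["white_matter"]]) & lr <= ls$radius_mm
    if (!any(les))
      stop(sprintf("lesion %d (%s, %s, %.1f mm): no white matter voxels at the requested location",
                   li, ls$lobe, ls$depth, ls$radius_mm))
    mind <- min(dmap[les])
    if (ls$depth == "deep" && mind < 10)
      stop(sprintf("lesion %d: requested deep placement but minimum ventricular distance is %.2f mm",
                   li, mind))
    if (ls$depth == "periventricular" && mind >= 10)
      stop(sprintf("lesion %d: requested periventricular placement but minimum ventricular distance is %.2f mm",
                   li, mind))
    wmh <- wmh | les
    lesion_rows[[li]] <- data.frame(
      lobe = ls$lobe, depth = ls$depth, radius_mm = ls$radius_mm,
      center_x_mm = ctr[1], center_y_mm = ctr[2], center_z_mm = ctr[3],
      n_voxels = sum(les), min_vent_dist_mm = mind)
    per_lesion_idx[[li]] <- which(les)
  }

  # ground truth: boundary voxels radially overlying each lesion, found by
  # deterministic ray casting through the orientation field (dispersion 0)
  truth_per_lesion <- lapply(per_lesion_idx, function(idx)
    radial_footprint(idx, field, bnd, brain, s))
  connected <- array(FALSE, d)
  for (tp in truth_per_lesion) connected[tp] <- TRUE

  metrics <- plant_metrics(config, bnd, regions, connected,
                           tissue == tc[["cerebellum_ref"]])

  structure(list(
    tissue = as_volume(tissue, s),
    regions = as_volume(regions, s),
    lobar_wm = as_volume(lobar_wm, s),
    wmh = as_volume(wmh, s),
    brain = as_volume(brain, s),
    field = field,
    metrics = metrics,
    truth = list(connected = connected,
                 per_lesion = truth_per_lesion,
                 lesion_table = do.call(rbind, lesion_rows),
                 effects = config$metric_effects,
                 region_baselines = region_baselines(),
                 cognition = config$cognition_model),
    spacing_mm = s,
    config = config,
    timepoint = "baseline"), class = "phantom")
}

radial_directions <- function(d, s, center, r) {
  cx <- (seq_len(d[1]) - 1) * s[1] - center[1]
  cy <- (seq_len(d[2]) - 1) * s[2] - center[2]
  cz <- (seq_len(d[3]) - 1) * s[3] - center[3]
  rr <- pmax(r, 1e-9)
  ux <- array(cx, d) / rr
  uy <- array(rep(cy, each = d[1]), d) / rr
  uz <- array(rep(cz, each = d[1] * d[2]), d) / rr
  dir <- array(0, c(d, 3L))
  dir[, , , 1] <- ux; dir[, , , 2] <- uy; dir[, , , 3] <- uz
  dir
}

# angular sector labels; six = cortical scheme (with cingulate/insula bands),
# otherwise the four-lobe WM scheme
sector_labels <- function(dir, mask, six) {
  idx <- which(mask)
  n <- prod(dim(mask))
  ux <- dir[idx]; uy <- dir[idx + n]; uz <- dir[idx + 2 * n]
  quad <- ifelse(uy >= 0,
                 ifelse(uz >= 0, "frontal", "temporal"),
                 ifelse(uz >= 0, "parietal", "occipital"))
  if (six) {
    lab <- match(quad, cortical_regions())
    lab[abs(ux) <= 0.15] <- 5L  # cingulate: para-midline band
    lab[abs(ux) >= 0.90] <- 6L  # insula: lateral caps
  } else {
    lab <- match(quad, wm_lobes())
  }
  as.integer(lab)
}

# deterministic lesion center for a (lobe, depth, radius) request; hemisphere
# alternates for repeated lesions in the same lobe
lesion_center <- function(ls, geo, occurrence, sbar) {
  hemi <- if (occurrence %% 2L == 1L) 1 else -1
  extra <- 15 * ((occurrence - 1L) %/% 2L) * pi / 180
  yz <- switch(ls$lobe,
               frontal   = c(1, 1), parietal = c(-1, 1),
               temporal  = c(1, -1), occipital = c(-1, -1)) / sqrt(2)
  a <- sqrt(1 - 0.4^2)
  u <- c(hemi * 0.4,
         a * (yz[1] * cos(extra) - yz[2] * sin(extra)),
         a * (yz[1] * sin(extra) + yz[2] * cos(extra)))
  radius <- ls$radius_mm
  if (ls$depth == "deep") {
    rmin <- geo$r_vent + 10 + radius
    rmax <- geo$r_wm - radius - 0.5 * sbar
    if (rmin > rmax)
      stop(sprintf("no deep white matter at lobe '%s' for a %.1f mm lesion on this grid",
                   ls$lobe, radius))
    cr <- (rmin + rmax) / 2
  } else {
    cr <- geo$r_vent + radius + 3.5
    if (cr + radius > geo$r_wm - 0.5 * sbar)
      stop(sprintf("no periventricular white matter at lobe '%s' for a %.1f mm lesion on this grid",
                   ls$lobe, radius))
  }
  geo$center + cr * u
}

# Deterministic radial footprint of a lesion on the WM/GM boundary: rays are
# cast from a 9x9x9 sub-grid spanning each lesion voxel and follow the
# orientation field voxel-wise, exactly as the tracker does with zero
# dispersion; the footprint is the set of boundary voxels any ray enters
# first. 9 offsets per axis is past the point where the hit set stops
# growing (the radial magnification from the deepest seeds can no longer
# skip boundary voxels between adjacent rays), so this is the deterministic
# continuum limit of the tracker over the lesion volume.
radial_footprint <- function(lesion_idx, field, boundary, brain, spacing,
                             step_frac = 0.5) {
  d <- dim(boundary)
  n <- prod(d)
  sub <- arrayInd(lesion_idx, d)
  o1 <- seq(-0.5, 0.5, length.out = 9)
  off <- as.matrix(expand.grid(o1, o1, o1))
  starts <- do.call(rbind, lapply(seq_len(nrow(off)), function(r)
    sweep(sub - 1 + matrix(off[r, ], nrow(sub), 3, byrow = TRUE), 2, spacing, `*`)))
  step <- step_frac * min(spacing)
  max_steps <- ceiling(2 * max(dim(boundary) * spacing) / step)
  pos <- starts
  active <- rep(TRUE, nrow(pos))
  hits <- integer(0)
  dirx <- field$dir[, , , 1]; diry <- field$dir[, , , 2]; dirz <- field$dir[, , , 3]
  for (it in seq_len(max_steps)) {
    if (!any(active)) break
    ai <- which(active)
    ijk <- round(sweep(pos[ai, , drop = FALSE], 2, spacing, `/`)) + 1
    inb <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
      ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    active[ai[!inb]] <- FALSE
    ai <- ai[inb]; ijk <- ijk[inb, , drop = FALSE]
    if (!length(ai)) next
    lin <- ijk[, 1] + (ijk[, 2] - 1) * d[1] + (ijk[, 3] - 1) * d[1] * d[2]
    hit <- boundary[lin]
    hits <- c(hits, lin[hit])
    active[ai[hit]] <- FALSE
    keep <- !hit & field$mask[lin] & brain[lin]
    active[ai[!hit & !field$mask[lin]]] <- FALSE
    active[ai[!hit & field$mask[lin] & !brain[lin]]] <- FALSE
    ai <- ai[keep]; lin <- lin[keep]
    if (!length(ai)) next
    dirs <- cbind(dirx[lin], diry[lin], dirz[lin])
    pos[ai, ] <- pos[ai, , drop = FALSE] + step * dirs
  }
  sort(unique(hits))
}

region_baselines <- function() {
  list(thickness = c(frontal = 2.6, temporal = 2.9, parietal = 2.4,
                     occipital = 2.2, cingulate = 2.7, insula = 3.0),
       abeta = 1.4, tau = 1.3, sv2a = 1.2, cereb_uptake = 1.0)
}

plant_metrics <- function(config, boundary, regions, connected, cereb) {
  d <- dim(boundary)
  base <- region_baselines()
  eff <- config$metric_effects
  sdlog <- sqrt(log1p(config$noise_sd_frac^2))
  noise <- function(k) {
    if (config$noise_sd_frac == 0) rep(1, k) else rlnorm(k, 0, sdlog)
  }
  bidx <- which(boundary)
  reg <- regions[bidx]
  conn <- connected[bidx]
  out <- list()
  th <- array(0, d)
  th[bidx] <- base$thickness[reg] * ifelse(conn, eff[["thickness"]], 1) *
    noise(length(bidx))
  out$thickness <- th
  for (m in c("abeta", "tau", "sv2a")) {
    u <- array(0, d)
    u[bidx] <- base[[m]] * ifelse(conn, eff[[m]], 1) * noise(length(bidx))
    cidx <- which(cereb)
    u[cidx] <- base$cereb_uptake * noise(length(cidx))
    out[[m]] <- u
  }
  lapply(out, as_volume, spacing_mm = config$spacing_mm)
}

#' Generate the 12-month follow-up of a phantom
#'
#' Follow-up thickness = baseline thickness + planted annual change (a larger
#' decrement inside the true connected patch) + fresh multiplicative noise.
#' Geometry, lesions and all ROI-defining volumes are unchanged, mirroring a
#' longitudinal design where follow-up metrics are sampled in baseline ROIs.
#'
#' @param phantom baseline [make_phantom()] output.
#' @param config optional config override (defaults to the phantom's own).
#' @return a `phantom` with `timepoint = "month12"`.
#' @export
make_followup <- function(phantom, config = phantom$config) {
  stopifnot(inherits(phantom, "phantom"))
  local_seed(config$seed + 1L)
  ac <- config$annual_change
  bidx <- which(phantom$tissue == tissue_codes()[["wm_gm_boundary"]])
  conn <- phantom$truth$connected[bidx]
  th <- phantom$metrics$thickness
  delta <- ifelse(conn, ac[["connected"]], ac[["unconnected"]])
  sdlog <- sqrt(log1p(config$noise_sd_frac^2))
  nz <- if (config$noise_sd_frac == 0) rep(1, length(bidx)) else
    rlnorm(length(bidx), 0, sdlog)
  th[bidx] <- pmax((th[bidx] + delta), 1e-6) * nz
  out <- phantom
  out$metrics$thickness <- as_volume(th, phantom$spacing_mm)
  out$timepoint <- "month12"
  out
}

#' Simulate a multi-subject cohort table
#'
#' Draws per-subject demographics, WMH burden, planted connected/unconnected
#' ratios per metric, and a cognitive score from the configured linear model
#' `score = intercept + beta_ratio * ratio + beta_age * age +
#' beta_education * education + beta_wmh * wmh_volume + noise`. Group labels
#' follow the clinical convention CDR > 0.5 = AD, CDR = 0.5 = MCI,
#' CDR = 0 = CN.
#'
#' @param config a [phantom_config()]; `cohort_size`, `group_ratio_means`,
#'   `ratio_sd` and `cognition_model` drive the simulation.
#' @param phantoms if `TRUE`, also generate one phantom per subject (with the
#'   subject's planted ratios and a per-subject seed); slow for large cohorts.
#' @return list with `subjects` (data.frame) and `phantoms` (list or NULL).
#' @export
make_cohort <- function(config = phantom_config(), phantoms = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  local_seed(config$seed)
  sizes <- config$cohort_size
  groups <- rep(names(sizes), times = sizes)
  n <- length(groups)
  age_par <- list(AD = c(70.7, 8.0), MCI = c(71.1, 7.0), CN = c(70.0, 8.0))
  mmse_par <- list(AD = c(17, 5), MCI = c(25, 1.5), CN = c(28.5, 1.2))
  age <- vapply(groups, function(g) rnorm(1, age_par[[g]][1], age_par[[g]][2]), 0)
  education <- pmax(1, rnorm(n, 10.7, 4.5))
  wmh_volume <- rlnorm(n, log(8), 0.9)
  mmse <- pmin(30, pmax(0, vapply(groups, function(g)
    rnorm(1, mmse_par[[g]][1], mmse_par[[g]][2]), 0)))
  grm <- config$group_ratio_means
  ratios <- sapply(rownames(grm), function(m)
    rnorm(n, grm[m, groups], config$ratio_sd))
  colnames(ratios) <- rownames(grm)
  cm <- config$cognition_model
  eps <- if (cm$residual_sd == 0) rep(0, n) else rnorm(n, 0, cm$residual_sd)
  score <- cm$intercept + cm$beta_ratio * ratios[, cm$ratio_metric] +
    cm$beta_age * age + cm$beta_education * education +
    cm$beta_wmh * wmh_volume + eps
  cdr <- c(AD = 1, MCI = 0.5, CN = 0)[groups]
  subjects <- data.frame(
    subject = sprintf("sub-%03d", seq_len(n)),
    group = factor(groups, levels = c("AD", "MCI", "CN")),
    cdr = cdr, age = age, education = education,
    wmh_volume_ml = wmh_volume, mmse = mmse, score = score,
    ratio_thickness = ratios[, "thickness"], ratio_abeta = ratios[, "abeta"],
    ratio_tau = ratios[, "tau"], ratio_sv2a = ratios[, "sv2a"],
    row.names = NULL)
  ph <- NULL
  if (phantoms && n > 0) {
    ph <- vector("list", n)
    for (i in seq_len(n)) {
      ci <- config
      ci$seed <- config$seed + 7919L * i
      ci$metric_effects <- c(thickness = ratios[i, "thickness"],
                             abeta = ratios[i, "abeta"],
                             tau = ratios[i, "tau"],
                             sv2a = ratios[i, "sv2a"])
      ph[[i]] <- make_phantom(ci)
    }
    names(ph) <- subjects$subject
  }
  list(subjects = subjects, phantoms = ph)
}

#' Simulate a paired longitudinal cohort of ratios and MMSE
#'
#' Emulates a 12-month follow-up sample: per-subject baseline
#' connected/unconnected thickness ratio and MMSE, plus planted 12-month
#' changes. Defaults describe a 23-subject follow-up group with baseline
#' ratio 0.976 (SD 0.034), a planted annual ratio change of -0.033 (SD 0.02),
#' baseline MMSE 21.4 (SD 5.1) and an MMSE change of -1.8 (SD 3).
#'
#' @param n number of paired subjects.
#' @param ratio_baseline,ratio_change,mmse_baseline,mmse_change numeric
#'   `c(mean, sd)` pairs.
#' @param seed RNG seed.
#' @return data.frame with one row per subject.
#' @export
make_longitudinal_cohort <- function(n = 23,
                                     ratio_baseline = c(0.976, 0.034),
                                     ratio_change = c(-0.033, 0.02),
                                     mmse_baseline = c(21.4, 5.1),
                                     mmse_change = c(-1.8, 3.0),
                                     seed = 1L) {
  local_seed(seed)
  rb <- rnorm(n, ratio_baseline[1], ratio_baseline[2])
  r12 <- rb + rnorm(n, ratio_change[1], ratio_change[2])
  mb <- rnorm(n, mmse_baseline[1], mmse_baseline[2])
  m12 <- mb + rnorm(n, mmse_change[1], mmse_change[2])
  data.frame(subject = sprintf("sub-%03d", seq_len(n)),
             ratio_baseline = rb, ratio_month12 = r12,
             mmse_baseline = mb, mmse_month12 = m12)
}

#' ROI set from the phantom's ground-truth connected patch
#'
#' Wraps the planted connected boundary patch as a single-level `roi_set`
#' (level `"truth"`), so the ratio machinery can be validated against the
#' generator's own truth masks, independently of tractography.
#'
#' @param phantom a [make_phantom()] result.
#' @return an `roi_set` with one level, `truth`.
#' @export
truth_roi_set <- function(phantom) {
  stopifnot(inherits(phantom, "phantom"))
  bnd <- phantom$tissue == tissue_codes()[["wm_gm_boundary"]]
  mask <- phantom$truth$connected & bnd
  structure(list(levels = list(truth = list(mask = mask, threshold = NA_real_,
                                            size = sum(mask))),
                 boundary = bnd), class = "roi_set")
}
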