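test_that("phantom generation is deterministic and geometrically consistent", {
  cfg <- phantom_config(seed = 7)
  ph1 <- make_phantom(cfg)
  ph2 <- make_phantom(cfg)
  expect_identical(ph1$tissue, ph2$tissue)
  expect_identical(ph1$wmh, ph2$wmh)
  expect_identical(ph1$metrics, ph2$metrics)
  expect_identical(ph1$truth$connected, ph2$truth$connected)

  tc <- tissue_codes()
  wm <- ph1$tissue == tc[["white_matter"]]
  gm <- ph1$tissue == tc[["gm_ribbon"]]
  bnd <- ph1$tissue == tc[["wm_gm_boundary"]]
  # boundary voxels are exactly the WM voxels 26-adjacent to the GM ribbon
  expect_true(all(periconnect:::adjacent_to(bnd, gm)[bnd] | !bnd[bnd]))
  expect_equal(sum(periconnect:::adjacent_to(wm, gm)), 0)  # all relabeled
  # every WMH voxel lies inside white matter (strict interior, not boundary)
  expect_true(all(ph1$tissue[ph1$wmh] == tc[["white_matter"]]))
  # each cortical region holds at least 1% of boundary voxels
  shares <- table(factor(ph1$regions[bnd], levels = 1:6)) / sum(bnd)
  expect_true(all(shares >= 0.01))
})

test_that("lesion depth placement is verified against brute-force distances", {
  ph <- make_phantom(phantom_config(seed = 3))
  tc <- tissue_codes()
  vent <- which(ph$tissue == tc[["ventricle"]])
  d <- dim(ph$tissue)
  vent_mm <- sweep(arrayInd(vent, d) - 1, 2, ph$spacing_mm, `*`)
  # brute-force min distance from each WMH voxel to the ventricle
  wmh_idx <- which(ph$wmh)
  wmh_mm <- sweep(arrayInd(wmh_idx, d) - 1, 2, ph$spacing_mm, `*`)
  mind <- vapply(seq_len(nrow(wmh_mm)), function(i)
    sqrt(min(colSums((t(vent_mm) - wmh_mm[i, ])^2))), 0)
  dm <- ventricle_distance_map(ph$tissue == tc[["ventricle"]], ph$spacing_mm)
  expect_equal(dm[wmh_idx], mind, tolerance = 1e-9)
  # the deep frontal lesion truly sits >= 10 mm from the ventricle
  deep <- ph$truth$lesion_table$depth == "deep"
  expect_true(all(ph$truth$lesion_table$min_vent_dist_mm[deep] >= 10))
  expect_true(all(ph$truth$lesion_table$min_vent_dist_mm[!deep] < 10))
})

test_that("unsatisfiable lesion specs raise an explicit placement error", {
  cfg <- phantom_config(grid_shape = c(24L, 24L, 24L),
                        lesion_specs = list(list(lobe = "frontal",
                                                 depth = "deep",
                                                 radius_mm = 4)))
  expect_error(make_phantom(cfg), "deep white matter")
})

test_that("planted metric effects are exact in the absence of noise", {
  # no effect, no noise: thickness identical inside and outside the patch
  cfg0 <- phantom_config(noise_sd_frac = 0,
                         metric_effects = c(thickness = 1, abeta = 1,
                                            tau = 1, sv2a = 1))
  ph0 <- make_phantom(cfg0)
  tc <- tissue_codes()
  bnd <- ph0$tissue == tc[["wm_gm_boundary"]]
  conn <- ph0$truth$connected & bnd
  for (ri in unique(ph0$regions[conn])) {
    inr <- bnd & ph0$regions == ri
    expect_equal(mean(ph0$metrics$thickness[inr & conn]),
                 mean(ph0$metrics$thickness[inr & !conn]))
  }
  # planted 0.95, no noise: the connected/unconnected ratio is exactly 0.95
  cfg <- phantom_config(noise_sd_frac = 0)
  ph <- make_phantom(cfg)
  bnd <- ph$tissue == tc[["wm_gm_boundary"]]
  conn <- ph$truth$connected & bnd
  for (ri in unique(ph$regions[conn])) {
    inr <- bnd & ph$regions == ri
    expect_equal(mean(ph$metrics$thickness[inr & conn]) /
                   mean(ph$metrics$thickness[inr & !conn]), 0.95)
  }
})

test_that("follow-up phantoms plant the configured 12-month change", {
  base_cfg <- phantom_config(noise_sd_frac = 0,
                             annual_change = c(connected = 0, unconnected = 0))
  ph <- make_phantom(base_cfg)
  expect_equal(make_followup(ph)$metrics$thickness, ph$metrics$thickness)

  cfg <- phantom_config(noise_sd_frac = 0,
                        annual_change = c(connected = -0.05, unconnected = 0))
  ph <- make_phantom(cfg)
  ph12 <- make_followup(ph)
  tc <- tissue_codes()
  bnd <- ph$tissue == tc[["wm_gm_boundary"]]
  rs <- truth_roi_set(ph)
  m0 <- surface_metric(ph$metrics$thickness, bnd, "thickness", "mm",
                       spacing_mm = ph$spacing_mm)
  m12 <- surface_metric(ph12$metrics$thickness, bnd, "thickness", "mm",
                        timepoint = "month12", spacing_mm = ph$spacing_mm)
  r0 <- regional_ratios(m0, rs, ph$regions)
  r12 <- longitudinal_ratio(rs, m12, ph$regions)
  conn <- ph$truth$connected & bnd
  for (reg in c("frontal", "parietal")) {
    ri <- match(reg, cortical_regions())
    mean_conn <- mean(ph$metrics$thickness[conn & ph$regions == ri])
    expect_equal(r12[[reg]], r0[[reg]] * (1 - 0.05 / mean_conn))
  }
  # faster connected thinning strictly lowers the averaged ratio
  expect_lt(r12$average, r0$average)
})

test_that("cohort simulation matches the configured group structure and model", {
  cfg <- phantom_config(seed = 11)
  co <- make_cohort(cfg)
  expect_equal(as.integer(table(co$subjects$group)[c("AD", "MCI", "CN")]),
               c(59L, 27L, 21L))
  expect_equal(co$subjects$cdr[co$subjects$group == "AD"][1], 1)
  expect_equal(co$subjects$cdr[co$subjects$group == "MCI"][1], 0.5)
  # determinism
  co2 <- make_cohort(cfg)
  expect_identical(co$subjects, co2$subjects)
  # zero residual SD: scores exactly linear in the planted ratios
  cfg0 <- phantom_config(seed = 5)
  cfg0$cognition_model$residual_sd <- 0
  s <- make_cohort(cfg0)$subjects
  cm <- cfg0$cognition_model
  pred <- cm$intercept + cm$beta_ratio * s$ratio_abeta + cm$beta_age * s$age +
    cm$beta_education * s$education + cm$beta_wmh * s$wmh_volume_ml
  expect_equal(s$score, pred)
})
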