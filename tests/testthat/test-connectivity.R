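test_that("a uniform straight field sends every streamline up its own column", {
  g <- straight_field_grid()
  seed <- array(FALSE, dim(g$brain)); seed[5, 5, 2] <- TRUE
  cm <- track_streamlines(seed, g$field, g$boundary, g$brain, g$spacing,
                          tracking_params(samples_per_voxel = 2000, seed = 1))
  expect_equal(cm$total_streamlines, 2000)
  expect_equal(cm$n_success, 2000)
  expect_equal(cm$n_failure, 0)
  expect_equal(cm$counts[5, 5, 9], 2000L)   # the overlying boundary voxel
  expect_equal(sum(cm$counts), 2000)
})

test_that("streamline accounting is exact and failures are counted", {
  g <- straight_field_grid()
  seed <- array(FALSE, dim(g$brain)); seed[4, 4, 2] <- TRUE; seed[6, 6, 2] <- TRUE
  cm <- track_streamlines(seed, g$field, g$boundary, g$brain, g$spacing,
                          tracking_params(seed = 1))
  expect_equal(cm$total_streamlines, 10000)   # 5000 per voxel, 2 voxels
  expect_equal(cm$n_success + cm$n_failure, cm$total_streamlines)
  # field pointing away from the boundary and out of the brain: 0 terminations
  gdown <- g
  gdown$field$dir[, , , 3] <- -1
  cm0 <- track_streamlines(seed, gdown$field, g$boundary, g$brain, g$spacing,
                           tracking_params(samples_per_voxel = 500, seed = 1))
  expect_equal(cm0$n_success, 0)
  expect_equal(sum(cm0$counts), 0)
  expect_equal(cm0$n_failure, 1000)
})

test_that("tracking validates its inputs", {
  g <- straight_field_grid()
  empty <- array(FALSE, dim(g$brain))
  expect_error(track_streamlines(empty, g$field, g$boundary, g$brain,
                                 g$spacing), "seed mask is empty")
  gap <- g$field
  gap$mask[5, 5, 2] <- FALSE
  seed <- empty; seed[5, 5, 2] <- TRUE
  expect_error(track_streamlines(seed, gap, g$boundary, g$brain, g$spacing),
               "undefined")
})

test_that("counts never decrease when seed voxels are added", {
  g <- straight_field_grid(d = c(7L, 7L, 7L))
  seedA <- array(FALSE, dim(g$brain)); seedA[3, 3, 2] <- TRUE
  seedB <- seedA; seedB[5, 5, 2] <- TRUE; seedB[4, 3, 3] <- TRUE
  p <- tracking_params(samples_per_voxel = 300, seed = 77)
  cmA <- track_streamlines(seedA, g$field, g$boundary, g$brain, g$spacing, p)
  cmB <- track_streamlines(seedB, g$field, g$boundary, g$brain, g$spacing, p)
  expect_true(all(cmB$counts >= cmA$counts))
})

test_that("the low-level threshold is a real-valued cut on counts", {
  d <- c(4L, 4L, 1L)
  counts <- array(0L, d)
  counts[1, 1, 1] <- 4L; counts[2, 1, 1] <- 3L; counts[3, 1, 1] <- 300L
  bnd <- array(TRUE, d)
  cm <- fake_cmap(counts, 1e7)
  roi <- low_roi(cm, bnd)                 # cutoff = 3.08e-7 * 1e7 = 3.08
  expect_true(roi[1, 1, 1])               # count 4 >= 3.08
  expect_false(roi[2, 1, 1])              # count 3 < 3.08
  expect_true(roi[3, 1, 1])
  expect_false(any(low_roi(fake_cmap(array(0L, d), 1e7), bnd)))
  expect_equal(sum(low_roi(cm, bnd, tau_low_percent = 0)), prod(d))
})

test_that("the adaptive search returns the maximal ROI under the size bound", {
  # counts 10 voxels at 5, 10 voxels at 50: medium keeps the high-count half
  d <- c(20L, 1L, 1L)
  counts <- array(c(rep(5L, 10), rep(50L, 10)), d)
  bnd <- array(TRUE, d)
  cm <- fake_cmap(counts, 1e6)
  lowm <- low_roi(cm, bnd)
  expect_equal(sum(lowm), 20)
  med <- adaptive_roi(cm, lowm, 0.5)
  expect_equal(med$size, 10)
  expect_true(all(cm$counts[med$mask] == 50))
  expect_equal(adaptive_roi(cm, lowm, 1)$size, 20)

  # property: on random count maps the result equals an exhaustive search
  set.seed(2024)
  for (rep in 1:20) {
    counts <- array(rpois(60, 8), c(60L, 1L, 1L))
    bnd <- array(TRUE, dim(counts))
    cm <- fake_cmap(counts, 1e6)
    lowm <- low_roi(cm, bnd, tau_low_percent = 0)
    frac <- sample(c(0.25, 0.5, 0.7), 1)
    res <- adaptive_roi(cm, lowm, frac)
    cand <- sort(unique(counts))
    sizes <- vapply(cand, function(t) sum(counts >= t), 0L)
    best <- max(c(0L, sizes[sizes <= frac * sum(lowm)]))
    expect_equal(res$size, best)
    expect_lte(res$size, frac * sum(lowm))
  }
})

test_that("ROI levels are nested and sized per the 50%/25% rule on the phantom", {
  fx <- default_tracked()
  rs <- fx$roi_set
  low <- rs$levels$low$mask; med <- rs$levels$medium$mask
  high <- rs$levels$high$mask
  expect_true(all(low[med]))       # medium subset of low
  expect_true(all(med[high]))      # high subset of medium
  expect_lte(sum(med), 0.5 * sum(low))
  expect_lte(sum(high), 0.25 * sum(low))
  expect_true(all(rs$levels$medium$threshold >= rs$levels$low$threshold))
})

test_that("reference ROIs complement the full ROI within each region", {
  fx <- default_tracked()
  ph <- fx$phantom
  part <- define_rrois(fx$roi_set, ph$regions)
  for (lev in names(part$levels)) {
    roi_full <- fx$roi_set$levels[[lev]]$mask
    for (ri in seq_along(part$region_names)) {
      pr <- part$levels[[lev]][[ri]]
      in_region <- which(fx$boundary & ph$regions == ri)
      expect_equal(sort(c(pr$roi, pr$rroi)), in_region)
      expect_length(intersect(pr$roi, pr$rroi), 0)
      # rROI excludes the *full* ROI, not only the regional part
      expect_false(any(roi_full[pr$rroi]))
    }
  }
  # degenerate ROIs
  empty_rs <- structure(list(levels = list(
    low = list(mask = array(FALSE, dim(fx$boundary)), threshold = 0, size = 0)),
    boundary = fx$boundary), class = "roi_set")
  p0 <- define_rrois(empty_rs, ph$regions)
  expect_equal(length(p0$levels$low$frontal$rroi),
               sum(fx$boundary & ph$regions == 1))
  expect_length(p0$levels$low$frontal$roi, 0)
})
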