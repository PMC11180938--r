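# shared fixtures and independent oracles

# brute-force Euclidean distance from every voxel of `dim` to the nearest
# TRUE voxel of mask, voxel-center to voxel-center, anisotropic spacing
brute_force_distance <- function(mask, spacing) {
  d <- dim(mask)
  src <- arrayInd(which(mask), d)
  src_mm <- sweep(src - 1, 2, spacing, `*`)
  all_mm <- sweep(arrayInd(seq_len(prod(d)), d) - 1, 2, spacing, `*`)
  out <- vapply(seq_len(nrow(all_mm)), function(i) {
    sqrt(min(colSums((t(src_mm) - all_mm[i, ])^2)))
  }, 0)
  array(out, d)
}

# brute-force step-up BH: p_adj(i) = min_{j >= i} (m / j) * p_(j), capped at 1
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min((m / i:m) * ps[i:m]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# straight-field toy grid: all-brain box with a flat boundary plane at the
# top and a uniform +z orientation field
straight_field_grid <- function(d = c(9L, 9L, 9L), spacing = c(1, 1, 1)) {
  brain <- array(TRUE, d)
  boundary <- array(FALSE, d)
  boundary[, , d[3]] <- TRUE
  dir <- array(0, c(d, 3))
  dir[, , , 3] <- 1
  field <- orientation_field(dir, 0, array(TRUE, d))
  list(brain = brain, boundary = boundary, field = field, spacing = spacing)
}

# a synthetic connectivity map with prescribed counts, for threshold tests
fake_cmap <- function(counts, total) {
  structure(list(counts = counts, total_streamlines = total,
                 n_success = sum(counts), n_failure = total - sum(counts),
                 samples_per_voxel = NA, n_seed_voxels = NA),
            class = "connectivity_map")
}

# memoized default phantom + tracking, shared across test files
.fixture_env <- new.env(parent = emptyenv())

default_tracked <- function() {
  if (is.null(.fixture_env$tracked)) {
    ph <- make_phantom(phantom_config())
    bnd <- ph$tissue == tissue_codes()[["wm_gm_boundary"]]
    cm <- track_streamlines(ph$wmh, ph$field, bnd, ph$brain, ph$spacing_mm,
                            tracking_params(seed = 20260923))
    rs <- threshold_roi_set(cm, bnd)
    .fixture_env$tracked <- list(phantom = ph, boundary = bnd, cmap = cm,
                                 roi_set = rs)
  }
  .fixture_env$tracked
}
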