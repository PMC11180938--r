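#' @title Voxel-grid helpers
#' @description Internal conventions: volumes are plain 3D arrays; voxel
#'   indexing is 0-based in world terms, so the voxel at array position
#'   `(i, j, k)` (1-based in R) has its center at `((i,j,k) - 1) * spacing`
#'   millimeters. All distances and step sizes are in mm.
#' @name volume-helpers
#' @keywords internal
NULL

#' Attach a voxel spacing to a volume array
#'
#' @param x 3D array.
#' @param spacing_mm numeric length-3 voxel size in mm (or scalar, recycled).
#' @return `x` with a `spacing_mm` attribute.
#' @export
as_volume <- function(x, spacing_mm) {
  stopifnot(length(dim(x)) == 3L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("spacing_mm must be positive")
  attr(x, "spacing_mm") <- spacing_mm
  x
}

spacing_of <- function(x, spacing_mm = NULL) {
  s <- if (is.null(spacing_mm)) attr(x, "spacing_mm") else spacing_mm
  if (is.null(s)) stop("no spacing_mm given and none attached to the volume")
  rep_len(as.numeric(s), 3L)
}

check_same_grid <- function(a, b, what_a = "first volume", what_b = "second volume") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("grid mismatch: %s has dim %s but %s has dim %s",
                 what_a, paste(dim(a), collapse = "x"),
                 what_b, paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

# all 26 neighbor offsets as a 26 x 3 integer matrix
neighbor_offsets_26 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# logical volume: voxels of `mask` having at least one 26-neighbor in `other`
adjacent_to <- function(mask, other) {
  check_same_grid(mask, other)
  d <- dim(mask)
  out <- array(FALSE, d)
  off <- neighbor_offsets_26()
  for (r in seq_len(nrow(off))) {
    sh <- shift_array(other, off[r, ])
    out <- out | sh
  }
  out & mask
}

# shift a logical array by an integer offset, padding with FALSE
shift_array <- function(x, off) {
  d <- dim(x)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3L)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) {
      src[[a]] <- seq_len(d[a] - o)
      dst[[a]] <- src[[a]] + o
    } else {
      src[[a]] <- seq(1 - o, d[a])
      dst[[a]] <- src[[a]] + o
    }
    if (length(src[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# world coordinates (mm) of voxel centers for 1-based array indices
voxel_centers_mm <- function(idx_mat, spacing_mm) {
  sweep(idx_mat - 1, 2L, spacing_mm, `*`)
}

# seed the R RNG locally, restoring the caller's stream on exit
local_seed <- function(seed, envir = parent.frame()) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  expr <- if (has_seed) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(seed)
}
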