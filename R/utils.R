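# Internal helpers shared across modules. Conventions used everywhere:
# 3-D grids are R arrays with dim = (nz, ny, nx); voxel (z, y, x) is 0-based
# in code that talks to the C++ kernels and 1-based when indexing R arrays.
# Physical coordinates are micrometres with the origin at the centre of voxel
# (0, 0, 0), so voxel i sits at i * spacing along each axis.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

check_spacing <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop_arg("spacing must be three positive numbers (z, y, x) in micrometres")
  }
  as.numeric(spacing)
}

# linear (1-based) index into a (nz, ny, nx) array from 0-based (z, y, x)
zyx_to_lin <- function(zyx, dims) {
  1L + zyx[, 1L] + dims[1L] * (zyx[, 2L] + dims[2L] * zyx[, 3L])
}

# 0-based (z, y, x) matrix from 1-based linear indices
lin_to_zyx <- function(idx, dims) {
  arrayInd(idx, dims) - 1L
}

# physical coordinates (um) of voxel centres, rows matching idx
lin_to_um <- function(idx, dims, spacing) {
  sweep(lin_to_zyx(idx, dims), 2L, spacing, `*`)
}

# anisotropic Euclidean distance between two (z, y, x) voxel index vectors
vox_dist_um <- function(a, b, spacing) {
  sqrt(sum(((a - b) * spacing)^2))
}

# order rows lexicographically by (z, y, x); returns the order permutation
order_zyx <- function(zyx) {
  order(zyx[, 1L], zyx[, 2L], zyx[, 3L])
}

# 6-connectivity surface of a logical mask: voxels with at least one face
# neighbour outside the set (the grid boundary counts as outside)
surface_mask <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  fg <- which(mask)
  if (length(fg) == 0L) return(out)
  inside <- rep(TRUE, length(fg))
  zyx <- lin_to_zyx(fg, d)
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- zyx
      nb[, ax] <- nb[, ax] + s
      off_grid <- nb[, ax] < 0L | nb[, ax] >= d[ax]
      lin <- rep(NA_integer_, nrow(nb))
      lin[!off_grid] <- zyx_to_lin(nb[!off_grid, , drop = FALSE], d)
      nb_bg <- off_grid | !mask[lin]
      nb_bg[is.na(nb_bg)] <- TRUE
      inside <- inside & !nb_bg
    }
  }
  out[fg[!inside]] <- TRUE
  out
}

# exact anisotropic EDT wrapper: distance (um) from every voxel centre to the
# nearest TRUE voxel centre, plus that voxel's 1-based linear index
edt_um <- function(feature, spacing) {
  d <- dim(feature)
  res <- .edt_cpp(as.logical(feature), as.integer(d), as.numeric(spacing))
  dist <- array(res$dist, d)
  index <- array(ifelse(res$index >= 0L, res$index + 1L, NA_integer_), d)
  list(dist = dist, index = index)
}

geodesic_um <- function(foreground, seeds, spacing) {
  d <- dim(foreground)
  array(.geodesic_cpp(as.logical(foreground), as.logical(seeds),
                      as.integer(d), as.numeric(spacing)), d)
}

# replicate-edge padding of a 3-D logical/numeric array
pad_replicate <- function(arr, pad) {
  d <- dim(arr)
  iz <- pmin(pmax(seq_len(d[1L] + 2L * pad[1L]) - pad[1L], 1L), d[1L])
  iy <- pmin(pmax(seq_len(d[2L] + 2L * pad[2L]) - pad[2L], 1L), d[2L])
  ix <- pmin(pmax(seq_len(d[3L] + 2L * pad[3L]) - pad[3L], 1L), d[3L])
  arr[iz, iy, ix, drop = FALSE]
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 &&
  x == round(x)
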