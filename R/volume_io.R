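# Volume, label-map and skeleton containers plus all file I/O.
#
# Axis conventions (fixed, tested): voxel arrays are (channel, z, y, x) for
# images and (z, y, x) for label maps; TIFF page order is z-fastest within
# channel, i.e. page p (0-based) holds channel p %/% nz, plane p %% nz.
# Coordinates are 0-based voxel indices internally; every exported table and
# SWC file uses physical micrometres with the origin at the centre of voxel
# (0, 0, 0). Voxel spacing comes from the caller/config, not from TIFF tags
# (resolution-tag dialects are too unreliable to trust).

#' Spine-pipeline semantic class codes
#'
#' The label maps consumed by this package encode five semantic classes.
#' External segmenters using different integer codes can be remapped via the
#' `class_codes` argument of [semantic_labels()] / [read_labels()].
#'
#' @return Named integer vector: background 0, dendrite 1, soma 2,
#'   spine_head 3, spine_neck 4.
#' @export
spine_class_codes <- function() {
  c(background = 0L, dendrite = 1L, soma = 2L, spine_head = 3L, spine_neck = 4L)
}

#' Construct a volume image
#'
#' A `volume_image` is an n-channel 3-D voxel grid with physical voxel
#' spacing. 2-D `[y, x]` and 3-D `[z, y, x]` inputs are promoted to the
#' canonical 4-D `(channel, z, y, x)` layout.
#'
#' @param voxels Numeric array: `[y, x]`, `[z, y, x]` or `[c, z, y, x]`.
#' @param spacing Voxel size `(z, y, x)` in micrometres, all positive.
#' @param channel_names Optional character vector, one per channel.
#' @return An object of class `volume_image` with elements `voxels` (4-D
#'   array), `spacing` and `channel_names`.
#' @export
volume_image <- function(voxels, spacing, channel_names = NULL) {
  spacing <- check_spacing(spacing)
  if (is.null(dim(voxels))) stop_arg("voxels must be a 2-D, 3-D or 4-D array")
  nd <- length(dim(voxels))
  if (nd == 2L) dim(voxels) <- c(1L, 1L, dim(voxels))
  else if (nd == 3L) dim(voxels) <- c(1L, dim(voxels))
  else if (nd != 4L) stop_arg("voxels must be a 2-D, 3-D or 4-D array")
  if (any(dim(voxels) < 1L)) stop_arg("every axis must have extent >= 1")
  nc <- dim(voxels)[1L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc) stop_arg("channel_names must have one entry per channel")
  structure(list(voxels = voxels, spacing = spacing,
                 channel_names = as.character(channel_names)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_image> %d channel(s), grid %d x %d x %d (z,y,x), spacing %.4g/%.4g/%.4g um\n",
              d[1], d[2], d[3], d[4], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$voxels)

#' Construct a semantic label map
#'
#' @param labels Integer array `[z, y, x]` (2-D inputs are promoted to depth
#'   1); every value must be one of `class_codes`.
#' @param spacing Voxel size `(z, y, x)` in micrometres.
#' @param class_codes Named integer vector mapping class names to codes;
#'   defaults to [spine_class_codes()].
#' @return An object of class `semantic_labels`.
#' @export
semantic_labels <- function(labels, spacing, class_codes = spine_class_codes()) {
  spacing <- check_spacing(spacing)
  if (is.null(dim(labels))) stop_arg("labels must be a 2-D or 3-D array")
  if (length(dim(labels)) == 2L) dim(labels) <- c(1L, dim(labels))
  if (length(dim(labels)) != 3L) stop_arg("labels must be a 2-D or 3-D array")
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), as.integer(class_codes))
  if (length(bad) > 0L) {
    stop_arg("label map contains undeclared class codes: ",
             paste(sort(bad), collapse = ", "))
  }
  structure(list(labels = labels, spacing = spacing, class_codes = class_codes),
            class = "semantic_labels")
}

#' @export
print.semantic_labels <- function(x, ...) {
  d <- dim(x$labels)
  counts <- vapply(x$class_codes, function(v) sum(x$labels == v), numeric(1))
  cat(sprintf("<semantic_labels> grid %d x %d x %d (z,y,x), spacing %.4g/%.4g/%.4g um\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat("  voxels:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

class_mask <- function(m, class) {
  m$labels == m$class_codes[[class]]
}

check_congruent <- function(v, m) {
  if (!all(dim(v$voxels)[2:4] == dim(m$labels)) ||
      !isTRUE(all.equal(v$spacing, m$spacing))) {
    stop_arg("image and label map must share grid shape and spacing")
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# TIFF volumes

#' Read a TIFF volume
#'
#' Reads a single- or multi-page grayscale TIFF into a [volume_image()].
#' Multi-channel stacks must be stored as channel blocks with z varying
#' fastest within each channel (page `p` = channel `p %/% nz`, plane
#' `p %% nz`); pass `channels` to demultiplex.
#'
#' @param path TIFF file path.
#' @param spacing Voxel size `(z, y, x)` in micrometres (not read from tags).
#' @param channels Number of channels interleaved in the page sequence.
#' @param channel_names Optional channel names.
#' @return A [volume_image()] with shape `(channels, pages/channels, y, x)`.
#' @export
read_volume <- function(path, spacing, channels = 1L, channel_names = NULL) {
  spacing <- check_spacing(spacing)
  if (!is_count(channels)) stop_arg("channels must be a positive integer")
  pages <- read_tiff_pages(path)
  np <- length(pages)
  if (np %% channels != 0L) {
    stop_arg("page count ", np, " is not a multiple of channels = ", channels)
  }
  d2 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d2), logical(1)))) {
    stop("cannot read TIFF (pages differ in shape): ", path, call. = FALSE)
  }
  nz <- np %/% channels
  vox <- array(0, c(channels, nz, d2[1L], d2[2L]))
  for (p in seq_len(np)) {
    ch <- (p - 1L) %/% nz + 1L
    z <- (p - 1L) %% nz + 1L
    vox[ch, z, , ] <- pages[[p]]
  }
  volume_image(vox, spacing, channel_names)
}

#' Write a TIFF volume
#'
#' Writes a [volume_image()] as an uncompressed multi-page grayscale TIFF
#' (page order: channel blocks, z fastest). Integer data in range are written
#' losslessly as uint8/uint16, everything else as float32.
#'
#' @param v A [volume_image()].
#' @param path Output path.
#' @param type Pixel type, `"auto"` (default), `"uint8"`, `"uint16"` or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, type = "auto") {
  stopifnot(inherits(v, "volume_image"))
  d <- dim(v$voxels)
  pages <- vector("list", d[1L] * d[2L])
  k <- 0L
  for (ch in seq_len(d[1L])) {
    for (z in seq_len(d[2L])) {
      k <- k + 1L
      pages[[k]] <- array(v$voxels[ch, z, , ], d[3:4])
    }
  }
  write_tiff_pages(pages, path, type = type)
}

#' Read a semantic label map from TIFF
#'
#' @inheritParams read_volume
#' @param class_codes Class-code mapping, default [spine_class_codes()].
#' @return A [semantic_labels()].
#' @export
read_labels <- function(path, spacing, class_codes = spine_class_codes()) {
  v <- read_volume(path, spacing)
  semantic_labels(array(as.integer(round(v$voxels[1L, , , ])), dim(v$voxels)[2:4]),
                  spacing, class_codes)
}

#' Write a semantic label map (or any integer array) to TIFF
#'
#' @param m A [semantic_labels()] object or a 3-D integer array.
#' @param path Output path.
#' @param spacing Required only when `m` is a bare array (unused in the file;
#'   kept for call symmetry).
#' @return `path`, invisibly.
#' @export
write_labels <- function(m, path, spacing = NULL) {
  arr <- if (inherits(m, "semantic_labels")) m$labels else m
  if (length(dim(arr)) != 3L) stop_arg("label array must be 3-D (z, y, x)")
  pages <- lapply(seq_len(dim(arr)[1L]), function(z) array(arr[z, , ], dim(arr)[2:3]))
  write_tiff_pages(pages, path, type = "uint16")
}

# ---------------------------------------------------------------------------
# Rescaling

resize_axis_linear <- function(arr, axis, n_out) {
  d <- dim(arr)
  n_in <- d[axis]
  if (n_out == n_in) return(arr)
  # centre-aligned mapping: output centre i maps to (i + 0.5) * n_in/n_out - 0.5
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- pmin(pmax(floor(src), 0), n_in - 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  w <- pmin(pmax(src - i0, 0), 1)
  idx <- function(i) {
    ix <- list(quote(expr = ), quote(expr = ), quote(expr = ))[seq_along(d)]
    ix[[axis]] <- i + 1
    do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
  }
  a0 <- idx(i0)
  a1 <- idx(i1)
  warr <- array(rep(w, each = prod(d[seq_len(axis - 1)])),
                replace(d, axis, n_out))
  a0 * (1 - warr) + a1 * warr
}

resize_axis_nearest <- function(arr, axis, n_out) {
  d <- dim(arr)
  n_in <- d[axis]
  if (n_out == n_in) return(arr)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i <- pmin(pmax(round(src), 0), n_in - 1) + 1
  ix <- list(quote(expr = ), quote(expr = ), quote(expr = ))[seq_along(d)]
  ix[[axis]] <- i
  do.call(`[`, c(list(arr), ix, list(drop = FALSE)))
}

resize3d <- function(arr, out_dim, order) {
  f <- if (order == "nearest") resize_axis_nearest else resize_axis_linear
  for (ax in 1:3) arr <- f(arr, ax, out_dim[ax])
  arr
}

#' Rescale a volume or label map to a new voxel spacing
#'
#' Resamples between acquisition and analysis resolutions. Output dimensions
#' are `round(dim * spacing / target_spacing)` (minimum 1). Label maps must
#' use `order = "nearest"` so that no new class codes appear; [rescale_labels()]
#' enforces this.
#'
#' @param v A [volume_image()].
#' @param target_spacing Desired `(z, y, x)` spacing in micrometres.
#' @param order Interpolation, `"linear"` (default for images) or `"nearest"`.
#' @return A [volume_image()] at `target_spacing`.
#' @export
rescale_volume <- function(v, target_spacing, order = c("linear", "nearest")) {
  stopifnot(inherits(v, "volume_image"))
  order <- match.arg(order)
  target_spacing <- check_spacing(target_spacing)
  d <- dim(v$voxels)
  out_dim <- pmax(1L, as.integer(round(d[2:4] * v$spacing / target_spacing)))
  if (isTRUE(all.equal(v$spacing, target_spacing)) && all(out_dim == d[2:4])) return(v)
  out <- array(0, c(d[1L], out_dim))
  for (ch in seq_len(d[1L])) {
    out[ch, , , ] <- resize3d(array(v$voxels[ch, , , ], d[2:4]), out_dim, order)
  }
  volume_image(out, target_spacing, v$channel_names)
}

#' @rdname rescale_volume
#' @param m A [semantic_labels()].
#' @export
rescale_labels <- function(m, target_spacing) {
  stopifnot(inherits(m, "semantic_labels"))
  target_spacing <- check_spacing(target_spacing)
  d <- dim(m$labels)
  out_dim <- pmax(1L, as.integer(round(d * m$spacing / target_spacing)))
  if (isTRUE(all.equal(m$spacing, target_spacing)) && all(out_dim == d)) return(m)
  out <- resize3d(m$labels, out_dim, "nearest")
  semantic_labels(out, target_spacing, m$class_codes)
}

# ---------------------------------------------------------------------------
# Skeleton trees and SWC

#' Construct a skeleton tree
#'
#' A dendrite/soma centreline as a rooted forest. Node coordinates are in
#' micrometres (origin at the centre of voxel (0,0,0)).
#'
#' @param nodes `data.frame` with columns `id`, `type` (SWC structure code:
#'   1 soma, 3 dendrite), `z`, `y`, `x` (um), `radius` (um) and `parent`
#'   (`-1` for roots). Parent references must form a forest.
#' @return An object of class `skeleton_tree` (a validated `data.frame`).
#' @export
skeleton_tree <- function(nodes) {
  need <- c("id", "type", "z", "y", "x", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    stop_arg("nodes must have columns ", paste(need, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[need]
  if (anyDuplicated(nodes$id)) stop_arg("node ids must be unique")
  known <- nodes$parent == -1L | nodes$parent %in% nodes$id
  if (!all(known)) stop_arg("parent ids must exist or be -1")
  # forest check: following parents must terminate (no cycles)
  pmap <- match(nodes$parent, nodes$id)
  for (i in seq_len(nrow(nodes))) {
    seen <- integer(0)
    j <- i
    while (!is.na(pmap[j])) {
      if (j %in% seen) stop("skeleton parent references contain a cycle", call. = FALSE)
      seen <- c(seen, j)
      j <- pmap[j]
    }
  }
  structure(nodes, class = c("skeleton_tree", "data.frame"))
}

#' @export
print.skeleton_tree <- function(x, ...) {
  cat(sprintf("<skeleton_tree> %d node(s), %d root(s), length %.3f um\n",
              nrow(x), sum(x$parent == -1L), dendrite_length(x)))
  invisible(x)
}

#' Write a skeleton tree to SWC
#'
#' Standard SWC text: one line per node with `id type x y z radius parent`,
#' ids renumbered contiguously from 1 with every parent preceding its
#' children. Roots inside the soma carry structure code 1, all other nodes 3.
#'
#' @param tree A [skeleton_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  tree <- skeleton_tree(tree)
  n <- nrow(tree)
  if (n == 0L) stop_arg("cannot write an empty skeleton")
  # topological order: parents before children
  ord <- integer(0)
  pmap <- match(tree$parent, tree$id)
  remaining <- seq_len(n)
  placed <- logical(n)
  while (length(ord) < n) {
    ready <- remaining[!placed[remaining] &
                         (is.na(pmap[remaining]) | placed[pmap[remaining]])]
    if (length(ready) == 0L) stop("skeleton parent references contain a cycle", call. = FALSE)
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  newid <- integer(n)
  newid[ord] <- seq_len(n)
  lines <- character(n + 1L)
  lines[1L] <- "# SWC export: id type x y z radius parent (um)"
  for (k in seq_len(n)) {
    i <- ord[k]
    par <- if (is.na(pmap[i])) -1L else newid[pmap[i]]
    lines[k + 1L] <- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                             newid[i], tree$type[i], tree$x[i], tree$y[i],
                             tree$z[i], tree$radius[i], par)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an SWC file back into a skeleton tree
#'
#' @param path SWC file path.
#' @return A [skeleton_tree()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("SWC file has no nodes: ", path, call. = FALSE)
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  skeleton_tree(data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                           z = m[, 5], y = m[, 4], x = m[, 3],
                           radius = m[, 6], parent = as.integer(m[, 7])))
}

# ---------------------------------------------------------------------------
# Measurement tables

spine_table_columns <- function(channel_names = "ch1") {
  c("instance_id", "volume_um3", "head_volume_um3",
    "centroid_z_um", "centroid_y_um", "centroid_x_um",
    "spine_length_um", "neck_length_um", "head_width_um",
    "distance_to_dendrite_um", "soma_distance_euclid_um", "soma_distance_geodesic_um",
    as.vector(t(outer(channel_names, c("mean", "max", "integrated"),
                      function(a, b) paste0("intensity_", b, "_", a)))))
}

#' Write the per-spine measurement table
#'
#' Fixed-schema UTF-8 CSV ("." decimal), one row per spine. Missing
#' measurements are written as empty fields, never as 0. Columns:
#' `instance_id`, `volume_um3` (head + neck), `head_volume_um3`, centroid
#' `(z, y, x)` in um, `spine_length_um`, `neck_length_um`, `head_width_um`,
#' `distance_to_dendrite_um`, `soma_distance_euclid_um`,
#' `soma_distance_geodesic_um`, then per-channel
#' `intensity_{mean,max,integrated}_<channel>`.
#'
#' @param records Per-spine `data.frame` as returned by [measure_spines()]
#'   (may have zero rows).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spine_table <- function(records, path) {
  if (is.null(records) || nrow(as.data.frame(records)) == 0L) {
    chn <- attr(records, "channel_names") %||% "ch1"
    records <- as.data.frame(matrix(numeric(0), ncol = length(spine_table_columns(chn)),
                                    dimnames = list(NULL, spine_table_columns(chn))))
  }
  utils::write.csv(records, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write per-dendrite / per-image summary tables
#'
#' @param summaries `data.frame` of summary rows (see [summarize_spines()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path) {
  utils::write.csv(as.data.frame(summaries), path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
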