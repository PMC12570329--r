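# Instance extraction: turn semantic head/neck labels into individual spine
# objects, attach each to the dendrite shaft, and filter spurious detections.
#
# Instances are the connected components of (head union neck). Default
# connectivity is 26: thin anisotropic necks fragment under 6-connectivity at
# 150 nm z-steps. Touching spines are not split; the upstream segmenter is
# expected to separate instances.

new_spine_instance <- function(instance_id, head_idx, neck_idx, dims, spacing) {
  structure(list(instance_id = instance_id,
                 head_idx = head_idx,     # 1-based linear indices, may be empty
                 neck_idx = neck_idx,
                 dims = dims, spacing = spacing,
                 attachment = NULL,       # 0-based (z, y, x) dendrite voxel
                 distance_to_dendrite_um = NA_real_),
            class = "spine_instance")
}

#' @export
print.spine_instance <- function(x, ...) {
  cat(sprintf("<spine_instance> id %d: %d head + %d neck voxel(s), volume %.4f um3\n",
              x$instance_id, length(x$head_idx), length(x$neck_idx),
              instance_volume_um3(x)))
  invisible(x)
}

instance_voxels <- function(s) c(s$head_idx, s$neck_idx)

instance_volume_um3 <- function(s) {
  (length(s$head_idx) + length(s$neck_idx)) * prod(s$spacing)
}

#' Extract spine instances from a semantic label map
#'
#' Connected components of the spine-head and spine-neck classes under the
#' chosen connectivity become individual spine instances; within each
#' instance, voxels keep their head/neck identity. Instance ids are assigned
#' in descending component size, ties broken by the lexicographically
#' smallest (z, y, x) voxel of the component.
#'
#' @param m A [semantic_labels()] map.
#' @param connectivity Voxel adjacency: 6 (faces), 18 (+edges) or 26
#'   (+corners, default).
#' @return A list of `spine_instance` objects (possibly empty).
#' @export
extract_spine_instances <- function(m, connectivity = 26L) {
  stopifnot(inherits(m, "semantic_labels"))
  if (!connectivity %in% c(6L, 18L, 26L)) stop_arg("connectivity must be 6, 18 or 26")
  d <- dim(m$labels)
  head_mask <- class_mask(m, "spine_head")
  neck_mask <- class_mask(m, "spine_neck")
  mask <- head_mask | neck_mask
  if (!any(mask)) return(list())
  lab <- array(.cc_label_cpp(as.logical(mask), as.integer(d), as.integer(connectivity)), d)
  ncomp <- max(lab)
  fg <- which(lab > 0L)
  comp <- lab[fg]
  zyx <- lin_to_zyx(fg, d)
  sizes <- tabulate(comp, ncomp)
  # per component, its lexicographically smallest (z, y, x) voxel
  ord_vox <- order(comp, zyx[, 1L], zyx[, 2L], zyx[, 3L])
  first_of <- ord_vox[!duplicated(comp[ord_vox])]
  min_zyx <- zyx[first_of, , drop = FALSE][order(comp[first_of]), , drop = FALSE]
  rank <- order(-sizes, min_zyx[, 1L], min_zyx[, 2L], min_zyx[, 3L])
  out <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    cid <- rank[k]
    vox <- fg[comp == cid]
    out[[k]] <- new_spine_instance(
      instance_id = k,
      head_idx = vox[head_mask[vox]],
      neck_idx = vox[neck_mask[vox]],
      dims = d, spacing = m$spacing)
  }
  out
}

#' Build an instance label array from spine instances
#'
#' Inverse of [extract_spine_instances()]: a `uint16`-style integer array with
#' 0 = background and k = instance k, suitable for audit output and for the
#' object-level validation/tracking functions.
#'
#' @param instances List of `spine_instance` objects.
#' @param dims Grid shape `(nz, ny, nx)`; defaults to the instances' grid.
#' @return 3-D integer array.
#' @export
instance_map <- function(instances, dims = NULL) {
  if (length(instances) == 0L && is.null(dims)) stop_arg("dims required for empty instance list")
  dims <- dims %||% instances[[1L]]$dims
  out <- array(0L, dims)
  for (s in instances) out[instance_voxels(s)] <- s$instance_id
  out
}

#' Attach spine instances to the dendrite shaft
#'
#' Fills `attachment` (the dendrite voxel nearest the instance; ties broken
#' by smallest (z, y, x)) and `distance_to_dendrite_um` (minimum anisotropic
#' Euclidean distance between any spine voxel centre and any dendrite voxel
#' centre) for each instance.
#'
#' @param instances A single `spine_instance` or a list of them.
#' @param m The [semantic_labels()] map (dendrite class must be non-empty).
#' @return Instances of the same shape as the input, with attachment and
#'   distance populated.
#' @export
attach_to_dendrite <- function(instances, m) {
  stopifnot(inherits(m, "semantic_labels"))
  single <- inherits(instances, "spine_instance")
  if (single) instances <- list(instances)
  dend <- class_mask(m, "dendrite")
  if (!any(dend)) {
    stop("dendrite class is empty: cannot attach spines (soma/geodesic metrics would be undefined)",
         call. = FALSE)
  }
  d <- dim(m$labels)
  e <- edt_um(dend, m$spacing)
  for (k in seq_along(instances)) {
    s <- instances[[k]]
    vox <- instance_voxels(s)
    dist <- e$dist[vox]
    dmin <- min(dist)
    # spine voxel achieving the minimum; ties by smallest (z, y, x)
    cand <- vox[dist <= dmin + 1e-12]
    czyx <- lin_to_zyx(cand, d)
    src <- czyx[order_zyx(czyx)[1L], ]
    # exact dendrite-side tie-break: enumerate dendrite voxels at distance dmin
    # within the bounding box that can contain them
    r_vox <- ceiling(dmin / m$spacing) + 1L
    lo <- pmax(src - r_vox, 0L)
    hi <- pmin(src + r_vox, d - 1L)
    sub <- dend[(lo[1L] + 1L):(hi[1L] + 1L), (lo[2L] + 1L):(hi[2L] + 1L),
                (lo[3L] + 1L):(hi[3L] + 1L), drop = FALSE]
    dv <- which(sub)
    stopifnot(length(dv) > 0L)
    dzyx <- sweep(lin_to_zyx(dv, dim(sub)), 2L, lo, `+`)
    dd <- sqrt(colSums((t(dzyx) - src)^2 * m$spacing^2))
    at <- dzyx[dd <= dmin + 1e-9, , drop = FALSE]
    at <- at[order_zyx(at)[1L], ]
    s$attachment <- as.integer(at)
    s$distance_to_dendrite_um <- dmin
    instances[[k]] <- s
  }
  if (single) instances[[1L]] else instances
}

#' Filter specification for spurious-detection removal
#'
#' Defaults follow the published spinning-disk analysis settings: spine
#' volumes outside 0.035--2 um^3 are rejected, as are instances farther than
#' `max_distance_to_dendrite_um` from the shaft.
#'
#' @param min_volume_um3,max_volume_um3 Volume bounds (um^3), `0 <= min < max`.
#' @param max_distance_to_dendrite_um Maximum gap to the dendrite (um).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(min_volume_um3 = 0.035, max_volume_um3 = 2,
                        max_distance_to_dendrite_um = 1) {
  if (!(min_volume_um3 >= 0 && min_volume_um3 < max_volume_um3)) {
    stop_arg("need 0 <= min_volume_um3 < max_volume_um3")
  }
  if (max_distance_to_dendrite_um < 0) stop_arg("max_distance_to_dendrite_um must be >= 0")
  structure(list(min_volume_um3 = min_volume_um3, max_volume_um3 = max_volume_um3,
                 max_distance_to_dendrite_um = max_distance_to_dendrite_um),
            class = "filter_spec")
}

#' Filter spine instances by volume and dendrite distance
#'
#' An instance is kept iff `min <= volume <= max` and
#' `distance_to_dendrite <= max_distance`, with volume = voxel count x voxel
#' volume over head + neck. Kept instances are relabelled 1..K preserving
#' order; rejected instances carry the first violated rule
#' (`"min_volume"`, `"max_volume"` or `"max_distance"`) in `$reject_reason`.
#' The operation is idempotent.
#'
#' @param instances List of attached `spine_instance` objects
#'   ([attach_to_dendrite()] must have run when a distance rule is active).
#' @param spec A [filter_spec()].
#' @return `list(kept = ..., rejected = ...)`.
#' @export
filter_spines <- function(instances, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  kept <- list()
  rejected <- list()
  for (s in instances) {
    vol <- instance_volume_um3(s)
    reason <- NULL
    if (vol < spec$min_volume_um3) reason <- "min_volume"
    else if (vol > spec$max_volume_um3) reason <- "max_volume"
    else if (!is.na(s$distance_to_dendrite_um) &&
             s$distance_to_dendrite_um > spec$max_distance_to_dendrite_um) {
      reason <- "max_distance"
    }
    if (is.null(reason)) {
      s$instance_id <- length(kept) + 1L
      kept[[length(kept) + 1L]] <- s
    } else {
      s$reject_reason <- reason
      rejected[[length(rejected) + 1L]] <- s
    }
  }
  list(kept = kept, rejected = rejected)
}
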