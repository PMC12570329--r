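# Longitudinal spine tracking: rigid translational registration by phase
# correlation, resampling of images/label maps, one-to-one IoU matching of
# spine instances across time points, and turnover statistics
# (stable / formed / eliminated).

#' Rigid (translation) registration by phase correlation
#'
#' Estimates the integer + subvoxel translation aligning `moving` to `fixed`
#' from the phase-correlation peak of one reference channel, refined by
#' quadratic peak interpolation per axis. Deterministic; errors on constant
#' (degenerate) images. Non-rigid correction is deliberately an adapter:
#' apply an externally computed displacement field before analysis instead.
#'
#' @param fixed,moving [volume_image()]s on grids of identical shape and
#'   spacing, or bare 3-D arrays.
#' @param channel Reference channel (default 1).
#' @return An object of class `rigid_transform` with `translation`
#'   `(z, y, x)` in voxels (apply to `moving` to align it to `fixed`) and
#'   `shape`.
#' @export
register_rigid <- function(fixed, moving, channel = 1L) {
  get_arr <- function(v) {
    if (inherits(v, "volume_image")) array(v$voxels[channel, , , ], dim(v$voxels)[2:4])
    else if (is.array(v) && length(dim(v)) == 3L) v
    else stop_arg("inputs must be volume_image objects or 3-D arrays")
  }
  a <- get_arr(fixed)
  b <- get_arr(moving)
  if (!identical(dim(a), dim(b))) stop_arg("fixed and moving grids must have identical shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("cannot register a constant (degenerate) image", call. = FALSE)
  }
  d <- dim(a)
  fa <- stats::fft(a)
  fb <- stats::fft(b)
  cross <- fa * Conj(fb)
  r <- Re(stats::fft(cross / pmax(Mod(cross), 1e-12), inverse = TRUE)) / length(cross)
  peak <- arrayInd(which.max(r), d)[1L, ]
  # quadratic subvoxel refinement per axis using wrapped neighbours
  sub <- numeric(3L)
  for (ax in 1:3) {
    pick <- function(off) {
      i <- peak
      i[ax] <- ((i[ax] - 1L + off) %% d[ax]) + 1L
      r[matrix(i, 1L)]
    }
    y0 <- pick(-1L); y1 <- pick(0L); y2 <- pick(1L)
    den <- y0 - 2 * y1 + y2
    sub[ax] <- if (abs(den) > 1e-12) max(-0.5, min(0.5, 0.5 * (y0 - y2) / den)) else 0
  }
  t_peak <- peak - 1L + sub
  t_peak <- ifelse(t_peak > d / 2, t_peak - d, t_peak) # wrap to signed shifts
  # moving == fixed translated by +t puts the correlation peak at -t, which
  # is exactly the translation that re-aligns moving to fixed
  structure(list(translation = t_peak, shape = d), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> translation (z, y, x) = (%.3f, %.3f, %.3f) voxels\n",
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param t A `rigid_transform`.
#' @return The inverse transform.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  structure(list(translation = -t$translation, shape = t$shape),
            class = "rigid_transform")
}

# translate a 3-D array by t voxels (content moves by +t); linear or nearest
shift_array <- function(arr, t, order = c("linear", "nearest"), fill = 0) {
  order <- match.arg(order)
  d <- dim(arr)
  if (order == "nearest") t <- round(t)
  ti <- floor(t)
  fr <- t - ti
  shift_int <- function(a, s) {
    out <- array(fill, d)
    src_lo <- pmax(1 - s, 1); src_hi <- pmin(d - s, d)
    if (any(src_lo > src_hi)) return(out)
    dst <- lapply(1:3, function(ax) (src_lo[ax] + s[ax]):(src_hi[ax] + s[ax]))
    src <- lapply(1:3, function(ax) src_lo[ax]:src_hi[ax])
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  out <- shift_int(arr, ti)
  if (order == "linear" && any(fr > 1e-9)) {
    for (ax in 1:3) {
      if (fr[ax] <= 1e-9) next
      s1 <- rep(0, 3); s1[ax] <- 1
      out <- (1 - fr[ax]) * shift_int(out, rep(0L, 3L)) + fr[ax] * shift_int(out, s1)
    }
  }
  out
}

#' Apply a rigid transform to a volume, label map or instance map
#'
#' Images are resampled linearly, label/instance maps with nearest-neighbour
#' (integer-rounded translation) so that no new codes appear; out-of-frame
#' regions are filled with background/0.
#'
#' @param x A [volume_image()], [semantic_labels()] or 3-D integer array.
#' @param t A `rigid_transform` from [register_rigid()].
#' @return Object of the same type as `x`, resampled.
#' @export
apply_transform <- function(x, t) {
  stopifnot(inherits(t, "rigid_transform"))
  tr <- t$translation
  if (inherits(x, "volume_image")) {
    d <- dim(x$voxels)
    out <- x$voxels
    for (ch in seq_len(d[1L])) {
      out[ch, , , ] <- shift_array(array(x$voxels[ch, , , ], d[2:4]), tr, "linear")
    }
    volume_image(out, x$spacing, x$channel_names)
  } else if (inherits(x, "semantic_labels")) {
    semantic_labels(shift_array(x$labels, tr, "nearest", fill = x$class_codes[["background"]]),
                    x$spacing, x$class_codes)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    out <- shift_array(x, tr, "nearest", fill = 0L)
    storage.mode(out) <- storage.mode(x)
    out
  } else {
    stop_arg("x must be a volume_image, semantic_labels or 3-D array")
  }
}

#' Match spine instances across two time points
#'
#' One-to-one greedy descending-IoU matching of aligned instance maps at
#' `min_iou` (default 0.3 -- lower than the validation threshold of 0.5
#' because day-to-day morphological change legitimately lowers overlap).
#' Matched instances are `stable` and share a track id; unmatched t1
#' instances are `formed`, unmatched t0 instances `eliminated`.
#'
#' @param inst_t0,inst_t1 Aligned integer instance label arrays.
#' @param min_iou Overlap threshold for persistence.
#' @param spacing Optional `(z, y, x)` spacing (um) to fill per-timepoint
#'   volumes.
#' @return A `track_table` `data.frame` with columns `track_id`, `id_t0`,
#'   `id_t1`, `status`, `volume_t0_um3`, `volume_t1_um3`.
#' @export
match_across_time <- function(inst_t0, inst_t1, min_iou = 0.3, spacing = NULL) {
  mc <- match_objects(inst_t0, inst_t1, min_iou)
  size0 <- tabulate(inst_t0[inst_t0 > 0L], max(inst_t0, 0L))
  size1 <- tabulate(inst_t1[inst_t1 > 0L], max(inst_t1, 0L))
  vox_vol <- if (is.null(spacing)) NA_real_ else prod(check_spacing(spacing))
  vol0 <- size0 * vox_vol
  vol1 <- size1 * vox_vol
  # in match_objects terms, pred = t0 and gt = t1
  stable <- data.frame(id_t0 = mc$pairs$pred_id, id_t1 = mc$pairs$gt_id)
  elim <- setdiff(which(size0 > 0L), stable$id_t0)
  formed <- setdiff(which(size1 > 0L), stable$id_t1)
  rows <- rbind(
    if (nrow(stable)) data.frame(id_t0 = stable$id_t0, id_t1 = stable$id_t1,
                                 status = "stable"),
    if (length(elim)) data.frame(id_t0 = elim, id_t1 = NA_integer_,
                                 status = "eliminated"),
    if (length(formed)) data.frame(id_t0 = NA_integer_, id_t1 = formed,
                                   status = "formed"))
  if (is.null(rows)) {
    rows <- data.frame(id_t0 = integer(0), id_t1 = integer(0), status = character(0))
  }
  rows$track_id <- seq_len(nrow(rows))
  rows$volume_t0_um3 <- ifelse(is.na(rows$id_t0), NA_real_, vol0[rows$id_t0])
  rows$volume_t1_um3 <- ifelse(is.na(rows$id_t1), NA_real_, vol1[rows$id_t1])
  out <- rows[, c("track_id", "id_t0", "id_t1", "status",
                  "volume_t0_um3", "volume_t1_um3")]
  structure(out, class = c("track_table", "data.frame"))
}

#' Spine turnover summary
#'
#' Rates on the percentage scale: stable and eliminated relative to the
#' number of t0 spines, formed relative to the number of t1 spines; plus the
#' paired (t0, t1) volume table of stable spines.
#'
#' @param tt A `track_table` from [match_across_time()].
#' @return List with `n_t0`, `n_t1`, `stable_pct`, `eliminated_pct`,
#'   `formed_pct` and `stable_volumes` (`data.frame`).
#' @export
dynamics_summary <- function(tt) {
  n0 <- sum(!is.na(tt$id_t0))
  n1 <- sum(!is.na(tt$id_t1))
  n_stable <- sum(tt$status == "stable")
  list(n_t0 = n0, n_t1 = n1,
       stable_pct = if (n0 > 0) 100 * n_stable / n0 else NA_real_,
       eliminated_pct = if (n0 > 0) 100 * sum(tt$status == "eliminated") / n0 else NA_real_,
       formed_pct = if (n1 > 0) 100 * sum(tt$status == "formed") / n1 else NA_real_,
       stable_volumes = tt[tt$status == "stable",
                           c("track_id", "volume_t0_um3", "volume_t1_um3")])
}

#' Track spines across two imaging sessions
#'
#' Full two-timepoint workflow: register t1 to t0 on a reference channel,
#' resample the t1 instance map into the t0 frame, match instances and
#' summarise turnover. Longer series can be chained by successive pairwise
#' calls, propagating `track_id` forward.
#'
#' @param v_t0,v_t1 [volume_image()]s of the two sessions.
#' @param inst_t0,inst_t1 Instance label arrays in each session's own frame.
#' @param channel Registration channel.
#' @param min_iou Persistence threshold (default 0.3).
#' @return List with `transform`, `table` (a `track_table`) and `summary`.
#' @export
track_spines <- function(v_t0, v_t1, inst_t0, inst_t1, channel = 1L, min_iou = 0.3) {
  tr <- register_rigid(v_t0, v_t1, channel = channel)
  inst_t1_aligned <- apply_transform(inst_t1, tr)
  tt <- match_across_time(inst_t0, inst_t1_aligned, min_iou = min_iou,
                          spacing = v_t0$spacing)
  list(transform = tr, table = tt, summary = dynamics_summary(tt))
}
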