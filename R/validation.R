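# Pixel- and object-level validation of a predicted segmentation against
# ground truth: Dice/IoU per class, one-to-one object matching at an IoU
# threshold (TP/FP/FN, precision/recall/F1, F1 curves across thresholds) and
# the surface Hausdorff distance in micrometres.

#' Dice coefficient and IoU of two voxel sets
#'
#' `dice = 2|A n B| / (|A| + |B|)`, `iou = |A n B| / |A u B|`. When both sets
#' are empty the agreement is vacuous and both metrics are 1 by convention;
#' when exactly one is empty they are 0.
#'
#' @param a,b Logical arrays on congruent grids.
#' @return A fraction in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a); nb <- sum(b)
  if (na == 0L && nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' @rdname dice
#' @export
iou <- function(a, b) {
  check_same_grid(a, b)
  na <- sum(a); nb <- sum(b)
  if (na == 0L && nb == 0L) return(1)
  sum(a & b) / sum(a | b)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop_arg("voxel sets must live on congruent grids")
  invisible(TRUE)
}

# pairwise IoU of all overlapping (pred, gt) instance pairs; ids absent from
# a map (relabelling gaps) are not instances and are not counted
overlap_iou_pairs <- function(pred, gt) {
  check_same_grid(pred, gt)
  psize <- tabulate(pred[pred > 0L], max(pred, 0L))
  gsize <- tabulate(gt[gt > 0L], max(gt, 0L))
  np <- sum(psize > 0L); ng <- sum(gsize > 0L)
  both <- pred > 0L & gt > 0L
  if (!any(both)) {
    return(list(pairs = data.frame(pred_id = integer(0), gt_id = integer(0),
                                   iou = numeric(0)),
                n_pred = np, n_gt = ng, psize = psize, gsize = gsize))
  }
  key <- paste(pred[both], gt[both])
  tab <- table(key)
  ids <- do.call(rbind, strsplit(names(tab), " "))
  pid <- as.integer(ids[, 1L]); gid <- as.integer(ids[, 2L])
  inter <- as.integer(tab)
  iou <- inter / (psize[pid] + gsize[gid] - inter)
  list(pairs = data.frame(pred_id = pid, gt_id = gid, iou = iou),
       n_pred = np, n_gt = ng, psize = psize, gsize = gsize)
}

#' Match predicted and ground-truth instances at an IoU threshold
#'
#' Candidate pairs are all (pred, gt) instance pairs with pairwise IoU at or
#' above the threshold; a one-to-one matching is then chosen greedily in
#' descending IoU (ties: lower gt id, then lower pred id). At thresholds
#' >= 0.5 each instance can exceed the threshold with at most one partner,
#' so the greedy matching is optimal there.
#'
#' @param pred,gt Integer instance label arrays (0 = background) on
#'   congruent grids.
#' @param iou_threshold Matching threshold in (0, 1); default 0.5, the
#'   conventional object-detection criterion.
#' @return `list(counts = list(tp, fp, fn, iou_threshold), pairs)` where
#'   `pairs` is a `data.frame(pred_id, gt_id, iou)` of the accepted matches.
#' @export
match_objects <- function(pred, gt, iou_threshold = 0.5) {
  if (!(iou_threshold > 0 && iou_threshold < 1)) stop_arg("iou_threshold must be in (0, 1)")
  ov <- overlap_iou_pairs(pred, gt)
  cand <- ov$pairs[ov$pairs$iou >= iou_threshold, , drop = FALSE]
  cand <- cand[order(-cand$iou, cand$gt_id, cand$pred_id), , drop = FALSE]
  used_p <- logical(length(ov$psize))
  used_g <- logical(length(ov$gsize))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    p <- cand$pred_id[i]; g <- cand$gt_id[i]
    if (!used_p[p] && !used_g[g]) {
      keep[i] <- TRUE
      used_p[p] <- TRUE
      used_g[g] <- TRUE
    }
  }
  pairs <- cand[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  tp <- nrow(pairs)
  list(counts = list(tp = tp, fp = ov$n_pred - tp, fn = ov$n_gt - tp,
                     iou_threshold = iou_threshold),
       pairs = pairs)
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `f1 = 2PR/(P+R)` (0 when P + R = 0). Undefined ratios (empty denominator)
#' are reported as missing, not as 0.
#'
#' @param counts List with `tp`, `fp`, `fn` (e.g. `match_objects()$counts`).
#' @return `data.frame(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(precision) || is.na(recall)) NA_real_
        else if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  data.frame(precision = precision, recall = recall, f1 = f1)
}

#' F1 across IoU thresholds
#'
#' Object-level F1 at each threshold (default 0.1--0.9 in steps of 0.1) via
#' [match_objects()]. The curve is monotone non-increasing in the threshold.
#'
#' @param pred,gt Integer instance label arrays.
#' @param thresholds IoU thresholds.
#' @return `data.frame(iou_threshold, tp, fp, fn, precision, recall, f1)`.
#' @export
f1_curve <- function(pred, gt, thresholds = seq(0.1, 0.9, by = 0.1)) {
  rows <- lapply(thresholds, function(t) {
    mc <- match_objects(pred, gt, t)
    cbind(data.frame(iou_threshold = t, tp = mc$counts$tp, fp = mc$counts$fp,
                     fn = mc$counts$fn),
          precision_recall_f1(mc$counts))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Surface Hausdorff distance between two voxel sets
#'
#' Symmetric Hausdorff distance under the anisotropic Euclidean metric over
#' the sets' 6-connectivity surface voxels: the farthest any boundary point
#' of one set lies from the other set's boundary, in micrometres. The robust
#' 95th-percentile variant (max of the two directed 95th percentiles) is
#' reported alongside.
#'
#' @param a,b Non-empty logical arrays on congruent grids.
#' @param spacing Voxel spacing `(z, y, x)` in micrometres.
#' @return `list(hd, hd95)` in micrometres.
#' @export
hausdorff <- function(a, b, spacing) {
  check_same_grid(a, b)
  spacing <- check_spacing(spacing)
  if (!any(a) || !any(b)) stop_arg("hausdorff requires two non-empty voxel sets")
  sa <- surface_mask(a)
  sb <- surface_mask(b)
  da <- edt_um(sb, spacing)$dist[which(sa)] # surface-a -> surface-b distances
  db <- edt_um(sa, spacing)$dist[which(sb)]
  list(hd = max(max(da), max(db)),
       hd95 = max(stats::quantile(da, 0.95, names = FALSE),
                  stats::quantile(db, 0.95, names = FALSE)))
}

#' Full validation report: predicted vs ground-truth segmentation
#'
#' Pixel-level Dice and IoU per semantic class, object-level matching of
#' spine instances at `iou_threshold` (TP/FP/FN, precision/recall/F1), the
#' F1 curve across `thresholds`, and the per-matched-spine Hausdorff
#' distances.
#'
#' @param pred,gt [semantic_labels()] maps on congruent grids.
#' @param pred_instances,gt_instances Optional instance label arrays; by
#'   default they are derived from the head + neck classes of each map via
#'   [extract_spine_instances()].
#' @param iou_threshold Object-match threshold (default 0.5).
#' @param thresholds Thresholds for the F1 curve.
#' @return An object of class `validation_report`: list with
#'   `dice_per_class`, `iou_per_class`, `counts`, `prf`, `f1_curve`,
#'   `hausdorff_um` (one row per matched spine).
#' @export
validate_segmentation <- function(pred, gt, pred_instances = NULL, gt_instances = NULL,
                                  iou_threshold = 0.5,
                                  thresholds = seq(0.1, 0.9, by = 0.1)) {
  stopifnot(inherits(pred, "semantic_labels"), inherits(gt, "semantic_labels"))
  check_same_grid(pred$labels, gt$labels)
  classes <- setdiff(names(pred$class_codes), "background")
  spine_mask <- function(m) class_mask(m, "spine_head") | class_mask(m, "spine_neck")
  dice_pc <- iou_pc <- stats::setNames(numeric(length(classes) + 1L), c(classes, "spine"))
  for (cl in classes) {
    dice_pc[cl] <- dice(class_mask(pred, cl), class_mask(gt, cl))
    iou_pc[cl] <- iou(class_mask(pred, cl), class_mask(gt, cl))
  }
  dice_pc["spine"] <- dice(spine_mask(pred), spine_mask(gt))
  iou_pc["spine"] <- iou(spine_mask(pred), spine_mask(gt))
  if (is.null(pred_instances)) pred_instances <- instance_map(
    extract_spine_instances(pred), dim(pred$labels))
  if (is.null(gt_instances)) gt_instances <- instance_map(
    extract_spine_instances(gt), dim(gt$labels))
  mc <- match_objects(pred_instances, gt_instances, iou_threshold)
  hrows <- lapply(seq_len(nrow(mc$pairs)), function(i) {
    h <- hausdorff(pred_instances == mc$pairs$pred_id[i],
                   gt_instances == mc$pairs$gt_id[i], pred$spacing)
    data.frame(pred_id = mc$pairs$pred_id[i], gt_id = mc$pairs$gt_id[i],
               iou = mc$pairs$iou[i], hausdorff_um = h$hd, hd95_um = h$hd95)
  })
  structure(list(dice_per_class = dice_pc, iou_per_class = iou_pc,
                 counts = mc$counts, prf = precision_recall_f1(mc$counts),
                 f1_curve = f1_curve(pred_instances, gt_instances, thresholds),
                 hausdorff_um = if (length(hrows)) do.call(rbind, hrows)
                                else data.frame(pred_id = integer(0), gt_id = integer(0),
                                                iou = numeric(0), hausdorff_um = numeric(0),
                                                hd95_um = numeric(0))),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n  Dice per class:\n")
  for (nm in names(x$dice_per_class)) {
    cat(sprintf("    %-11s dice %.3f  iou %.3f\n", nm, x$dice_per_class[nm],
                x$iou_per_class[nm]))
  }
  cat(sprintf("  objects @ IoU %.2f: TP %d, FP %d, FN %d\n",
              x$counts$iou_threshold, x$counts$tp, x$counts$fp, x$counts$fn))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n",
              x$prf$precision, x$prf$recall, x$prf$f1))
  if (nrow(x$hausdorff_um) > 0L) {
    cat(sprintf("  Hausdorff (matched spines): median %.3f um, max %.3f um\n",
                stats::median(x$hausdorff_um$hausdorff_um),
                max(x$hausdorff_um$hausdorff_um)))
  }
  invisible(x)
}

#' Write a validation report to CSV files
#'
#' @param report A `validation_report`.
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Paths of the written files, invisibly.
#' @export
write_validation_report <- function(report, dir, stem = "validation") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, paste0(stem, "_pixel.csv"))
  utils::write.csv(data.frame(class = names(report$dice_per_class),
                              dice = as.numeric(report$dice_per_class),
                              iou = as.numeric(report$iou_per_class)),
                   p1, row.names = FALSE)
  p2 <- file.path(dir, paste0(stem, "_objects.csv"))
  utils::write.csv(cbind(data.frame(tp = report$counts$tp, fp = report$counts$fp,
                                    fn = report$counts$fn,
                                    iou_threshold = report$counts$iou_threshold),
                         report$prf), p2, row.names = FALSE)
  p3 <- file.path(dir, paste0(stem, "_f1_curve.csv"))
  utils::write.csv(report$f1_curve, p3, row.names = FALSE)
  p4 <- file.path(dir, paste0(stem, "_hausdorff.csv"))
  utils::write.csv(report$hausdorff_um, p4, row.names = FALSE)
  invisible(c(p1, p2, p3, p4))
}
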