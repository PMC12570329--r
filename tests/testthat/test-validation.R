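# Pixel metrics, object matching, F1 curves, Hausdorff.

test_that("dice and iou follow the set formulas with the empty conventions", {
  a <- array(FALSE, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- TRUE
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  b <- array(FALSE, c(4, 4, 4)); b[1, 1, 1] <- TRUE
  expect_equal(dice(a, b), 0)
  expect_equal(iou(a, b), 0)
  e <- array(FALSE, c(4, 4, 4))
  expect_equal(dice(e, e), 1) # vacuous agreement convention
  expect_equal(iou(e, e), 1)
  expect_equal(dice(a, e), 0)
  # 2x2x2 cube vs the same cube shifted 1 voxel in x: overlap 4 of 8
  s <- array(FALSE, c(4, 4, 4)); s[2:3, 2:3, 3:4] <- TRUE
  expect_equal(dice(a, s), 0.5)
  expect_equal(iou(a, s), 1 / 3)
  expect_error(dice(a, array(FALSE, c(3, 4, 4))), "congruent")
})

test_that("dice = 2 iou / (1 + iou) identity holds on random masks", {
  for (seed in 1:20) {
    set.seed(seed)
    a <- array(runif(6^3) < 0.4, c(6, 6, 6))
    b <- array(runif(6^3) < 0.4, c(6, 6, 6))
    expect_equal(dice(a, b), 2 * iou(a, b) / (1 + iou(a, b)), tolerance = 1e-12)
  }
})

test_that("object matching counts TP/FP/FN with greedy descending-IoU pairing", {
  inst <- random_instance_scene(c(10, 12, 12), 4, r = 1, seed = 3)
  mc <- match_objects(inst, inst, 0.5)
  expect_equal(mc$counts[c("tp", "fp", "fn")], list(tp = 4L, fp = 0L, fn = 0L))
  # one gt instance, pred overlapping 40%: below a 0.5 threshold
  gt <- array(0L, c(4, 4, 10)); gt[2, 2, 1:5] <- 1L
  pr <- array(0L, c(4, 4, 10)); pr[2, 2, 4:9] <- 1L # overlap 2, union 9
  mc2 <- match_objects(pr, gt, 0.5)
  expect_equal(unlist(mc2$counts[c("tp", "fp", "fn")]), c(tp = 0L, fp = 1L, fn = 1L))
  expect_equal(unlist(match_objects(pr, gt, 0.2)$counts[c("tp", "fp", "fn")]),
               c(tp = 1L, fp = 0L, fn = 0L))
  # counts are consistent with instance totals
  expect_equal(mc2$counts$tp + mc2$counts$fp, 1L)
  expect_equal(mc2$counts$tp + mc2$counts$fn, 1L)
})

test_that("greedy matching equals the exhaustive optimal assignment oracle", {
  n_checked <- 0L
  for (seed in 1:12) {
    pred <- random_instance_scene(c(8, 10, 10), sample(2:5, 1), r = 1, seed = seed)
    gt <- random_instance_scene(c(8, 10, 10), sample(2:5, 1), r = 1, seed = seed + 100)
    ov <- spinemorph:::overlap_iou_pairs(pred, gt)
    np <- length(ov$psize); ng <- length(ov$gsize)
    iou_mat <- matrix(0, np, ng)
    if (nrow(ov$pairs) > 0) iou_mat[cbind(ov$pairs$pred_id, ov$pairs$gt_id)] <- ov$pairs$iou
    for (thr in c(0.3, 0.5)) {
      # at >= 0.5 greedy is optimal outright; below, compare only when the
      # IoU matrix has unique row/column maxima above threshold
      above <- iou_mat >= thr
      unique_max <- all(rowSums(above) <= 1) && all(colSums(above) <= 1)
      if (thr >= 0.5 || unique_max) {
        mc <- match_objects(pred, gt, thr)
        expect_equal(mc$counts$tp, bf_optimal_matches(iou_mat, thr))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gte(n_checked, 12L)
})

test_that("precision/recall/F1 reproduce the worked arithmetic", {
  expect_equal(precision_recall_f1(list(tp = 3, fp = 1, fn = 1)),
               data.frame(precision = 0.75, recall = 0.75, f1 = 0.75))
  und <- precision_recall_f1(list(tp = 0, fp = 0, fn = 0))
  expect_true(all(is.na(und)))
  onlyfp <- precision_recall_f1(list(tp = 0, fp = 2, fn = 0))
  expect_equal(onlyfp$precision, 0)
  expect_true(is.na(onlyfp$recall))
})

test_that("F1 curves are non-increasing and step where the IoU sits", {
  inst <- random_instance_scene(c(8, 12, 12), 5, r = 1, seed = 2)
  fc <- f1_curve(inst, inst)
  expect_equal(fc$f1, rep(1, 9))
  # single pair with IoU between 0.5 and 0.6: f1 = 1 up to 0.5, 0 above
  gt <- array(0L, c(4, 4, 20)); gt[2, 2, 1:10] <- 1L
  pr <- array(0L, c(4, 4, 20)); pr[2, 2, 3:12] <- 1L # overlap 8, union 12: IoU 2/3
  pr2 <- array(0L, c(4, 4, 20)); pr2[2, 2, 4:13] <- 1L # overlap 7/13 = 0.538
  fc2 <- f1_curve(pr2, gt)
  expect_equal(fc2$f1, c(rep(1, 5), rep(0, 4)))
  # monotone on random scenes
  for (seed in 1:8) {
    pred <- random_instance_scene(c(8, 10, 10), 4, r = 1, seed = seed)
    gtt <- random_instance_scene(c(8, 10, 10), 4, r = 1, seed = seed + 50)
    f <- f1_curve(pred, gtt)$f1
    f[is.na(f)] <- 0
    expect_true(all(diff(f) <= 1e-12))
  }
})

test_that("Hausdorff matches hand arithmetic and the brute-force oracle", {
  a <- array(FALSE, c(4, 4, 8)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(4, 4, 8)); b[2, 2, 5] <- TRUE # 3 lateral steps at 65 nm
  h <- hausdorff(a, b, SPIN_SP)
  expect_equal(h$hd, 0.195)
  expect_equal(hausdorff(a, a, SPIN_SP)$hd, 0)
  expect_error(hausdorff(a, array(FALSE, c(4, 4, 8)), SPIN_SP), "non-empty")
  for (seed in 1:10) {
    set.seed(seed)
    d <- c(10, 12, 14)
    aa <- array(FALSE, d); aa[sample(prod(d), 40)] <- TRUE
    bb <- array(FALSE, d); bb[sample(prod(d), 40)] <- TRUE
    expect_equal(hausdorff(aa, bb, SPIN_SP)$hd, bf_hausdorff(aa, bb, SPIN_SP),
                 tolerance = 1e-9)
  }
})

test_that("Hausdorff is symmetric and satisfies the triangle inequality", {
  set.seed(11)
  d <- c(8, 10, 10)
  masks <- lapply(1:3, function(i) {
    m <- array(FALSE, d); m[sample(prod(d), 30)] <- TRUE; m
  })
  hab <- hausdorff(masks[[1]], masks[[2]], SPIN_SP)$hd
  hba <- hausdorff(masks[[2]], masks[[1]], SPIN_SP)$hd
  hbc <- hausdorff(masks[[2]], masks[[3]], SPIN_SP)$hd
  hac <- hausdorff(masks[[1]], masks[[3]], SPIN_SP)$hd
  expect_equal(hab, hba)
  expect_lte(hac, hab + hbc + 1e-9)
})

test_that("the full validation report is coherent on a perturbed phantom", {
  sc <- straight_scene(6, shape = c(24, 64, 128), seed = 8)
  pred_arr <- spinemorph:::shift_array(sc$labels$labels, c(0, 1, 0), "nearest", fill = 0L)
  pred <- semantic_labels(pred_arr, sc$labels$spacing)
  rep <- validate_segmentation(pred, sc$labels)
  expect_s3_class(rep, "validation_report")
  expect_true(all(rep$dice_per_class >= 0 & rep$dice_per_class <= 1))
  expect_equal(rep$dice_per_class, 2 * rep$iou_per_class / (1 + rep$iou_per_class),
               tolerance = 1e-12)
  expect_equal(rep$prf$f1,
               2 * rep$prf$precision * rep$prf$recall /
                 (rep$prf$precision + rep$prf$recall))
  expect_equal(nrow(rep$hausdorff_um), rep$counts$tp)
  # precision bounded by the fraction of pred instances with any partner
  ov <- spinemorph:::overlap_iou_pairs(instance_map(extract_spine_instances(pred),
                                                    dim(pred$labels)),
                                       instance_map(extract_spine_instances(sc$labels),
                                                    dim(sc$labels$labels)))
  frac <- length(unique(ov$pairs$pred_id[ov$pairs$iou >= 0.5])) / length(ov$psize)
  expect_lte(rep$prf$precision, frac + 1e-12)
  out <- withr::local_tempdir()
  paths <- write_validation_report(rep, out)
  expect_true(all(file.exists(paths)))
})
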