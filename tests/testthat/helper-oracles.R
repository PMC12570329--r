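# Brute-force oracles and tiny fixture builders. Oracles are deliberately
# implemented with plain R loops (or igraph where noted), fully independent
# of the package's C++ kernels.

SPIN_SP <- c(0.150, 0.065, 0.065) # spinning-disk voxel spacing (z, y, x), um

mk_labels <- function(arr, spacing = SPIN_SP) semantic_labels(arr, spacing)

# all 26 (z, y, x) offsets filtered to a connectivity level
offsets26 <- function(connectivity = 26L) {
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  s <- rowSums(abs(off))
  keep <- s > 0 & s <= switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  off[keep, , drop = FALSE]
}

# brute-force connected components by repeated neighbourhood dilation
bf_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  off <- offsets26(connectivity)
  lab <- array(0L, d)
  nxt <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    frontier <- start
    lab[start] <- nxt
    while (length(frontier) > 0L) {
      zyx <- arrayInd(frontier, d)
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(r) {
        sweep(zyx, 2L, off[r, ], `+`)
      }))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      lin <- unique(lin[mask[lin] & lab[lin] == 0L])
      lab[lin] <- nxt
      frontier <- lin
    }
  }
  lab
}

# all-pairs minimum anisotropic distance between two voxel index sets
bf_min_dist <- function(lin_a, lin_b, dims, spacing) {
  a <- (arrayInd(lin_a, dims) - 1) %*% diag(spacing)
  b <- (arrayInd(lin_b, dims) - 1) %*% diag(spacing)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    best <- min(best, sqrt(min(colSums((t(b) - a[i, ])^2))))
  }
  best
}

# brute-force symmetric Hausdorff distance over 6-connectivity surfaces
bf_hausdorff <- function(a, b, spacing) {
  surf <- function(m) {
    d <- dim(m)
    keep <- logical(0)
    idx <- which(m)
    zyx <- arrayInd(idx, d)
    for (i in seq_along(idx)) {
      p <- zyx[i, ]
      border <- FALSE
      for (ax in 1:3) for (s in c(-1, 1)) {
        q <- p
        q[ax] <- q[ax] + s
        if (q[ax] < 1 || q[ax] > d[ax] || !m[q[1], q[2], q[3]]) border <- TRUE
      }
      keep[i] <- border
    }
    zyx[keep, , drop = FALSE]
  }
  sa <- surf(a) %*% diag(spacing)
  sb <- surf(b) %*% diag(spacing)
  dmat <- outer(seq_len(nrow(sa)), seq_len(nrow(sb)), Vectorize(function(i, j) {
    sqrt(sum((sa[i, ] - sb[j, ])^2))
  }))
  max(max(apply(dmat, 1L, min)), max(apply(dmat, 2L, min)))
}

# exhaustive optimal one-to-one assignment: maximum number of (pred, gt)
# pairs with IoU >= thr, over all injective mappings (<= 6 x 6)
bf_optimal_matches <- function(iou_mat, thr) {
  np <- nrow(iou_mat); ng <- ncol(iou_mat)
  if (np == 0L || ng == 0L) return(0L)
  best <- 0L
  gt_sets <- utils::combn(ng, min(np, ng), simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  pr_sets <- utils::combn(np, min(np, ng), simplify = FALSE)
  for (ps in pr_sets) for (gs in gt_sets) for (gp in perms(gs)) {
    best <- max(best, sum(iou_mat[cbind(ps, gp)] >= thr))
  }
  best
}

# random multi-instance label scene on a small grid: k blobs of given radius
random_instance_scene <- function(dims, k, r = 1L, seed = 1L) {
  set.seed(seed)
  lab <- array(0L, dims)
  for (i in seq_len(k)) {
    c0 <- sapply(dims, function(n) sample(seq_len(n), 1L))
    zz <- pmax(c0[1] - r, 1):pmin(c0[1] + r, dims[1])
    yy <- pmax(c0[2] - r, 1):pmin(c0[2] + r, dims[2])
    xx <- pmax(c0[3] - r, 1):pmin(c0[3] + r, dims[3])
    lab[zz, yy, xx] <- i
  }
  lab
}

# small straight-dendrite label map with hand-placed spines, for unit tests
straight_scene <- function(n_spines = 5L, shape = c(32L, 96L, 160L), seed = 1L,
                           soma = TRUE) {
  generate_scene(random_scene_spec(n_spines = n_spines, shape = shape,
                                   seed = seed, soma = soma))
}
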