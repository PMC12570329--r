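# Skeletonization, soma distances, spine geometry, intensities, summaries.

test_that("skeleton length recovers straight and L-shaped tube geometry", {
  # straight cylinder, radius 0.3 um, 10 um long, caps inside the grid
  path <- rbind(c(3.5, 4.13, 1.5), c(3.5, 4.13, 11.5))
  sc <- generate_scene(scene_spec(shape = c(48, 128, 220), path = path,
                                  dendrite_radius_um = 0.3))
  len <- dendrite_length(skeletonize_dendrite(sc$labels))
  expect_lt(abs(len - 10) / 10, 0.05)
  # L-shaped tube: 5 um + 5 um arms (corner discretization tolerance 7%)
  pathL <- rbind(c(3.5, 6.6, 0.5), c(3.5, 6.6, 5.5), c(3.5, 1.6, 5.5))
  scL <- generate_scene(scene_spec(shape = c(48, 128, 160), path = pathL))
  lenL <- dendrite_length(skeletonize_dendrite(scL$labels))
  expect_lt(abs(lenL - 10) / 10, 0.07)
})

test_that("degenerate skeleton inputs behave as documented", {
  lab <- array(0L, c(5, 5, 5))
  lab[3, 3, 3] <- 1L
  tree <- skeletonize_dendrite(mk_labels(lab))
  expect_equal(nrow(tree), 1L)
  expect_equal(dendrite_length(tree), 0)
  expect_error(skeletonize_dendrite(mk_labels(array(0L, c(4, 4, 4)))), "empty")
  # dendrite_length is translation invariant (relative coordinates only)
  t2 <- tree
  t2$x <- t2$x + 5; t2$y <- t2$y + 1
  expect_equal(dendrite_length(t2), dendrite_length(tree))
})

test_that("soma distances: geodesic tracks the foreground, Euclid the straight line", {
  # straight dendrite with soma at one end: geodesic ~ euclid (within 10%)
  sc <- straight_scene(6, shape = c(32, 96, 192), seed = 4)
  inst <- attach_to_dendrite(extract_spine_instances(sc$labels), sc$labels)
  sd <- soma_distances(inst, sc$labels)
  rec <- measure_spines(inst, sc$labels)
  expect_true(all(is.finite(sd$soma_distance_euclid_um)))
  expect_true(all(is.finite(sd$soma_distance_geodesic_um)))
  diag_vox <- sqrt(sum(sc$labels$spacing^2))
  # geometric bounds on a straight shaft: the geodesic can exceed the chord
  # only by the within-spine leg + shaft radius + chamfer discretization
  expect_true(all(sd$soma_distance_geodesic_um >=
                    sd$soma_distance_euclid_um - diag_vox))
  expect_true(all(sd$soma_distance_geodesic_um <=
                    sd$soma_distance_euclid_um + rec$spine_length_um + 0.4 +
                    0.05 * sd$soma_distance_euclid_um + 2 * diag_vox))

  # straight-phantom limit: for a small spine far from the soma the two
  # distances agree within discretization (<= 10%)
  spec_small <- sc$spec
  spec_small$spines <- data.frame(position_um = attr(sc$gt, "path_length_um") - 1.5,
                                  angle = pi / 2, neck_length_um = 0.1,
                                  neck_radius_um = 0.1, head_radius_um = 0.15)
  scs <- generate_scene(spec_small)
  insts <- attach_to_dendrite(extract_spine_instances(scs$labels), scs$labels)
  sds <- soma_distances(insts, scs$labels)
  expect_lt(abs(sds$soma_distance_geodesic_um - sds$soma_distance_euclid_um) /
              sds$soma_distance_euclid_um, 0.10)

  # a spine attached directly on the soma surface has geodesic ~ 0-ish
  spec <- sc$spec
  spec$spines <- spec$spines[1, ]
  spec$spines$position_um <- attr(sc$gt, "path_length_um") * 0 + spec$soma_radius_um
  sc2 <- generate_scene(spec)
  inst2 <- attach_to_dendrite(extract_spine_instances(sc2$labels), sc2$labels)
  sd2 <- soma_distances(inst2, sc2$labels)
  # the reading point is the spine body, so the distance is bounded by its length
  expect_lt(sd2$soma_distance_geodesic_um, sc2$gt$spine_length_um[1] + 0.5)

  # no soma: both missing, with a notice
  scn <- straight_scene(3, shape = c(24, 64, 96), seed = 1, soma = FALSE)
  instn <- attach_to_dendrite(extract_spine_instances(scn$labels), scn$labels)
  expect_message(sdn <- soma_distances(instn, scn$labels), "missing")
  expect_true(all(is.na(sdn$soma_distance_euclid_um)))
  expect_true(all(is.na(sdn$soma_distance_geodesic_um)))
})

test_that("on a U-shaped dendrite the geodesic exceeds the Euclidean distance", {
  # U: soma at one tip, spine at the other; straight-line distance is short
  # but the path runs around the U
  sp <- SPIN_SP
  path <- rbind(c(2.4, 1.0, 1.0), c(2.4, 1.0, 7.0), c(2.4, 3.4, 7.0),
                c(2.4, 3.4, 1.0))
  spines <- data.frame(position_um = 13.5, angle = pi, neck_length_um = 0.5,
                       neck_radius_um = 0.1, head_radius_um = 0.3)
  spec <- scene_spec(shape = c(32, 80, 140), path = path,
                     soma_center = c(2.4, 1.0, 1.0), soma_radius_um = 0.8,
                     spines = spines)
  sc <- generate_scene(spec)
  inst <- attach_to_dendrite(extract_spine_instances(sc$labels), sc$labels)
  sd <- soma_distances(inst, sc$labels)
  expect_gt(sd$soma_distance_geodesic_um, sd$soma_distance_euclid_um + 1)

  # independent oracle: igraph shortest path over the voxel adjacency graph
  skip_if_not_installed("igraph")
  m <- sc$labels
  d <- dim(m$labels)
  fg <- which(m$labels != 0L)
  sub <- seq_along(fg)
  zyx <- arrayInd(fg, d)
  edges <- NULL
  w <- NULL
  off <- offsets26(26L)
  lut <- integer(prod(d)); lut[fg] <- sub
  for (r in seq_len(nrow(off))) {
    nb <- sweep(zyx, 2L, off[r, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + d[1] * (nb[ok, 2] - 1L) + d[1] * d[2] * (nb[ok, 3] - 1L)
    hit <- lut[lin] > 0L
    edges <- rbind(edges, cbind(sub[ok][hit], lut[lin][hit]))
    w <- c(w, rep(sqrt(sum((off[r, ] * m$spacing)^2)), sum(hit)))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  soma_v <- which(m$labels[fg] == 2L)
  geo <- spinemorph:::geodesic_um(m$labels != 0L, m$labels == 2L, m$spacing)
  probe <- sample(which(is.finite(geo[fg]) & m$labels[fg] == 1L), 5)
  dmat <- igraph::distances(g, v = probe, to = soma_v)
  expect_equal(geo[fg][probe], apply(dmat, 1L, min), tolerance = 1e-9)
})

test_that("spine geometry recovers planted head width, neck and spine length", {
  sp <- SPIN_SP
  # spherical head r = 0.4 on zero-length neck
  spec <- scene_spec(shape = c(32, 64, 96),
                     path = rbind(c(2.4, 2.08, 0), c(2.4, 2.08, 6.17)),
                     spines = data.frame(position_um = 3, angle = pi / 2,
                                         neck_length_um = 0, neck_radius_um = 0.1,
                                         head_radius_um = 0.4))
  sc <- generate_scene(spec)
  inst <- attach_to_dendrite(extract_spine_instances(sc$labels), sc$labels)
  geom <- spine_geometry(inst[[1]])
  expect_lt(abs(geom$head_width_um - 0.8) / 0.8, 0.15)

  # straight 1.0 um neck + head: neck length within 15%, spine length longer
  spec$spines$neck_length_um <- 1.0
  sc2 <- generate_scene(spec)
  inst2 <- attach_to_dendrite(extract_spine_instances(sc2$labels), sc2$labels)
  g2 <- spine_geometry(inst2[[1]])
  expect_lt(abs(g2$neck_length_um - 1.0), 0.15)
  expect_gt(g2$spine_length_um, g2$neck_length_um)
  expect_lt(abs(g2$spine_length_um - sc2$gt$spine_length_um[1]) /
            sc2$gt$spine_length_um[1], 0.15)

  # single-voxel spine adjacent to the dendrite: length is one lateral step
  lab <- array(0L, c(8, 8, 8))
  lab[4, 4, 4] <- 1L
  lab[4, 4, 5] <- 3L
  m <- mk_labels(lab)
  s <- attach_to_dendrite(extract_spine_instances(m)[[1]], m)
  gs <- spine_geometry(s)
  expect_equal(gs$spine_length_um, 0.065)
  # headless instance: head-specific metrics missing
  lab[4, 4, 5] <- 4L
  m2 <- mk_labels(lab)
  s2 <- attach_to_dendrite(extract_spine_instances(m2)[[1]], m2)
  g3 <- spine_geometry(s2)
  expect_true(is.na(g3$head_width_um))
  expect_true(is.na(g3$neck_length_um))
})

test_that("intensity statistics are exact and relabelling invariant", {
  lab <- array(0L, c(6, 6, 6))
  lab[2:3, 2:3, 2:3] <- 3L
  m <- mk_labels(lab)
  v <- volume_image(array(7, c(6, 6, 6)), m$spacing)
  s <- extract_spine_instances(m)[[1]]
  st <- intensity_stats(s, v)
  expect_equal(st$intensity_mean_ch1, 7)
  expect_equal(st$intensity_max_ch1, 7)
  # integrated: 8 voxels x 2 x voxel volume (65 x 65 x 150 nm)
  v2 <- volume_image(array(2, c(6, 6, 6)), m$spacing)
  expect_equal(intensity_stats(s, v2)$intensity_integrated_ch1,
               8 * 2 * 6.3375e-4, tolerance = 1e-12)
  s_relab <- s
  s_relab$instance_id <- 99L
  expect_equal(intensity_stats(s_relab, v), st)
  # grid mismatch is an argument error
  bad <- volume_image(array(1, c(5, 6, 6)), m$spacing)
  expect_error(intensity_stats(s, bad), "grid")
})

test_that("summaries compute density and averages with missing handling", {
  rec10 <- data.frame(volume_um3 = rep(0.2, 10), spine_length_um = 1,
                      head_width_um = c(NA, rep(0.5, 9)))
  tree <- skeleton_tree(data.frame(id = 1:2, type = 3L, z = 0, y = 0,
                                   x = c(0, 20), radius = 0.3, parent = c(-1L, 1L)))
  s <- summarize_spines(rec10, tree)
  expect_equal(s$spine_density_per_um[1], 0.5)
  expect_equal(s$mean_head_width_um[1], 0.5)
  empty <- summarize_spines(data.frame(), NULL)
  expect_equal(empty$spine_count[1], 0L)
  expect_true(is.na(empty$mean_volume_um3[1]))
  expect_true(is.na(empty$spine_density_per_um[1]))
})

test_that("measurements are equivariant under axis permutation with matched spacing", {
  lab <- array(0L, c(10, 12, 14))
  lab[4:6, 5:7, 3:9] <- 1L
  lab[7, 6, 5] <- 3L
  m <- mk_labels(lab)
  inst <- attach_to_dendrite(extract_spine_instances(m), m)
  # permute (z, y, x) -> (x, z, y) with matching spacing permutation
  perm <- aperm(lab, c(3, 1, 2))
  mp <- semantic_labels(perm, m$spacing[c(3, 1, 2)])
  instp <- attach_to_dendrite(extract_spine_instances(mp), mp)
  expect_equal(instp[[1]]$distance_to_dendrite_um, inst[[1]]$distance_to_dendrite_um)
  expect_equal(spine_geometry(instp[[1]])$spine_length_um,
               spine_geometry(inst[[1]])$spine_length_um)
})
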