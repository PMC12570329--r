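# Volume/label I/O, rescaling, SWC and table export.

test_that("TIFF round trips are lossless and axes are bookkept correctly", {
  # 3-page 4x4 stack -> (1, 3, 4, 4)
  v <- volume_image(array(sample(0:255, 48, TRUE), c(3, 4, 4)),
                    c(0.15, 0.065, 0.065))
  expect_equal(dim(v$voxels), c(1L, 3L, 4L, 4L))
  p <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, p)
  v2 <- read_volume(p, v$spacing)
  expect_identical(dim(v2$voxels), dim(v$voxels))
  expect_true(all(v2$voxels == v$voxels))
  expect_equal(v2$spacing, v$spacing)

  # uint16 and float32 payloads
  vu <- volume_image(array(sample(0:65535, 60, TRUE), c(3, 4, 5)), c(1, 1, 1))
  write_volume(vu, p)
  expect_true(all(read_volume(p, c(1, 1, 1))$voxels == vu$voxels))
  vf <- volume_image(array(rnorm(60), c(3, 4, 5)), c(1, 1, 1))
  write_volume(vf, p)
  expect_lt(max(abs(read_volume(p, c(1, 1, 1))$voxels - vf$voxels)), 1e-6)
})

test_that("multi-channel page demultiplexing matches manual page indexing", {
  # 2 channels x 3 z-planes = 6 pages, z fastest within channel
  arr <- array(seq_len(2 * 3 * 4 * 5), c(2, 3, 4, 5))
  v <- volume_image(arr, c(0.3, 0.1, 0.1))
  p <- withr::local_tempfile(fileext = ".tif")
  write_volume(v, p)
  v2 <- read_volume(p, v$spacing, channels = 2L)
  expect_equal(v2$voxels, v$voxels)
  # manual check: page index = (channel - 1) * nz + z
  pages <- spinemorph:::read_tiff_pages(p)
  expect_length(pages, 6L)
  for (ch in 1:2) for (z in 1:3) {
    expect_equal(pages[[(ch - 1) * 3 + z]], array(arr[ch, z, , ], c(4, 5)))
  }
  expect_error(read_volume(p, v$spacing, channels = 4L), "multiple")
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(volume_image(array(1, c(2, 2, 2)), c(0, 1, 1)), "positive")
  expect_error(read_volume(tempfile(), c(1, 1, 1)), "not found")
  expect_error(semantic_labels(array(7L, c(2, 2, 2)), c(1, 1, 1)), "undeclared")
  # 2-D inputs become z-depth 1
  expect_equal(dim(volume_image(matrix(1, 4, 5), c(1, 1, 1))$voxels), c(1L, 1L, 4L, 5L))
})

test_that("rescaling follows the round(dim x spacing / target) contract", {
  plane <- volume_image(array(runif(100 * 100), c(1, 100, 100)),
                        c(0.15, 0.065, 0.065))
  same <- rescale_volume(plane, plane$spacing)
  expect_identical(same$voxels, plane$voxels)
  down <- rescale_volume(plane, c(0.15, 0.130, 0.130))
  expect_equal(dim(down$voxels), c(1L, 1L, 50L, 50L))
  expect_equal(down$spacing, c(0.15, 0.130, 0.130))
})

test_that("nearest-neighbour label rescaling never invents class codes", {
  for (seed in 1:5) {
    set.seed(seed)
    lab <- array(sample(c(0L, 1L, 3L, 4L), 24 * 20 * 16, TRUE,
                        prob = c(0.7, 0.1, 0.1, 0.1)), c(24, 20, 16))
    m <- mk_labels(lab)
    for (target in list(c(0.3, 0.13, 0.13), c(0.1, 0.05, 0.05), c(0.15, 0.1, 0.07))) {
      r <- rescale_labels(m, target)
      expect_true(all(unique(as.vector(r$labels)) %in% unique(as.vector(lab))))
    }
    # integer-factor down-then-up returns the original shape
    down <- rescale_labels(m, m$spacing * 2)
    up <- rescale_labels(down, m$spacing)
    expect_identical(dim(up$labels), dim(lab))
  }
})

test_that("SWC export writes parents before children and round trips", {
  tree <- skeleton_tree(data.frame(
    id = c(10L, 20L, 30L), type = c(1L, 3L, 3L),
    z = c(0, 0, 0), y = c(0, 0.5, 1.0), x = c(0, 0.25, 0.5),
    radius = c(1, 0.3, 0.3), parent = c(-1L, 10L, 20L)))
  p <- withr::local_tempfile(fileext = ".swc")
  write_swc(tree, p)
  lines <- grep("^#", readLines(p), invert = TRUE, value = TRUE)
  expect_length(lines, 3L)
  parsed <- do.call(rbind, lapply(strsplit(lines, " "), as.numeric))
  expect_equal(parsed[, 1], 1:3)          # contiguous ids from 1
  expect_equal(parsed[, 7], c(-1, 1, 2))  # chain parents
  back <- read_swc(p)
  expect_equal(back$y, tree$y, tolerance = 1e-4)
  expect_equal(back$x, tree$x, tolerance = 1e-4)
  # cycles are refused
  expect_error(skeleton_tree(data.frame(id = 1:2, type = 3L, z = 0, y = 0,
                                        x = c(0, 1), radius = 1,
                                        parent = c(2L, 1L))), "cycle")
})

test_that("SWC of a straight 10 um phantom dendrite has the right path length", {
  path <- rbind(c(3.5, 4.13, 1.5), c(3.5, 4.13, 11.5))
  sc <- generate_scene(scene_spec(shape = c(48, 128, 220), path = path,
                                  dendrite_radius_um = 0.3))
  tree <- skeletonize_dendrite(sc$labels)
  p <- withr::local_tempfile(fileext = ".swc")
  write_swc(tree, p)
  back <- read_swc(p)
  pmap <- match(back$parent, back$id)
  has <- !is.na(pmap)
  len <- sum(sqrt((back$z[has] - back$z[pmap[has]])^2 +
                  (back$y[has] - back$y[pmap[has]])^2 +
                  (back$x[has] - back$x[pmap[has]])^2))
  expect_lt(abs(len - 10) / 10, 0.05)
})

test_that("spine tables have the fixed schema and empty-field missing values", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_spine_table(NULL, p)
  hdr <- read.csv(p)
  expect_equal(nrow(hdr), 0L)
  expect_true(all(c("instance_id", "volume_um3", "centroid_z_um", "spine_length_um",
                    "neck_length_um", "head_width_um", "distance_to_dendrite_um",
                    "soma_distance_euclid_um", "soma_distance_geodesic_um",
                    "intensity_mean_ch1", "intensity_max_ch1",
                    "intensity_integrated_ch1") %in% names(hdr)))
  sc <- straight_scene(5, shape = c(24, 64, 128), seed = 2)
  inst <- attach_to_dendrite(extract_spine_instances(sc$labels), sc$labels)
  rec <- measure_spines(inst, sc$labels, sc$image)
  write_spine_table(rec, p)
  expect_equal(nrow(read.csv(p)), 5L)
  # a missing measurement must be an empty field, never 0
  rec$head_width_um[1] <- NA_real_
  write_spine_table(rec, p)
  raw <- readLines(p)[2L]
  expect_match(raw, ",,")
})

test_that("config files parse from JSON and the YAML subset", {
  skip_if_not_installed("jsonlite")
  pj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"spacing": [0.15, 0.065, 0.065], "channels": 2,
               "filter": {"min_volume_um3": 0.05, "max_volume_um3": 1.5,
                          "max_distance_to_dendrite_um": 0.5},
               "iou_threshold": 0.4}', pj)
  cfg <- read_config(pj)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$channels, 2L)
  expect_equal(cfg$filter$min_volume_um3, 0.05)
  py <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("spacing: [0.15, 0.065, 0.065]", "channels: 2",
               "filter:", "  min_volume_um3: 0.05", "  max_volume_um3: 1.5",
               "  max_distance_to_dendrite_um: 0.5",
               "iou_threshold: 0.4", "save_overlays: false"), py)
  cfg2 <- read_config(py)
  expect_equal(cfg2$filter$max_volume_um3, 1.5)
  expect_false(cfg2$save_overlays)
  expect_equal(cfg$spacing, cfg2$spacing)
  expect_error(read_config(withr::local_tempfile(fileext = ".txt")), "json")
})
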