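# Phantom generation, degradation physics and augmentation contracts.

test_that("scene generation yields exact ground truth and is deterministic", {
  spec <- random_scene_spec(n_spines = 5, shape = c(24, 64, 128), seed = 11)
  sc <- generate_scene(spec)
  expect_equal(nrow(sc$gt), 5L)
  expect_equal(sort(unique(as.vector(sc$instances))), 0:5)
  # analytic head volume vs voxelized head volume (r = 3+ lateral voxels)
  for (k in seq_len(5)) {
    vox_vol <- sum(sc$instances == k & sc$labels$labels == 3L) * prod(sc$labels$spacing)
    expect_lt(abs(vox_vol - sc$gt$head_volume_um3[k]) / sc$gt$head_volume_um3[k], 0.15)
  }
  # 4/3 pi 0.4^3 = 0.268 um3 for a 0.4 um head
  expect_equal(4 / 3 * pi * 0.4^3, 0.2681, tolerance = 1e-3)
  sc2 <- generate_scene(spec)
  expect_identical(sc$image$voxels, sc2$image$voxels)
  expect_identical(sc$labels$labels, sc2$labels$labels)
  expect_identical(sc$instances, sc2$instances)
  # painting precedence: head and neck codes survive where spines overlap shaft
  expect_true(all(sc$labels$labels[sc$instances > 0L] %in% c(3L, 4L)))
  # off-path spine placement is a spec error
  bad <- spec
  expect_error(scene_spec(shape = spec$shape, path = spec$path,
                          spines = data.frame(position_um = 99, angle = 0,
                                              neck_length_um = 0.5,
                                              neck_radius_um = 0.1,
                                              head_radius_um = 0.3)),
               "on the dendrite path")
})

test_that("the two-photon preset renders valid scenes at ~10x z anisotropy", {
  spec <- random_scene_spec(n_spines = 6, shape = c(12, 96, 160),
                            preset = "two-photon", seed = 3)
  expect_equal(spec$spacing, c(1.0, 0.102, 0.102))
  sc <- generate_scene(spec)
  expect_equal(max(sc$instances), 6L)
  inst <- extract_spine_instances(sc$labels)
  expect_length(inst, 6L)
})

test_that("degradation follows blur -> shot noise -> read noise with an identity limit", {
  # scene fully interior to the grid, so no intensity crosses the border
  spec <- scene_spec(shape = c(24, 64, 128),
                     path = rbind(c(1.7, 2.1, 1.5), c(1.7, 2.1, 6.5)),
                     spines = data.frame(position_um = c(2.5, 4), angle = c(pi/2, pi),
                                         neck_length_um = 0.5, neck_radius_um = 0.1,
                                         head_radius_um = 0.3))
  sc <- generate_scene(spec)
  idd <- degrade(sc$image, degrade_spec(sigma_lateral_um = 0, sigma_axial_um = 0,
                                        photon_scale = Inf, read_noise_sd = 0))
  expect_equal(idd$voxels, sc$image$voxels)
  # blur conserves mean intensity (normalized kernel; all signal interior)
  blurred <- degrade(sc$image, degrade_spec(sigma_lateral_um = 0.1,
                                            sigma_axial_um = 0.3,
                                            photon_scale = Inf, read_noise_sd = 0))
  expect_lt(abs(mean(blurred$voxels) - mean(sc$image$voxels)) /
              mean(sc$image$voxels), 0.01)
  # degradation never alters the label map (ground truth is generated)
  lab_before <- sc$labels$labels
  invisible(degrade(sc$image, degrade_spec(seed = 9)))
  expect_identical(sc$labels$labels, lab_before)
})

test_that("noise variance grows as the photon scale drops", {
  sc <- straight_scene(3, shape = c(12, 32, 64), seed = 2, soma = FALSE)
  vars <- vapply(c(2, 0.5, 0.1, 0.02), function(ps) {
    draws <- vapply(1:4, function(s) {
      g <- degrade(sc$image, degrade_spec(sigma_lateral_um = 0, sigma_axial_um = 0,
                                          photon_scale = ps, read_noise_sd = 0,
                                          seed = s))
      stats::var(as.vector(g$voxels - sc$image$voxels))
    }, numeric(1))
    mean(draws)
  }, numeric(1))
  expect_true(all(diff(vars) > 0))
})

test_that("augmentation ops respect the geometric/photometric contract", {
  sc <- straight_scene(3, shape = c(12, 48, 96), seed = 6, soma = FALSE)
  aug <- augment_pair(sc$image, sc$labels, seed = 5)
  expect_named(aug, c("rot90", "flip_z", "flip_y", "flip_x", "shot_noise",
                      "gaussian_blur"))
  # flips applied twice are the identity
  ff <- augment_pair(aug$flip_y$image, aug$flip_y$labels, ops = "flip_y", seed = 1)
  expect_equal(ff$flip_y$image$voxels, sc$image$voxels)
  expect_identical(ff$flip_y$labels$labels, sc$labels$labels)
  # right-angle rotation permutes voxels: per-class counts are exact
  for (code in 0:4) {
    expect_equal(sum(aug$rot90$labels$labels == code), sum(sc$labels$labels == code))
  }
  # rotation applies the same permutation to image and labels
  expect_equal(sum(aug$rot90$image$voxels > sc$spec$bg_intensity),
               sum(sc$image$voxels > sc$spec$bg_intensity))
  # photometric ops change the image but never the labels
  expect_false(identical(aug$shot_noise$image$voxels, sc$image$voxels))
  expect_identical(aug$shot_noise$labels$labels, sc$labels$labels)
  expect_false(identical(aug$gaussian_blur$image$voxels, sc$image$voxels))
  expect_identical(aug$gaussian_blur$labels$labels, sc$labels$labels)
  # reproducible under a fixed seed; arbitrary-angle rotation unsupported
  aug2 <- augment_pair(sc$image, sc$labels, seed = 5)
  expect_equal(aug$shot_noise$image$voxels, aug2$shot_noise$image$voxels)
  expect_error(augment_pair(sc$image, sc$labels, ops = "rot45"), "unsupported")
})

test_that("clean-scene morphometry round trip recovers the planted geometry", {
  sc <- straight_scene(8, shape = c(32, 96, 192), seed = 21)
  inst <- attach_to_dendrite(extract_spine_instances(sc$labels), sc$labels)
  expect_length(inst, 8L) # spine count exact
  rec <- measure_spines(inst, sc$labels, sc$image)
  # match measured instances to gt rows through the gt instance map
  gt_of <- vapply(inst, function(s) {
    ids <- sc$instances[spinemorph:::instance_voxels(s)]
    as.integer(names(sort(table(ids[ids > 0]), decreasing = TRUE))[1])
  }, integer(1))
  gt <- sc$gt[gt_of, ]
  big <- gt$head_radius_um >= 3 * sc$labels$spacing[3]
  expect_true(all(abs(rec$head_volume_um3[big] - gt$head_volume_um3[big]) /
                    gt$head_volume_um3[big] < 0.15))
  expect_true(all(abs(rec$neck_length_um - gt$neck_length_um) <
                    pmax(0.15 * gt$neck_length_um, 0.15)))
  expect_true(all(abs(rec$spine_length_um - gt$spine_length_um) /
                    gt$spine_length_um < 0.15))
})
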