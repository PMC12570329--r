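# Synthetic dendrite + spine phantoms with exact ground truth, plus the
# imaging-degradation (anisotropic PSF blur -> shot noise -> read noise) and
# augmentation operators. Scenes emulate sparsely labelled dendrites imaged
# at the two acquisition geometries used throughout: spinning-disk confocal
# (65 x 65 x 150 nm voxels) and in vivo two-photon (102 x 102 x 1000 nm,
# ~10x axial anisotropy).

#' Acquisition presets
#'
#' @param preset `"spinning-disk"` (0.150, 0.065, 0.065 um) or
#'   `"two-photon"` (1.0, 0.102, 0.102 um), spacing as `(z, y, x)`.
#' @return Named list with `spacing`.
#' @export
acquisition_preset <- function(preset = c("spinning-disk", "two-photon")) {
  preset <- match.arg(preset)
  switch(preset,
         "spinning-disk" = list(spacing = c(0.150, 0.065, 0.065)),
         "two-photon" = list(spacing = c(1.0, 0.102, 0.102)))
}

#' Specify a synthetic dendrite + spine scene
#'
#' The stated world: a tube-like dendritic shaft following `path`, an
#' optional spherical soma, and spines made of a thin cylindrical neck plus
#' an ellipsoidal (spherical) head attached on the shaft surface. Class
#' painting precedence at overlaps is head > neck > dendrite > soma.
#'
#' @param shape Grid shape `(nz, ny, nx)`.
#' @param spacing Voxel size `(z, y, x)` um; default spinning-disk geometry.
#' @param path Dendrite centreline polyline, matrix of `(z, y, x)` um rows.
#' @param dendrite_radius_um Shaft radius.
#' @param soma_center,soma_radius_um Optional soma ball (um); `NULL` for none.
#' @param spines `data.frame` with one row per spine: `position_um` (arc
#'   length along `path`), `angle` (radians around the local tangent),
#'   `neck_length_um`, `neck_radius_um`, `head_radius_um`.
#' @param fg_intensity,bg_intensity Rendered intensities.
#' @param seed Integer seed fixing everything random downstream.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(shape, spacing = acquisition_preset()$spacing, path,
                       dendrite_radius_um = 0.4,
                       soma_center = NULL, soma_radius_um = NULL,
                       spines = NULL, fg_intensity = 200, bg_intensity = 10,
                       seed = 1L) {
  spacing <- check_spacing(spacing)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) stop_arg("shape must be (nz, ny, nx) >= 1")
  path <- as.matrix(path)
  if (ncol(path) != 3L || nrow(path) < 2L) stop_arg("path must be >= 2 rows of (z, y, x) um")
  if (dendrite_radius_um <= 0) stop_arg("dendrite_radius_um must be > 0")
  if (!is.null(soma_center) && (is.null(soma_radius_um) || soma_radius_um <= 0)) {
    stop_arg("soma_radius_um must be > 0 when a soma is given")
  }
  if (is.null(spines)) {
    spines <- data.frame(position_um = numeric(0), angle = numeric(0),
                         neck_length_um = numeric(0), neck_radius_um = numeric(0),
                         head_radius_um = numeric(0))
  }
  spines <- as.data.frame(spines)
  need <- c("position_um", "angle", "neck_length_um", "neck_radius_um", "head_radius_um")
  if (!all(need %in% names(spines))) {
    stop_arg("spines must have columns ", paste(need, collapse = ", "))
  }
  plen <- path_length(path)
  if (nrow(spines) > 0L) {
    if (any(spines$position_um < 0 | spines$position_um > plen)) {
      stop_arg("spine position_um must lie on the dendrite path (0..", round(plen, 3), " um)")
    }
    if (any(spines$neck_radius_um <= 0) || any(spines$head_radius_um < 0) ||
        any(spines$neck_length_um < 0)) {
      stop_arg("spine radii must be positive and neck lengths non-negative")
    }
  }
  structure(list(shape = shape, spacing = spacing, path = path,
                 dendrite_radius_um = dendrite_radius_um,
                 soma_center = soma_center, soma_radius_um = soma_radius_um,
                 spines = spines, fg_intensity = fg_intensity,
                 bg_intensity = bg_intensity, seed = as.integer(seed)),
            class = "scene_spec")
}

path_length <- function(path) {
  sum(sqrt(rowSums((path[-1L, , drop = FALSE] - path[-nrow(path), , drop = FALSE])^2)))
}

# point at arc length s along the polyline, plus the local unit tangent
path_point <- function(path, s) {
  seg <- path[-1L, , drop = FALSE] - path[-nrow(path), , drop = FALSE]
  lens <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(lens))
  s <- min(max(s, 0), cum[length(cum)])
  i <- max(which(cum <= s + 1e-12))
  i <- min(i, nrow(seg))
  t <- if (lens[i] > 0) (s - cum[i]) / lens[i] else 0
  list(point = path[i, ] + t * seg[i, ], tangent = seg[i, ] / max(lens[i], 1e-12))
}

# a unit vector perpendicular to `tangent`, rotated by `angle` around it
perp_vector <- function(tangent, angle) {
  ref <- if (abs(tangent[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * tangent) * tangent
  u <- u / sqrt(sum(u^2))
  w <- c(tangent[2L] * u[3L] - tangent[3L] * u[2L],
         tangent[3L] * u[1L] - tangent[1L] * u[3L],
         tangent[1L] * u[2L] - tangent[2L] * u[1L])
  cos(angle) * u + sin(angle) * w
}

# paint all voxels within `radius` of segment p0-p1 (um) into arr (by ref
# semantics: returns modified copy); only the bounding box is scanned
paint_capsule <- function(arr, value, p0, p1, radius, spacing) {
  d <- dim(arr)
  lo <- pmax(floor((pmin(p0, p1) - radius) / spacing), 0)
  hi <- pmin(ceiling((pmax(p0, p1) + radius) / spacing), d - 1)
  if (any(lo > hi)) return(arr)
  zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
  nz <- length(zi); ny <- length(yi); nx <- length(xi)
  Z <- array(zi * spacing[1L], c(nz, ny, nx))
  Y <- array(rep(yi * spacing[2L], each = nz), c(nz, ny, nx))
  X <- array(rep(xi * spacing[3L], each = nz * ny), c(nz, ny, nx))
  w <- p1 - p0
  L2 <- sum(w^2)
  if (L2 < 1e-18) {
    d2 <- (Z - p0[1L])^2 + (Y - p0[2L])^2 + (X - p0[3L])^2
  } else {
    t <- ((Z - p0[1L]) * w[1L] + (Y - p0[2L]) * w[2L] + (X - p0[3L]) * w[3L]) / L2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (Z - (p0[1L] + t * w[1L]))^2 + (Y - (p0[2L] + t * w[2L]))^2 +
      (X - (p0[3L] + t * w[3L]))^2
  }
  sel <- d2 <= radius^2
  sub <- arr[zi + 1L, yi + 1L, xi + 1L, drop = FALSE]
  sub[sel] <- value
  arr[zi + 1L, yi + 1L, xi + 1L] <- sub
  arr
}

paint_ball <- function(arr, value, center, radius, spacing) {
  paint_capsule(arr, value, center, center, radius, spacing)
}

#' Generate a synthetic scene with exact ground truth
#'
#' Voxelizes the scene into a fluorescence [volume_image()], a
#' [semantic_labels()] map, a ground-truth instance label array (spine k =
#' label k, in the order of `spec$spines`) and a ground-truth table carrying
#' the analytic measurements of every spine: head volume `4/3 pi r^3`,
#' neck length, head width `2r`, spine length (neck + head diameter), and
#' the path-measured geodesic soma distance. Identical specs (same seed)
#' produce bit-identical outputs; the generator itself is deterministic.
#'
#' @param spec A [scene_spec()].
#' @return List with `image`, `labels`, `instances`, `gt` (`data.frame`) and
#'   `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  d <- spec$shape
  sp <- spec$spacing
  codes <- spine_class_codes()
  lab <- array(codes[["background"]], d)
  inst <- array(0L, d)
  # precedence head > neck > dendrite > soma: paint in reverse order
  if (!is.null(spec$soma_center)) {
    lab <- paint_ball(lab, codes[["soma"]], spec$soma_center, spec$soma_radius_um, sp)
  }
  for (i in seq_len(nrow(spec$path) - 1L)) {
    lab <- paint_capsule(lab, codes[["dendrite"]], spec$path[i, ], spec$path[i + 1L, ],
                         spec$dendrite_radius_um, sp)
  }
  ns <- nrow(spec$spines)
  gt <- cbind(data.frame(instance_id = seq_len(ns)), spec$spines,
              data.frame(head_volume_um3 = rep(NA_real_, ns),
                         volume_um3 = rep(NA_real_, ns),
                         head_width_um = rep(NA_real_, ns),
                         spine_length_um = rep(NA_real_, ns),
                         soma_distance_geodesic_um = rep(NA_real_, ns)))
  soma_exit <- if (!is.null(spec$soma_center)) {
    # arc position where the path leaves the soma ball (assumed near path start)
    ss <- seq(0, path_length(spec$path), length.out = 512L)
    inside <- vapply(ss, function(s) {
      sqrt(sum((path_point(spec$path, s)$point - spec$soma_center)^2)) <= spec$soma_radius_um
    }, logical(1))
    if (any(inside)) max(ss[inside]) else 0
  } else NA_real_
  for (k in seq_len(ns)) {
    srow <- spec$spines[k, ]
    pp <- path_point(spec$path, srow$position_um)
    u <- perp_vector(pp$tangent, srow$angle)
    base <- pp$point + u * spec$dendrite_radius_um          # on the shaft surface
    neck_end <- base + u * srow$neck_length_um
    head_center <- neck_end + u * srow$head_radius_um        # head tangent to neck end
    if (srow$neck_length_um > 0) {
      lab <- paint_capsule(lab, codes[["spine_neck"]], base, neck_end,
                           srow$neck_radius_um, sp)
      inst <- paint_capsule(inst, k, base, neck_end, srow$neck_radius_um, sp)
    }
    if (srow$head_radius_um > 0) {
      lab <- paint_ball(lab, codes[["spine_head"]], head_center, srow$head_radius_um, sp)
      inst <- paint_ball(inst, k, head_center, srow$head_radius_um, sp)
    }
    gt$head_volume_um3[k] <- 4 / 3 * pi * srow$head_radius_um^3
    gt$volume_um3[k] <- gt$head_volume_um3[k] +
      pi * srow$neck_radius_um^2 * srow$neck_length_um
    gt$head_width_um[k] <- 2 * srow$head_radius_um
    gt$spine_length_um[k] <- srow$neck_length_um + 2 * srow$head_radius_um
    gt$soma_distance_geodesic_um[k] <- if (is.na(soma_exit)) NA_real_
      else max(0, srow$position_um - soma_exit)
  }
  storage.mode(inst) <- "integer"
  labels <- semantic_labels(lab, sp)
  img <- array(spec$bg_intensity, d)
  img[lab != codes[["background"]]] <- spec$fg_intensity
  image <- volume_image(array(img, c(1L, d)), sp)
  attr(gt, "path_length_um") <- path_length(spec$path)
  attr(gt, "density_per_um") <- if (path_length(spec$path) > 0)
    ns / path_length(spec$path) else NA_real_
  list(image = image, labels = labels, instances = inst, gt = gt, spec = spec)
}

#' Random scene with realistic spine statistics
#'
#' Convenience builder for tests and demos: a straight dendrite spanning the
#' field along x at mid-depth, an optional soma at the start, and `n_spines`
#' spines evenly spread with jittered positions and alternating orientations.
#' Geometry defaults reflect typical cortical pyramidal-neuron spines: head
#' radii 0.25--0.45 um, neck lengths 0.4--1.0 um, neck radius 0.1 um, shaft
#' radius 0.4 um.
#'
#' @param n_spines Number of spines.
#' @param shape Grid `(nz, ny, nx)`; default `c(48, 128, 256)`.
#' @param preset Acquisition preset name (see [acquisition_preset()]).
#' @param soma Add a soma ball at the path start.
#' @param seed Random seed.
#' @return A [scene_spec()].
#' @export
random_scene_spec <- function(n_spines = 12L, shape = c(48L, 128L, 256L),
                              preset = "spinning-disk", soma = TRUE, seed = 1L) {
  sp <- acquisition_preset(preset)$spacing
  shape <- as.integer(shape)
  extent <- (shape - 1L) * sp
  mid <- extent / 2
  # snap the shaft axis onto a z voxel plane: at coarse axial sampling an
  # off-plane axis can leave thin structures without any voxel centres
  mid[1L] <- round(mid[1L] / sp[1L]) * sp[1L]
  path <- rbind(c(mid[1L], mid[2L], 0), c(mid[1L], mid[2L], extent[3L]))
  plen <- extent[3L]
  soma_center <- NULL
  soma_radius <- NULL
  if (soma) {
    soma_radius <- min(1.5, extent[2L] / 3)
    soma_center <- c(mid[1L], mid[2L], 0)
  }
  set.seed(seed)
  lo <- if (soma) (soma_radius %||% 0) + 1.5 else 1.0
  if (n_spines > 1L && (plen - 1.0 - lo) / (n_spines - 1L) < 0.55) {
    stop_arg("too many spines for this field of view: spines would overlap ",
             "(need >= 0.55 um spacing along the shaft)")
  }
  pos <- seq(lo, plen - 1.0, length.out = max(n_spines, 1L))
  pos <- pos + stats::runif(n_spines, -0.2, 0.2) * (if (n_spines > 1) diff(pos[1:2]) else 1)
  pos <- pmin(pmax(pos, lo), plen - 1.0)
  # orientations rotate around the shaft so that neighbouring spines sit on
  # different sides and never touch (instances must stay disjoint); under
  # strong axial anisotropy (two-photon, ~10x) axially projecting spines are
  # unresolvable, so spines stay lateral there as they would in analysis
  angles <- if (sp[1L] / sp[2L] > 4) {
    # exactly lateral: any tilt out of the z plane fragments thin necks
    rep(c(pi / 2, 3 * pi / 2), length.out = n_spines)
  } else {
    (seq_len(n_spines) %% 4L) * pi / 2 + stats::runif(n_spines, -0.3, 0.3)
  }
  spines <- data.frame(
    position_um = pos,
    angle = angles,
    neck_length_um = stats::runif(n_spines, 0.4, 1.0),
    neck_radius_um = 0.1,
    head_radius_um = stats::runif(n_spines, 0.25, 0.45))
  scene_spec(shape = shape, spacing = sp, path = path,
             dendrite_radius_um = 0.4,
             soma_center = soma_center, soma_radius_um = soma_radius,
             spines = spines, seed = seed)
}

# ---------------------------------------------------------------------------
# Imaging degradation

#' Specify the imaging-degradation model
#'
#' Anisotropic Gaussian blur (axial sigma >= lateral, mimicking PSF
#' elongation: axial optical resolution is typically 2--3x worse), then
#' Poisson shot noise at `photon_scale` photons per intensity unit, then
#' additive Gaussian read noise. `photon_scale` is the single SNR knob: the
#' defaults (0.1 photons/unit at the low end vs 2.5 at the high end,
#' constructed as `low_snr`/`high_snr` presets) emulate paired low/high-SNR
#' acquisitions at low vs standard excitation power.
#'
#' @param sigma_lateral_um,sigma_axial_um PSF Gaussian sigmas (um).
#' @param photon_scale Photons per intensity unit (`Inf` disables shot noise).
#' @param read_noise_sd Additive Gaussian sigma (intensity units).
#' @param seed Seed used by [degrade()].
#' @return An object of class `degrade_spec`.
#' @export
degrade_spec <- function(sigma_lateral_um = 0.09, sigma_axial_um = 0.25,
                         photon_scale = 0.1, read_noise_sd = 2, seed = 1L) {
  if (sigma_lateral_um < 0 || sigma_axial_um < 0) stop_arg("PSF sigmas must be >= 0")
  if (!(photon_scale > 0)) stop_arg("photon_scale must be > 0 (use Inf to disable)")
  structure(list(sigma_lateral_um = sigma_lateral_um, sigma_axial_um = sigma_axial_um,
                 photon_scale = photon_scale, read_noise_sd = read_noise_sd,
                 seed = as.integer(seed)),
            class = "degrade_spec")
}

# separable Gaussian convolution with replicate edges, sigma in um per axis
gaussian_blur_um <- function(arr, sigma_um, spacing) {
  d <- dim(arr)
  for (ax in 1:3) {
    sv <- sigma_um[ax] / spacing[ax]
    if (sv < 1e-3) next
    r <- max(1L, ceiling(3 * sv))
    k <- stats::dnorm(-r:r, sd = sv)
    k <- k / sum(k)
    out <- array(0, d)
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(d[ax]) + j, 1L), d[ax]) # replicate edges
      sl <- switch(ax, arr[idx, , , drop = FALSE], arr[, idx, , drop = FALSE],
                   arr[, , idx, drop = FALSE])
      out <- out + k[j + r + 1L] * sl
    }
    arr <- out
  }
  arr
}

#' Degrade a clean volume with the imaging model
#'
#' Blur -> Poisson shot noise -> read noise, per channel. The zero-sigma,
#' infinite-photon, zero-read-noise limit is the identity. Degradation never
#' touches label maps: ground truth is generated, not re-derived.
#'
#' @param v A [volume_image()].
#' @param d A [degrade_spec()].
#' @return A degraded [volume_image()].
#' @export
degrade <- function(v, d = degrade_spec()) {
  stopifnot(inherits(v, "volume_image"), inherits(d, "degrade_spec"))
  set.seed(d$seed)
  dims <- dim(v$voxels)
  sigma <- c(d$sigma_axial_um, d$sigma_lateral_um, d$sigma_lateral_um)
  out <- v$voxels
  for (ch in seq_len(dims[1L])) {
    a <- gaussian_blur_um(array(v$voxels[ch, , , ], dims[2:4]), sigma, v$spacing)
    if (is.finite(d$photon_scale)) {
      a <- array(stats::rpois(length(a), pmax(a, 0) * d$photon_scale) / d$photon_scale,
                 dims[2:4])
    }
    if (d$read_noise_sd > 0) {
      a <- a + array(stats::rnorm(length(a), 0, d$read_noise_sd), dims[2:4])
    }
    out[ch, , , ] <- a
  }
  volume_image(out, v$spacing, v$channel_names)
}

# ---------------------------------------------------------------------------
# Augmentation

#' Training-style augmentation of an image/label pair
#'
#' One augmented pair per requested op. Geometric ops (right-angle rotation
#' about z, per-axis flips) are applied identically to image and labels
#' (labels are permuted voxels, never interpolated); photometric ops (shot
#' noise, Gaussian blur) touch the image only. Arbitrary-angle rotation is
#' deliberately unsupported: it would force label interpolation. Seeded and
#' reproducible.
#'
#' @param image A [volume_image()].
#' @param labels The congruent [semantic_labels()].
#' @param ops Subset of `"rot90"`, `"flip_z"`, `"flip_y"`, `"flip_x"`,
#'   `"shot_noise"`, `"gaussian_blur"`.
#' @param seed Seed for the random parameters (rotation count, noise level,
#'   blur width).
#' @return Named list of `list(image, labels)` pairs, one per op.
#' @export
augment_pair <- function(image, labels,
                         ops = c("rot90", "flip_z", "flip_y", "flip_x",
                                 "shot_noise", "gaussian_blur"),
                         seed = 1L) {
  stopifnot(inherits(image, "volume_image"), inherits(labels, "semantic_labels"))
  check_congruent(image, labels)
  allowed <- c("rot90", "flip_z", "flip_y", "flip_x", "shot_noise", "gaussian_blur")
  bad <- setdiff(ops, allowed)
  if (length(bad) > 0L) {
    stop_arg("unsupported augmentation op(s): ", paste(bad, collapse = ", "),
             " (right-angle geometric ops only)")
  }
  set.seed(seed)
  geom <- function(f3) {
    # apply a 3-D voxel permutation to every channel and to the labels
    dims <- dim(image$voxels)
    l2 <- f3(labels$labels)
    iv <- array(0, c(dims[1L], dim(l2)))
    for (ch in seq_len(dims[1L])) iv[ch, , , ] <- f3(array(image$voxels[ch, , , ], dims[2:4]))
    sp <- labels$spacing
    list(image = volume_image(iv, sp, image$channel_names),
         labels = semantic_labels(l2, sp, labels$class_codes))
  }
  out <- list()
  for (op in ops) {
    out[[op] ] <- switch(op,
      rot90 = {
        k <- sample(1:3, 1L)
        if (!isTRUE(all.equal(image$spacing[2L], image$spacing[3L]))) {
          stop_arg("rot90 about z requires equal y and x spacing")
        }
        geom(function(a) rot90_z(a, k))
      },
      flip_z = geom(function(a) a[dim(a)[1L]:1, , , drop = FALSE]),
      flip_y = geom(function(a) a[, dim(a)[2L]:1, , drop = FALSE]),
      flip_x = geom(function(a) a[, , dim(a)[3L]:1, drop = FALSE]),
      shot_noise = list(
        image = degrade(image, degrade_spec(sigma_lateral_um = 0, sigma_axial_um = 0,
                                            photon_scale = stats::runif(1, 0.05, 0.5),
                                            read_noise_sd = 0,
                                            seed = sample.int(1e6, 1L))),
        labels = labels),
      gaussian_blur = {
        s <- stats::runif(1, 0.05, 0.2)
        list(image = degrade(image, degrade_spec(sigma_lateral_um = s,
                                                 sigma_axial_um = 2 * s,
                                                 photon_scale = Inf, read_noise_sd = 0,
                                                 seed = 1L)),
             labels = labels)
      })
  }
  out
}

# right-angle rotation of a (z, y, x) array about the z axis, k quarter turns
rot90_z <- function(a, k) {
  k <- k %% 4L
  for (i in seq_len(k)) {
    # (y, x) -> (x, ny - y + 1): transpose then reverse the new y axis
    a <- aperm(a, c(1L, 3L, 2L))
    a <- a[, dim(a)[2L]:1, , drop = FALSE]
  }
  a
}
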