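# Batch orchestration: configuration, the per-folder analysis driver, run
# logging, and the visual audit outputs (MIP overlays, spine crop arrays).
# Restoration and segmentation are adapter stages: this driver consumes
# precomputed (optionally restored) volumes and label maps produced by
# external models; it never bundles or runs them.

#' Pipeline configuration
#'
#' All user-facing knobs of the analysis driver, resolvable from a single
#' JSON or flat YAML file via [read_config()]. Every run logs the fully
#' resolved configuration.
#'
#' @param spacing Acquisition voxel size `(z, y, x)` um.
#' @param channels Channels interleaved in each image TIFF.
#' @param filter A [filter_spec()].
#' @param analysis_spacing Optional `(z, y, x)` um to rescale to before
#'   instance extraction (labels nearest, image linear); measurements are in
#'   um either way and audit volumes are written back at the original grid.
#' @param connectivity Instance connectivity (6/18/26).
#' @param iou_threshold Validation object-match threshold.
#' @param track_min_iou Tracking persistence threshold.
#' @param save_intermediates Write skeleton + distance-map TIFFs.
#' @param save_overlays Write MIP overlay images (PPM).
#' @param save_spine_arrays Write per-spine crop montages and 3-D stacks.
#' @param crop_size_um Side length of the per-spine crops.
#' @param seed Seed for the (only) stochastic output choice: overlay colors.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spacing = acquisition_preset()$spacing, channels = 1L,
                            filter = filter_spec(), analysis_spacing = NULL,
                            connectivity = 26L, iou_threshold = 0.5,
                            track_min_iou = 0.3, save_intermediates = FALSE,
                            save_overlays = TRUE, save_spine_arrays = FALSE,
                            crop_size_um = 2, seed = 1L) {
  if (is.list(filter) && !inherits(filter, "filter_spec")) filter <- do.call(filter_spec, filter)
  structure(list(spacing = check_spacing(spacing), channels = as.integer(channels),
                 filter = filter,
                 analysis_spacing = if (is.null(analysis_spacing)) NULL
                                    else check_spacing(analysis_spacing),
                 connectivity = as.integer(connectivity),
                 iou_threshold = iou_threshold, track_min_iou = track_min_iou,
                 save_intermediates = isTRUE(save_intermediates),
                 save_overlays = isTRUE(save_overlays),
                 save_spine_arrays = isTRUE(save_spine_arrays),
                 crop_size_um = crop_size_um, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or flat YAML
#'
#' JSON is parsed with jsonlite. The YAML support is a deliberately small
#' subset (scalar `key: value` pairs, one level of nesting by two-space
#' indentation, inline `[a, b, c]` lists) sufficient for this configuration.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("jsonlite is required to read JSON configs", call. = FALSE)
    }
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    parse_mini_yaml(readLines(path, warn = FALSE))
  } else {
    stop_arg("config must be .json, .yaml or .yml")
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop_arg("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

parse_scalar <- function(x) {
  x <- trimws(x)
  if (grepl("^\\[.*\\]$", x)) {
    parts <- trimws(strsplit(sub("^\\[(.*)\\]$", "\\1", x), ",")[[1L]])
    return(unlist(lapply(parts, parse_scalar)))
  }
  if (x %in% c("true", "True", "TRUE", "yes")) return(TRUE)
  if (x %in% c("false", "False", "FALSE", "no")) return(FALSE)
  if (x %in% c("null", "~", "")) return(NULL)
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) return(n)
  gsub('^"|"$', "", x)
}

parse_mini_yaml <- function(lines) {
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  current <- NULL
  for (ln in lines) {
    indented <- grepl("^\\s+\\S", ln)
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1L]]
    if (length(m) == 0L) stop_arg("cannot parse config line: ", ln)
    key <- m[2L]
    val <- m[3L]
    if (!indented) {
      if (val == "") {
        current <- key
        out[[key]] <- list()
      } else {
        current <- NULL
        out[key] <- list(parse_scalar(val))
      }
    } else {
      if (is.null(current)) stop_arg("indented key without a parent: ", ln)
      out[[current]][key] <- list(parse_scalar(val))
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Analysis driver

#' Analyze a folder of image / label-map pairs
#'
#' Pairs `<stem>.tif` with `<stem>_labels.tif` in `input_dir` and, for each
#' pair: optional rescale to the analysis spacing, instance extraction,
#' dendrite attachment, filtering, skeletonization, morphometry; writes the
#' per-spine CSV, the instance label TIFF (at the original grid), the MIP
#' overlay and optional intermediates, then one combined summary CSV and a
#' timestamped run log. Per-image failures are logged and skipped; the run
#' continues. Outputs are deterministic for identical inputs + config.
#'
#' @param input_dir Folder of TIFF pairs.
#' @param output_dir Output folder (created).
#' @param config A [pipeline_config()].
#' @return Invisibly, a `data.frame` of per-image status with attribute
#'   `ok` (TRUE iff every image succeeded).
#' @export
run_analysis <- function(input_dir, output_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(output_dir, "run_log.txt")
  logf <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", sprintf(...))
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat("", file = log_path)
  logf("spinemorph %s analysis run", as.character(utils::packageVersion("spinemorph")))
  logf("resolved config: %s", paste(utils::capture.output(utils::str(unclass(config))),
                                    collapse = " "))
  tifs <- list.files(input_dir, pattern = "\\.tif{1,2}$", ignore.case = TRUE)
  stems <- sub("\\.tif{1,2}$", "", tifs, ignore.case = TRUE)
  images <- tifs[!grepl("_labels$", stems)]
  status <- data.frame(image = character(0), n_spines = integer(0), ok = logical(0),
                       note = character(0))
  all_summaries <- list()
  for (img_file in images) {
    stem <- sub("\\.tif{1,2}$", "", img_file, ignore.case = TRUE)
    lab_file <- file.path(input_dir, paste0(stem, "_labels.tif"))
    if (!file.exists(lab_file)) lab_file <- file.path(input_dir, paste0(stem, "_labels.tiff"))
    if (!file.exists(lab_file)) {
      logf("WARNING %s: no matching label file, skipped", img_file)
      status <- rbind(status, data.frame(image = stem, n_spines = NA_integer_,
                                         ok = FALSE, note = "missing labels"))
      next
    }
    res <- tryCatch({
      v <- read_volume(file.path(input_dir, img_file), config$spacing,
                       channels = config$channels)
      m <- read_labels(lab_file, config$spacing)
      check_congruent(v, m)
      orig_dims <- dim(m$labels)
      va <- v; ma <- m
      if (!is.null(config$analysis_spacing)) {
        va <- rescale_volume(v, config$analysis_spacing, order = "linear")
        ma <- rescale_labels(m, config$analysis_spacing)
      }
      inst <- extract_spine_instances(ma, config$connectivity)
      inst <- attach_to_dendrite(inst, ma)
      flt <- filter_spines(inst, config$filter)
      tree <- skeletonize_dendrite(ma)
      records <- measure_spines(flt$kept, ma, va)
      imap <- instance_map(flt$kept, dim(ma$labels))
      if (!is.null(config$analysis_spacing)) {
        # audit volumes are reported back at the original resolution
        imap <- resize3d(imap, orig_dims, "nearest")
      }
      write_spine_table(records, file.path(output_dir, paste0(stem, "_spines.csv")))
      write_labels(imap, file.path(output_dir, paste0(stem, "_instances.tif")))
      summ <- summarize_spines(records, tree, image_id = stem)
      if (config$save_overlays) {
        mip_overlay(v, imap, records, path = file.path(output_dir, paste0(stem, "_mip.ppm")),
                    seed = config$seed)
      }
      if (config$save_spine_arrays) {
        spine_crop_array(va, flt$kept, records, crop_size_um = config$crop_size_um,
                         path_prefix = file.path(output_dir, stem))
      }
      if (config$save_intermediates) {
        skel_arr <- array(0L, dim(ma$labels))
        vox <- round(cbind(tree$z / ma$spacing[1], tree$y / ma$spacing[2],
                           tree$x / ma$spacing[3]))
        skel_arr[zyx_to_lin(vox, dim(ma$labels))] <- 1L
        write_labels(skel_arr, file.path(output_dir, paste0(stem, "_skeleton.tif")))
        dmap <- edt_um(class_mask(ma, "dendrite"), ma$spacing)$dist
        write_volume(volume_image(array(dmap, c(1L, dim(dmap))), ma$spacing),
                     file.path(output_dir, paste0(stem, "_distance_map.tif")),
                     type = "float32")
        write_swc(tree, file.path(output_dir, paste0(stem, ".swc")))
      }
      logf("OK %s: %d spine(s) kept, %d rejected", stem, length(flt$kept),
           length(flt$rejected))
      list(summary = summ, n = length(flt$kept))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      logf("ERROR %s: %s", stem, conditionMessage(res))
      status <- rbind(status, data.frame(image = stem, n_spines = NA_integer_,
                                         ok = FALSE, note = conditionMessage(res)))
    } else {
      all_summaries[[stem]] <- res$summary
      status <- rbind(status, data.frame(image = stem, n_spines = res$n,
                                         ok = TRUE, note = ""))
    }
  }
  if (length(all_summaries) > 0L) {
    write_summary_table(do.call(rbind, all_summaries),
                        file.path(output_dir, "summary.csv"))
  }
  logf("run complete: %d/%d image(s) succeeded", sum(status$ok), nrow(status))
  attr(status, "ok") <- nrow(status) > 0L && all(status$ok)
  invisible(status)
}

# ---------------------------------------------------------------------------
# Visual audit outputs

instance_palette <- function(k, seed = 1L) {
  if (k == 0L) return(character(0))
  hues <- (seq_len(k) - 1L) * 360 / max(k, 1L)
  set.seed(seed)
  hues <- (hues + stats::runif(1, 0, 360)) %% 360
  grDevices::hcl(h = hues, c = 90, l = 65)
}

#' Write an RGB array as a binary PPM image
#'
#' @param rgb Array `[y, x, 3]` with values in `[0, 1]`.
#' @param path Output path (`.ppm`).
#' @return `path`, invisibly.
#' @export
write_ppm <- function(rgb, path) {
  d <- dim(rgb)
  stopifnot(length(d) == 3L, d[3L] == 3L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(sprintf("P6\n%d %d\n255\n", d[2L], d[1L])), con)
  v <- round(pmin(pmax(rgb, 0), 1) * 255)
  # PPM is row-major with interleaved RGB
  inter <- aperm(v, c(3L, 2L, 1L))
  writeBin(as.raw(as.integer(inter)), con)
  invisible(path)
}

#' Maximum-intensity-projection overlay of spine detections
#'
#' Z-axis maximum projection of the reference channel in gray with
#' per-instance colored outlines of the projected instance map. Colors are
#' stable for a fixed seed.
#'
#' @param v A [volume_image()].
#' @param instances Instance label array (3-D) congruent with `v`.
#' @param records Optional per-spine table (reserved for annotations).
#' @param path Optional `.ppm` output path.
#' @param channel Projected channel.
#' @param seed Color seed.
#' @return The RGB array `[y, x, 3]`, invisibly if `path` is given.
#' @export
mip_overlay <- function(v, instances, records = NULL, path = NULL, channel = 1L,
                        seed = 1L) {
  stopifnot(inherits(v, "volume_image"))
  d <- dim(v$voxels)
  mip <- apply(array(v$voxels[channel, , , ], d[2:4]), c(2L, 3L), max)
  rng <- range(mip)
  g <- if (diff(rng) > 0) (mip - rng[1L]) / diff(rng) else mip * 0
  rgb <- array(rep(g, 3L), c(dim(g), 3L))
  if (!is.null(instances) && max(instances) > 0L) {
    proj <- apply(instances, c(2L, 3L), max)
    k <- max(proj)
    cols <- grDevices::col2rgb(instance_palette(k, seed)) / 255
    # outline: projected pixels whose 4-neighbourhood changes id
    pad <- function(m, dy, dx) {
      ny <- nrow(m); nx <- ncol(m)
      m[pmin(pmax(seq_len(ny) + dy, 1L), ny), pmin(pmax(seq_len(nx) + dx, 1L), nx)]
    }
    edge <- proj > 0 & (proj != pad(proj, 1, 0) | proj != pad(proj, -1, 0) |
                        proj != pad(proj, 0, 1) | proj != pad(proj, 0, -1))
    idx <- which(edge, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      ids <- proj[edge]
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[idx] <- cols[ch, ids]
        rgb[, , ch] <- plane
      }
    }
  }
  if (!is.null(path)) {
    write_ppm(rgb, path)
    return(invisible(rgb))
  }
  rgb
}

#' Per-spine crop array (2-D montage + 3-D stack)
#'
#' Cuts a cube of side `crop_size_um` around each spine centroid (image +
#' instance mask), tiles per-spine MIPs into a 2-D montage ordered by
#' instance id, and optionally writes the stacked 3-D crops as a multi-page
#' TIFF. Crops that extend past the volume border are clipped and flagged.
#'
#' @param v A [volume_image()].
#' @param instances List of `spine_instance` objects.
#' @param records Matching per-spine table (for centroids).
#' @param crop_size_um Cube side length (um).
#' @param path_prefix If given, writes `<prefix>_spine_montage.ppm` and
#'   `<prefix>_spine_crops.tif`.
#' @param channel Channel to crop.
#' @return List with `crops` (list of 3-D arrays), `clipped` (logical
#'   vector) and `montage` (RGB array), invisibly when writing.
#' @export
spine_crop_array <- function(v, instances, records, crop_size_um = 2,
                             path_prefix = NULL, channel = 1L) {
  stopifnot(inherits(v, "volume_image"))
  d <- dim(v$voxels)[2:4]
  sp <- v$spacing
  half <- ceiling(crop_size_um / 2 / sp)
  arr <- array(v$voxels[channel, , , ], d)
  n <- length(instances)
  crops <- vector("list", n)
  clipped <- logical(n)
  for (k in seq_len(n)) {
    cz <- c(records$centroid_z_um[k], records$centroid_y_um[k],
            records$centroid_x_um[k]) / sp
    c0 <- round(cz)
    lo <- c0 - half
    hi <- c0 + half
    clipped[k] <- any(lo < 0) || any(hi > d - 1)
    lo <- pmax(lo, 0); hi <- pmin(hi, d - 1)
    crops[[k]] <- arr[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                      (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  }
  tile_h <- 2L * max(half[2L], 1L) + 1L
  tile_w <- 2L * max(half[3L], 1L) + 1L
  ncol_m <- max(1L, ceiling(sqrt(max(n, 1L))))
  nrow_m <- max(1L, ceiling(max(n, 1L) / ncol_m))
  mont <- array(0, c(nrow_m * tile_h, ncol_m * tile_w, 3L))
  rng <- range(arr)
  for (k in seq_len(n)) {
    mipc <- apply(crops[[k]], c(2L, 3L), max)
    g <- if (diff(rng) > 0) (mipc - rng[1L]) / diff(rng) else mipc * 0
    r0 <- ((k - 1L) %/% ncol_m) * tile_h
    c0 <- ((k - 1L) %% ncol_m) * tile_w
    for (ch in 1:3) {
      mont[r0 + seq_len(nrow(g)), c0 + seq_len(ncol(g)), ch] <- g
    }
  }
  out <- list(crops = crops, clipped = clipped, montage = mont)
  if (!is.null(path_prefix)) {
    write_ppm(mont, paste0(path_prefix, "_spine_montage.ppm"))
    if (n > 0L) {
      pages <- unlist(lapply(crops, function(cr) {
        lapply(seq_len(dim(cr)[1L]), function(z) array(cr[z, , ], dim(cr)[2:3]))
      }), recursive = FALSE)
      write_tiff_pages(pages, paste0(path_prefix, "_spine_crops.tif"))
    }
    return(invisible(out))
  }
  out
}
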