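# Minimal baseline TIFF codec. The analysis exchanges multi-page grayscale
# TIFF volumes with external segmenters; no TIFF package is available in the
# target environment, so uncompressed strip-based baseline TIFF is implemented
# directly. Supported: uint8/uint16/float32 (and int16/int32 on read), single
# sample per pixel, compression "none", both byte orders on read,
# little-endian on write. That covers the files this package writes and the
# typical raw/label exports of microscopy pipelines; anything fancier should
# be converted externally (e.g. via Bio-Formats or tifffile).

u16_raw <- function(x) {
  x <- as.integer(round(x))
  as.raw(as.vector(rbind(x %% 256L, x %/% 256L)))
}

u32_raw <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; x <- x %/% 256
  b3 <- x %% 256
  as.raw(as.vector(rbind(b0, b1, b2, b3)))
}

rd_u16 <- function(raw, off, n = 1L, endian = "little") {
  b <- as.integer(raw[off + seq_len(2L * n)])
  lo <- b[seq(1L, 2L * n, by = 2L)]
  hi <- b[seq(2L, 2L * n, by = 2L)]
  if (endian == "little") lo + 256L * hi else hi + 256L * lo
}

rd_u32 <- function(raw, off, n = 1L, endian = "little") {
  b <- as.numeric(raw[off + seq_len(4L * n)])
  m <- matrix(b, nrow = 4L)
  if (endian == "little") m[1, ] + 256 * m[2, ] + 65536 * m[3, ] + 16777216 * m[4, ]
  else m[4, ] + 256 * m[3, ] + 65536 * m[2, ] + 16777216 * m[1, ]
}

# one IFD entry; value must fit in 4 bytes (always true for the tags we write)
tiff_entry <- function(tag, type, count, value) {
  val <- if (type == 3L) c(u16_raw(value), as.raw(c(0, 0))) else u32_raw(value)
  c(u16_raw(tag), u16_raw(type), u32_raw(count), val[1:4])
}

#' @keywords internal
#' @noRd
write_tiff_pages <- function(pages, path, type = c("auto", "uint8", "uint16", "float32")) {
  type <- match.arg(type)
  if (!is.list(pages) || length(pages) == 0L) stop_arg("pages must be a non-empty list of matrices")
  vals <- unlist(lapply(pages, as.numeric), use.names = FALSE)
  if (type == "auto") {
    if (all(vals == round(vals)) && all(vals >= 0) && all(vals <= 65535)) {
      type <- if (all(vals <= 255)) "uint8" else "uint16"
    } else {
      type <- "float32"
    }
  }
  bits <- switch(type, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- if (type == "float32") 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  # header; offset of the first IFD is patched in after writing page data
  writeBin(charToRaw("II"), con)
  writeBin(u16_raw(42L), con)
  n <- length(pages)
  data_off <- numeric(n)
  nbytes <- numeric(n)
  dims <- lapply(pages, dim)
  pos <- 8
  for (p in seq_len(n)) {
    d <- dims[[p]]
    if (is.null(d) || length(d) != 2L) stop_arg("each page must be a 2-D matrix [y, x]")
    nbytes[p] <- prod(d) * (bits / 8L)
    data_off[p] <- pos
    pos <- pos + nbytes[p]
  }
  ifd_size <- 2 + 10 * 12 + 4
  ifd_off <- data_off[n] + nbytes[n] + (seq_len(n) - 1) * ifd_size
  writeBin(u32_raw(ifd_off[1]), con)
  for (p in seq_len(n)) {
    m <- pages[[p]]
    v <- as.numeric(t(m)) # row-major: x fastest within each row y
    bytes <- switch(type,
      uint8 = as.raw(as.integer(round(v))),
      uint16 = u16_raw(v),
      float32 = writeBin(v, raw(), size = 4L, endian = "little"))
    writeBin(bytes, con)
  }
  for (p in seq_len(n)) {
    d <- dims[[p]]
    ifd <- c(
      u16_raw(10L),
      tiff_entry(256L, 4L, 1L, d[2L]),          # ImageWidth
      tiff_entry(257L, 4L, 1L, d[1L]),          # ImageLength
      tiff_entry(258L, 3L, 1L, bits),           # BitsPerSample
      tiff_entry(259L, 3L, 1L, 1L),             # Compression: none
      tiff_entry(262L, 3L, 1L, 1L),             # Photometric: BlackIsZero
      tiff_entry(273L, 4L, 1L, data_off[p]),    # StripOffsets
      tiff_entry(277L, 3L, 1L, 1L),             # SamplesPerPixel
      tiff_entry(278L, 4L, 1L, d[1L]),          # RowsPerStrip
      tiff_entry(279L, 4L, 1L, nbytes[p]),      # StripByteCounts
      tiff_entry(339L, 3L, 1L, fmt),            # SampleFormat
      u32_raw(if (p < length(pages)) ifd_off[p + 1L] else 0)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}

read_tag_values <- function(raw, entry_off, endian) {
  type <- rd_u16(raw, entry_off + 2L, endian = endian)
  count <- rd_u32(raw, entry_off + 4L, endian = endian)
  size <- switch(as.character(type), `1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                 `6` = 1L, `8` = 2L, `9` = 4L, `11` = 4L, `12` = 8L, 4L)
  total <- size * count
  voff <- if (total <= 4) entry_off + 8L else rd_u32(raw, entry_off + 8L, endian = endian)
  if (type == 3L) rd_u16(raw, voff, count, endian)
  else if (type %in% c(1L, 2L, 6L)) as.numeric(raw[voff + seq_len(count)])
  else rd_u32(raw, voff, count, endian)
}

#' @keywords internal
#' @noRd
read_tiff_pages <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("cannot read TIFF (truncated): ", path, call. = FALSE)
  order_tag <- rawToChar(raw[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big" else
    stop("cannot read TIFF (bad byte-order mark): ", path, call. = FALSE)
  if (rd_u16(raw, 2L, endian = endian) != 42L)
    stop("cannot read TIFF (bad magic): ", path, call. = FALSE)
  ifd_off <- rd_u32(raw, 4L, endian = endian)
  pages <- list()
  while (ifd_off != 0) {
    if (ifd_off + 2L > length(raw)) stop("cannot read TIFF (truncated IFD): ", path, call. = FALSE)
    n_entries <- rd_u16(raw, ifd_off, endian = endian)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd_u16(raw, eo, endian = endian)
      tags[[as.character(tag)]] <- read_tag_values(raw, eo, endian)
    }
    width <- tags[["256"]]
    height <- tags[["257"]]
    if (is.null(width) || is.null(height))
      stop("cannot read TIFF (missing dimensions): ", path, call. = FALSE)
    bits <- (tags[["258"]] %||% 1L)[1L]
    comp <- (tags[["259"]] %||% 1L)[1L]
    fmt <- (tags[["339"]] %||% 1L)[1L]
    spp <- (tags[["277"]] %||% 1L)[1L]
    if (comp != 1L)
      stop("cannot read TIFF (compressed data unsupported): ", path, call. = FALSE)
    if (spp != 1L)
      stop("cannot read TIFF (multi-sample pixels unsupported; split channels to pages): ",
           path, call. = FALSE)
    offs <- tags[["273"]]
    counts <- tags[["279"]]
    if (is.null(offs) || is.null(counts))
      stop("cannot read TIFF (missing strip layout): ", path, call. = FALSE)
    if (max(offs + counts) > length(raw))
      stop("cannot read TIFF (truncated strips): ", path, call. = FALSE)
    bytes <- raw[unlist(lapply(seq_along(offs),
                               function(i) offs[i] + seq_len(counts[i])))]
    npix <- width * height
    vals <- if (bits == 8L && fmt == 1L) {
      as.numeric(bytes[seq_len(npix)])
    } else if (bits == 16L && fmt == 1L) {
      rd_u16(bytes, 0L, npix, endian)
    } else if (bits == 16L && fmt == 2L) {
      readBin(bytes, "integer", n = npix, size = 2L, signed = TRUE, endian = endian)
    } else if (bits == 32L && fmt == 3L) {
      readBin(bytes, "double", n = npix, size = 4L, endian = endian)
    } else if (bits == 32L && fmt %in% c(1L, 2L)) {
      readBin(bytes, "integer", n = npix, size = 4L, endian = endian)
    } else {
      stop("cannot read TIFF (unsupported pixel type ", bits, "-bit format ", fmt, "): ",
           path, call. = FALSE)
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = width)) # -> [y, x]
    ifd_off <- rd_u32(raw, ifd_off + 2L + n_entries * 12L, endian = endian)
  }
  if (length(pages) == 0L) stop("cannot read TIFF (no pages): ", path, call. = FALSE)
  pages
}
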