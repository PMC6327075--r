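#' @name tiff-io
#' @title Minimal baseline TIFF reader and writer
#'
#' @description
#' The package carries its own reader/writer for uncompressed baseline TIFF
#' because no image-IO package is assumed to be available at run time.
#' Supported on read: little- and big-endian files, 8- or 16-bit samples,
#' 1 (grayscale) or 3 (RGB) samples per pixel, chunky planar layout, any
#' strip arrangement, multi-page files. Written files are little-endian,
#' single-strip, one IFD per page.
#'
#' Pixel values are returned as numeric matrices (grayscale) or
#' height x width x 3 arrays (RGB), unscaled.
NULL

# ---- little helpers on raw vectors ----------------------------------------

.u16 <- function(bytes, off, le) {
  b <- as.integer(bytes[off + 1:2])
  if (le) b[1] + 256 * b[2] else b[2] + 256 * b[1]
}

.u32 <- function(bytes, off, le) {
  b <- as.numeric(as.integer(bytes[off + 1:4]))
  if (!le) b <- rev(b)
  b[1] + 256 * (b[2] + 256 * (b[3] + 256 * b[4]))
}

.le16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}

.le32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

# TIFF type sizes: 1 BYTE, 2 ASCII, 3 SHORT, 4 LONG, 5 RATIONAL
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L)

# Read `count` unsigned integers of TIFF `type` for one IFD entry, resolving
# the inline-vs-offset rule (values <= 4 bytes are stored in the entry).
.tag_values <- function(bytes, entry_off, type, count, le) {
  size <- .tiff_type_size[type]
  total <- size * count
  base <- if (total <= 4) entry_off + 8 else .u32(bytes, entry_off + 8, le)
  vapply(seq_len(count) - 1L, function(i) {
    if (size == 1L) as.numeric(as.integer(bytes[base + i + 1]))
    else if (size == 2L) as.numeric(.u16(bytes, base + 2 * i, le))
    else .u32(bytes, base + 4 * i, le)
  }, numeric(1))
}

# ---- reader ----------------------------------------------------------------

#' Read an uncompressed TIFF file
#'
#' @param path path to a TIFF file.
#' @return A list with one element per page; each element is a numeric
#'   `height x width` matrix (1 sample/pixel) or a `height x width x 3`
#'   array (RGB).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read TIFF: file does not exist: ", path)
  }
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 8) stop("not a TIFF file (too short): ", path)
  order_tag <- rawToChar(bytes[1:2])
  le <- order_tag == "II"
  if (!le && order_tag != "MM") stop("not a TIFF file (bad byte order mark): ", path)
  if (.u16(bytes, 2, le) != 42) stop("not a TIFF file (bad magic): ", path)

  pages <- list()
  ifd_off <- .u32(bytes, 4, le)
  while (ifd_off != 0) {
    n_entries <- .u16(bytes, ifd_off, le)
    tags <- list()
    for (k in seq_len(n_entries)) {
      eoff <- ifd_off + 2 + 12 * (k - 1)
      tag <- .u16(bytes, eoff, le)
      type <- .u16(bytes, eoff + 2, le)
      count <- .u32(bytes, eoff + 4, le)
      if (type >= 1 && type <= 5) {
        tags[[as.character(tag)]] <- .tag_values(bytes, eoff, type, count, le)
      }
    }
    pages[[length(pages) + 1L]] <- .decode_tiff_page(bytes, tags, le, path)
    ifd_off <- .u32(bytes, ifd_off + 2 + 12 * n_entries, le)
  }
  if (length(pages) == 0) stop("TIFF file contains no pages: ", path)
  pages
}

.decode_tiff_page <- function(bytes, tags, le, path) {
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF page missing required tag ", tag, ": ", path)
      default
    } else v
  }
  width <- need(256)
  height <- need(257)
  spp <- need(277, default = 1)
  bits <- need(258, default = rep(8, spp))
  compression <- need(259, default = 1)
  planar <- need(284, default = 1)
  if (compression != 1) {
    stop("unsupported TIFF compression (", compression, "); only uncompressed is supported: ", path)
  }
  if (planar != 1) stop("unsupported TIFF planar configuration: ", path)
  if (!spp %in% c(1, 3)) {
    stop("unsupported TIFF channel count ", spp, " (expected 1 or 3): ", path)
  }
  if (length(unique(bits)) != 1 || !bits[1] %in% c(8, 16)) {
    stop("unsupported TIFF bit depth (", paste(bits, collapse = ","), "): ", path)
  }
  bits <- bits[1]

  strip_offsets <- need(273)
  strip_counts <- need(279)
  payload <- raw(0)
  for (s in seq_along(strip_offsets)) {
    payload <- c(payload, bytes[strip_offsets[s] + seq_len(strip_counts[s])])
  }
  n_samples <- width * height * spp
  if (bits == 8) {
    vals <- as.numeric(as.integer(payload[seq_len(n_samples)]))
  } else {
    lo_first <- le
    idx <- seq_len(n_samples)
    b1 <- as.numeric(as.integer(payload[2 * idx - 1]))
    b2 <- as.numeric(as.integer(payload[2 * idx]))
    vals <- if (lo_first) b1 + 256 * b2 else b2 + 256 * b1
  }
  # TIFF stores rows sequentially with samples interleaved
  if (spp == 1) {
    matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  } else {
    a <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      a[, , ch] <- matrix(vals[seq(ch, n_samples, by = 3)],
                          nrow = height, ncol = width, byrow = TRUE)
    }
    a
  }
}

# ---- writer ----------------------------------------------------------------

#' Write an uncompressed TIFF file
#'
#' @param pages a single matrix/array or a list of them. Matrices are written
#'   as grayscale pages; `height x width x 3` arrays as RGB pages. All values
#'   must be integers representable at the chosen bit depth.
#' @param path output path.
#' @param bits sample bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, bits = 8L) {
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0) stop("write_tiff: no pages to write")
  if (!bits %in% c(8L, 16L)) stop("write_tiff: bits must be 8 or 16")
  maxval <- 2^bits - 1

  chunks <- list(c(charToRaw("II"), .le16(42), .le32(8)))
  pos <- 8  # running byte offset of the next chunk
  pending_next_field <- NULL  # (chunk idx, byte offset within chunk) to patch

  for (p in seq_along(pages)) {
    img <- pages[[p]]
    if (is.matrix(img)) {
      spp <- 1L; height <- nrow(img); width <- ncol(img)
      vals <- as.vector(t(img))
    } else if (is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3) {
      spp <- 3L; height <- dim(img)[1]; width <- dim(img)[2]
      vals <- numeric(height * width * 3)
      for (ch in 1:3) vals[seq(ch, length(vals), by = 3)] <- as.vector(t(img[, , ch]))
    } else {
      stop("write_tiff: page ", p, " is neither a matrix nor an HxWx3 array")
    }
    if (any(!is.finite(vals)) || any(vals < 0) || any(vals > maxval) ||
        any(vals != round(vals))) {
      stop("write_tiff: page ", p, " has values outside integer range [0, ", maxval, "]")
    }

    if (bits == 8L) {
      pix <- as.raw(vals)
    } else {
      pix <- raw(2 * length(vals))
      pix[c(TRUE, FALSE)] <- as.raw(vals %% 256)
      pix[c(FALSE, TRUE)] <- as.raw(vals %/% 256)
    }

    extra <- raw(0)
    if (spp == 3L) {
      # BitsPerSample needs 3 shorts = 6 bytes -> stored out of line
      extra <- c(.le16(bits), .le16(bits), .le16(bits))
      bps_offset <- pos
      pos <- pos + length(extra)
    }
    strip_offset <- pos
    pad <- raw(length(pix) %% 2)  # keep IFD offsets word-aligned
    pos <- pos + length(pix) + length(pad)

    entry <- function(tag, type, count, value) {
      val_bytes <- if (type == 3 && count == 1) c(.le16(value), .le16(0)) else .le32(value)
      c(.le16(tag), .le16(type), .le32(count), val_bytes)
    }
    entries <- list(
      entry(256, 4, 1, width),
      entry(257, 4, 1, height),
      if (spp == 1L) entry(258, 3, 1, bits) else entry(258, 3, 3, bps_offset),
      entry(259, 3, 1, 1),                       # uncompressed
      entry(262, 3, 1, if (spp == 1L) 1 else 2), # BlackIsZero / RGB
      entry(273, 4, 1, strip_offset),
      entry(277, 3, 1, spp),
      entry(278, 4, 1, height),
      entry(279, 4, 1, length(pix)),
      entry(284, 3, 1, 1)                        # chunky
    )
    ifd <- c(.le16(length(entries)), do.call(c, entries), .le32(0))
    ifd_offset <- pos
    pos <- pos + length(ifd)

    # patch the previous IFD-chain pointer (or the header) to this IFD
    if (is.null(pending_next_field)) {
      chunks[[1]][5:8] <- .le32(ifd_offset)
    } else {
      ci <- pending_next_field[[1]]; at <- pending_next_field[[2]]
      chunks[[ci]][at + 1:4] <- .le32(ifd_offset)
    }
    page_chunk <- c(extra, pix, pad, ifd)
    chunks[[length(chunks) + 1L]] <- page_chunk
    pending_next_field <- list(length(chunks), length(page_chunk) - 4L)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  for (ch in chunks) writeBin(ch, con)
  invisible(path)
}
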