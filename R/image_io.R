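#' @name image-io
#' @title Reading confocal frame sequences
#'
#' @description
#' Confocal exports of undyed grayscale movies are commonly stored as RGB
#' images whose three channels are identical copies of the gray signal,
#' with intensities in \[0, 254\]. These readers collapse such storage back
#' to a single-channel frame without rescaling. Coordinates throughout the
#' package are 1-based (row, col); row increases downward.
NULL

#' Construct a grayscale frame
#'
#' @param pixels numeric matrix of intensities.
#' @param frame_index 1-based position of the frame in its sequence.
#' @return A `grayscale_frame` object: list with `pixels`, `frame_index`,
#'   `height`, `width`.
#' @export
grayscale_frame <- function(pixels, frame_index = 1L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("pixels must be a numeric matrix")
  }
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("frame must be at least 1x1")
  if (any(!is.finite(pixels))) stop("frame contains non-finite intensities")
  if (any(pixels < 0)) stop("frame contains negative intensities")
  structure(
    list(pixels = pixels, frame_index = as.integer(frame_index),
         height = nrow(pixels), width = ncol(pixels)),
    class = "grayscale_frame"
  )
}

#' @export
print.grayscale_frame <- function(x, ...) {
  cat(sprintf("<grayscale_frame #%d: %d x %d, intensity [%g, %g]>\n",
              x$frame_index, x$height, x$width,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read one frame from a TIFF file
#'
#' For 3-channel (RGB) storage the first channel is taken; a warning is
#' emitted if the channels are not identical, since genuinely colored input
#' indicates the file is not a grayscale confocal export. Intensities are
#' preserved without rescaling (8- and 16-bit input both accepted).
#'
#' @param path path to a single-page TIFF file.
#' @param frame_index frame index to record on the returned frame.
#' @return A [grayscale_frame()].
#' @export
read_frame <- function(path, frame_index = 1L) {
  pages <- read_tiff(path)
  if (length(pages) > 1) {
    stop("read_frame expects a single-page image; got ", length(pages),
         " pages in ", path, " (use read_sequence for stacks)")
  }
  grayscale_frame(.collapse_channels(pages[[1]], path), frame_index)
}

.collapse_channels <- function(img, origin) {
  if (is.matrix(img)) return(img)
  if (!identical(img[, , 1], img[, , 2]) || !identical(img[, , 1], img[, , 3])) {
    warning("RGB channels differ in ", origin,
            "; taking channel 1 (input may not be a grayscale export)")
  }
  img[, , 1]
}

#' Read an ordered frame sequence
#'
#' @param source either a directory containing numbered single-page TIFF
#'   files, or the path of one multi-page TIFF stack.
#' @param pattern filename glob used when `source` is a directory.
#' @return List of [grayscale_frame()] with `frame_index` 1..N in ascending
#'   frame order. Directory entries are ordered by natural numeric sort of
#'   their filenames (`f2` before `f10`), never lexicographically, because a
#'   lexicographic order silently scrambles time.
#' @export
read_sequence <- function(source, pattern = "*.tif*") {
  if (dir.exists(source)) {
    files <- Sys.glob(file.path(source, pattern))
    if (length(files) == 0) {
      stop("empty sequence: no files matching '", pattern, "' in ", source)
    }
    files <- files[natural_order(basename(files))]
    frames <- vector("list", length(files))
    for (i in seq_along(files)) {
      pages <- read_tiff(files[i])
      if (length(pages) != 1) {
        stop("sequence member is multi-page: ", files[i])
      }
      frames[[i]] <- grayscale_frame(.collapse_channels(pages[[1]], files[i]), i)
    }
  } else if (file.exists(source)) {
    pages <- read_tiff(source)
    frames <- vector("list", length(pages))
    for (i in seq_along(pages)) {
      frames[[i]] <- grayscale_frame(.collapse_channels(pages[[i]], source), i)
    }
  } else {
    stop("cannot read sequence: ", source, " does not exist")
  }
  dims <- vapply(frames, function(f) c(f$height, f$width), integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad) > 0) {
    stop(sprintf("frame %d is %dx%d but frame 1 is %dx%d: inconsistent dimensions",
                 bad[1], dims[1, bad[1]], dims[2, bad[1]], dims[1, 1], dims[2, 1]))
  }
  frames
}

#' Natural (numeric-aware) filename ordering
#'
#' @param x character vector of file names.
#' @return Integer permutation ordering `x` so embedded integers compare
#'   numerically: `f2.tif` sorts before `f10.tif`.
#' @export
natural_order <- function(x) {
  # compare name prefix lexicographically, then the first embedded number
  prefix <- sub("[0-9].*$", "", x)
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*([0-9]+).*$", "\\1", x)))
  num[is.na(num)] <- -Inf
  order(prefix, num, x)
}

#' Write a frame sequence as TIFF
#'
#' @param frames list of [grayscale_frame()] or plain matrices.
#' @param path output path: a directory (one numbered file per frame) or a
#'   `.tif` filename (one multi-page stack).
#' @param bits sample depth, 8 or 16.
#' @return The written path(s), invisibly.
#' @export
write_sequence <- function(frames, path, bits = 8L) {
  mats <- lapply(frames, function(f) {
    m <- if (inherits(f, "grayscale_frame")) f$pixels else f
    round(m)
  })
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    write_tiff(mats, path, bits = bits)
    invisible(path)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    files <- file.path(path, sprintf("frame_%04d.tif", seq_along(mats)))
    for (i in seq_along(mats)) write_tiff(mats[[i]], files[i], bits = bits)
    invisible(files)
  }
}
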