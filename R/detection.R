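#' @name detection
#' @title Per-frame vesicle detection
#'
#' @description
#' Vesicles appear as point-like bright spots of roughly uniform size on a
#' dark, noisy background. Detection proceeds per frame:
#' Laplacian-of-Gaussian (LOG) filtering (sign-flipped so bright blobs give
#' large positive responses), affine normalization of the response to
#' \[0, 1\], thresholding at `response_lower_bound`, connected-component
#' labeling of the foreground, a minimum blob-size filter against
#' noise-born specks, and the unweighted pixel-coordinate centroid of each
#' surviving blob as the vesicle position. The LOG zero-crossing separates
#' vesicles that are close to each other, so no watershed step is needed.
NULL

#' Detection parameters
#'
#' @param log_sigma Gaussian scale of the LOG kernel, in pixels. Should match
#'   the apparent spot radius; default 2 px for spots a few pixels across.
#' @param log_kernel_size odd kernel side length; default `2*ceiling(3*sigma)+1`
#'   captures the kernel's support to ~3 sigma.
#' @param response_lower_bound threshold on the normalized LOG response in
#'   \[0, 1\]; pixels with response `>=` the bound become foreground. In
#'   practice calibrated by eye against a threshold sweep (see
#'   [cmd_threshold_sweep()]).
#' @param min_blob_size minimum pixel count of an accepted blob, approximately
#'   the area of the smallest true vesicle; smaller blobs are treated as noise.
#' @param connectivity neighbor rule for labeling, 4 or 8. Default 8: the rim
#'   of a round LOG response is often only diagonally connected.
#' @return A `detection_params` object.
#' @export
detection_params <- function(log_sigma = 2,
                             log_kernel_size = 2 * ceiling(3 * log_sigma) + 1,
                             response_lower_bound = 0.5,
                             min_blob_size = 4L,
                             connectivity = 8L) {
  if (!is.numeric(log_sigma) || log_sigma <= 0) stop("log_sigma must be > 0")
  if (log_kernel_size < 3 || log_kernel_size %% 2 != 1) {
    stop("log_kernel_size must be odd and >= 3")
  }
  if (response_lower_bound < 0 || response_lower_bound > 1) {
    stop("response_lower_bound must be in [0, 1]")
  }
  if (min_blob_size < 1) stop("min_blob_size must be >= 1")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(
    list(log_sigma = log_sigma,
         log_kernel_size = as.integer(log_kernel_size),
         response_lower_bound = response_lower_bound,
         min_blob_size = as.integer(min_blob_size),
         connectivity = as.integer(connectivity)),
    class = "detection_params"
  )
}

#' Build the (negated) Laplacian-of-Gaussian kernel
#'
#' The analytic LOG is negative at its center; the returned kernel is
#' sign-flipped so convolution with a bright spot yields a positive peak,
#' and mean-subtracted so it sums exactly to zero (a constant image maps to
#' an identically zero response).
#'
#' @param sigma Gaussian scale in pixels.
#' @param size odd kernel side length.
#' @return `size x size` numeric matrix summing to 0.
#' @export
log_kernel <- function(sigma, size = 2 * ceiling(3 * sigma) + 1) {
  if (size %% 2 != 1) stop("kernel size must be odd")
  half <- (size - 1) / 2
  g <- expand.grid(x = -half:half, y = -half:half)
  r2 <- g$x^2 + g$y^2
  k <- (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2)) / (pi * sigma^4)
  k <- matrix(k, size, size)
  k - mean(k)
}

#' 2-D convolution with edge-replication padding
#'
#' Direct convolution implemented as a sum over kernel taps of shifted image
#' slices; edge replication avoids the spurious border responses that
#' zero-padding creates.
#'
#' @param img numeric matrix.
#' @param kernel odd-sized numeric matrix.
#' @return Matrix of `dim(img)`.
#' @export
convolve2d_replicate <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  if (kh %% 2 != 1 || kw %% 2 != 1) stop("kernel dimensions must be odd")
  ph <- (kh - 1) / 2; pw <- (kw - 1) / 2
  h <- nrow(img); w <- ncol(img)
  ridx <- pmin(pmax(seq(1 - ph, h + ph), 1), h)
  cidx <- pmin(pmax(seq(1 - pw, w + pw), 1), w)
  padded <- img[ridx, cidx, drop = FALSE]
  out <- matrix(0, h, w)
  for (a in seq_len(kh)) {
    for (b in seq_len(kw)) {
      if (kernel[a, b] != 0) {
        out <- out + kernel[a, b] * padded[a:(a + h - 1), b:(b + w - 1), drop = FALSE]
      }
    }
  }
  out
}

#' Apply the LOG filter to a frame
#'
#' @param frame a [grayscale_frame()] or numeric matrix.
#' @param params a [detection_params()].
#' @return Numeric response matrix, large and positive on bright point-like
#'   features.
#' @export
log_filter <- function(frame, params = detection_params()) {
  img <- if (inherits(frame, "grayscale_frame")) frame$pixels else frame
  k <- params$log_kernel_size
  if (nrow(img) < k || ncol(img) < k) {
    stop(sprintf("frame (%dx%d) is smaller than the LOG kernel (%dx%d)",
                 nrow(img), ncol(img), k, k))
  }
  convolve2d_replicate(img, log_kernel(params$log_sigma, k))
}

#' Normalize a filter response onto [0, 1]
#'
#' Affine map of `[min, max]` onto `[0, 1]`; the ordering of pixel values is
#' preserved.
#'
#' @param response numeric matrix.
#' @return Matrix with values in \[0, 1\].
#' @export
normalize_response <- function(response) {
  lo <- min(response); hi <- max(response)
  if (hi == lo) {
    stop("degenerate response: all pixels equal (no vesicles detectable)")
  }
  (response - lo) / (hi - lo)
}

#' Threshold a normalized response
#'
#' @param normalized matrix with values in \[0, 1\].
#' @param lower_bound threshold; pixels with value `>=` the bound map to 1.
#'   The comparison is `>=` (fixed, documented: the boundary pixel belongs to
#'   the foreground).
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(normalized, lower_bound) {
  if (min(normalized) < 0 || max(normalized) > 1) {
    stop("binarize expects values in [0, 1]; call normalize_response first")
  }
  out <- matrix(0L, nrow(normalized), ncol(normalized))
  out[normalized >= lower_bound] <- 1L
  out
}

#' Label connected foreground blobs
#'
#' Iterative frontier flood fill (no recursion, so arbitrarily large blobs
#' cannot exhaust the stack), with output identical to the recursive
#' formulation. Seeds are scanned in row-major order so blob discovery order
#' is deterministic.
#'
#' @param binary integer 0/1 matrix.
#' @param connectivity 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
#' @return List of blobs; each blob is a list with `pixels` (n x 2 matrix of
#'   1-based (row, col)), `size`, and `centroid` (length-2 numeric,
#'   unweighted mean of pixel coordinates).
#' @export
find_blobs <- function(binary, connectivity = 8L) {
  if (!all(binary %in% c(0L, 1L))) {
    stop("find_blobs expects a binary (0/1) image")
  }
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  h <- nrow(binary); w <- ncol(binary)
  fg <- binary == 1L
  labels <- matrix(0L, h, w)
  # row-major seed scan: order linear (column-major) indices by (row, col)
  fg_lin <- which(fg)
  if (length(fg_lin) == 0) return(list())
  fg_row <- (fg_lin - 1L) %% h + 1L
  fg_col <- (fg_lin - 1L) %/% h + 1L
  seeds <- fg_lin[order(fg_row, fg_col)]

  dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  if (connectivity == 8L) {
    dr <- c(dr, -1L, -1L, 1L, 1L); dc <- c(dc, -1L, 1L, -1L, 1L)
  }

  blobs <- list()
  next_label <- 0L
  for (s in seeds) {
    if (labels[s] != 0L) next
    next_label <- next_label + 1L
    labels[s] <- next_label
    members <- s
    frontier <- s
    while (length(frontier) > 0) {
      fr <- (frontier - 1L) %% h + 1L
      fc <- (frontier - 1L) %/% h + 1L
      cand_r <- rep(fr, times = length(dr)) + rep(dr, each = length(fr))
      cand_c <- rep(fc, times = length(dc)) + rep(dc, each = length(fc))
      ok <- cand_r >= 1L & cand_r <= h & cand_c >= 1L & cand_c <= w
      cand <- unique((cand_c[ok] - 1L) * h + cand_r[ok])
      cand <- cand[fg[cand] & labels[cand] == 0L]
      labels[cand] <- next_label
      members <- c(members, cand)
      frontier <- cand
    }
    rows <- (members - 1L) %% h + 1L
    cols <- (members - 1L) %/% h + 1L
    ord <- order(rows, cols)
    blobs[[next_label]] <- list(
      pixels = cbind(row = rows[ord], col = cols[ord]),
      size = length(members),
      centroid = c(mean(rows), mean(cols))
    )
  }
  blobs
}

#' Size-filter blobs and collect centroids into a detection set
#'
#' @param blobs list of blobs from [find_blobs()].
#' @param min_blob_size blobs with fewer pixels are discarded as noise.
#' @param frame_index 1-based frame number recorded on the result.
#' @return A `detection_set`: list with `frame_index`, `positions` (K x 2
#'   matrix of (row, col) centroids; vesicle index = row number, 1-based and
#'   dense in blob discovery order), and `sizes` (integer K-vector).
#' @export
filter_and_centroid <- function(blobs, min_blob_size = 1L, frame_index = 1L) {
  keep <- vapply(blobs, function(b) b$size >= min_blob_size, logical(1))
  kept <- blobs[keep]
  positions <- if (length(kept) == 0) {
    matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  } else {
    m <- t(vapply(kept, function(b) b$centroid, numeric(2)))
    colnames(m) <- c("row", "col")
    m
  }
  structure(
    list(frame_index = as.integer(frame_index),
         positions = positions,
         sizes = vapply(kept, function(b) as.integer(b$size), integer(1))),
    class = "detection_set"
  )
}

#' @export
print.detection_set <- function(x, ...) {
  cat(sprintf("<detection_set frame %d: %d vesicles>\n",
              x$frame_index, nrow(x$positions)))
  invisible(x)
}

#' Number of detections in a detection set
#' @param d a `detection_set`.
#' @return Integer count.
#' @export
n_detections <- function(d) nrow(d$positions)

#' Detect vesicles in one frame
#'
#' Full per-frame pipeline: LOG filter, normalization, threshold, labeling,
#' size filter, centroids. A constant frame (nothing to normalize) yields an
#' empty detection set with a warning rather than an error, so a dark frame
#' does not abort a batch run.
#'
#' @param frame a [grayscale_frame()] or numeric matrix.
#' @param params a [detection_params()].
#' @return A `detection_set` for the frame.
#' @export
detect_frame <- function(frame, params = detection_params()) {
  fidx <- if (inherits(frame, "grayscale_frame")) frame$frame_index else 1L
  response <- log_filter(frame, params)
  if (max(response) == min(response)) {
    warning("frame ", fidx, " is constant; returning 0 detections")
    return(filter_and_centroid(list(), params$min_blob_size, fidx))
  }
  normalized <- normalize_response(response)
  bw <- binarize(normalized, params$response_lower_bound)
  blobs <- find_blobs(bw, params$connectivity)
  filter_and_centroid(blobs, params$min_blob_size, fidx)
}

#' Detect vesicles in every frame of a sequence
#'
#' @param frames list of [grayscale_frame()].
#' @param params a [detection_params()].
#' @return List of `detection_set`, one per frame, in frame order.
#' @export
detect_sequence <- function(frames, params = detection_params()) {
  lapply(frames, detect_frame, params = params)
}

#' Write detections to CSV
#'
#' Columns: frame, vesicle_id, row, col, size. Coordinates are 1-based pixel
#' (row, col) with row increasing downward; a comment header records this
#' and the parameters used.
#'
#' @param detections list of `detection_set`.
#' @param path output CSV path.
#' @param params the [detection_params()] used (recorded in the header).
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path, params = NULL) {
  header <- c(
    "# vestrack detections",
    "# coordinates: 1-based pixel (row, col), row increases downward",
    if (!is.null(params)) {
      sprintf("# params: log_sigma=%g kernel=%d lower_bound=%g min_blob_size=%d connectivity=%d",
              params$log_sigma, params$log_kernel_size, params$response_lower_bound,
              params$min_blob_size, params$connectivity)
    }
  )
  rows <- do.call(rbind, lapply(detections, function(d) {
    k <- n_detections(d)
    if (k == 0) return(NULL)
    data.frame(frame = d$frame_index, vesicle_id = seq_len(k),
               row = d$positions[, 1], col = d$positions[, 2],
               size = d$sizes)
  }))
  if (is.null(rows)) {
    rows <- data.frame(frame = integer(0), vesicle_id = integer(0),
                       row = numeric(0), col = numeric(0), size = integer(0))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Read a detections CSV back into detection sets
#'
#' @param path CSV written by [write_detections_csv()].
#' @param n_frames total number of frames in the sequence (frames with zero
#'   detections have no CSV rows, so the count cannot be inferred).
#' @return List of `detection_set` of length `n_frames`.
#' @export
read_detections_csv <- function(path, n_frames = NULL) {
  df <- utils::read.csv(path, comment.char = "#")
  if (is.null(n_frames)) n_frames <- if (nrow(df) == 0) 0L else max(df$frame)
  out <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    sub <- df[df$frame == f, , drop = FALSE]
    sub <- sub[order(sub$vesicle_id), , drop = FALSE]
    pos <- as.matrix(sub[, c("row", "col")])
    dimnames(pos) <- list(NULL, c("row", "col"))
    out[[f]] <- structure(
      list(frame_index = f, positions = pos, sizes = as.integer(sub$size)),
      class = "detection_set"
    )
  }
  out
}
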