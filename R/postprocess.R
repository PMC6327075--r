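#' @name postprocess
#' @title Trajectory matrix and kinematics
#'
#' @description
#' The segment store is convenient for tracing but awkward for analysis, so
#' trajectories are first flattened into the trajectory matrix: rows are
#' trajectories, columns are frames, and entry (t, n) is the index of the
#' vesicle that trajectory t occupies in frame n (0 = absent). Each row's
#' non-zero entries form one contiguous block; its length is the
#' trajectory's life, and a lower bound on life screens out the short-lived
#' tracks that image noise produces.
#'
#' From a trajectory's position sequence \eqn{x(n)} (px) and frame interval
#' \eqn{\Delta t} (s), four kinematic quantities follow:
#' velocity \eqn{v(n)} by finite differences (forward at the first sample,
#' central at interior samples, backward at the last); speed as the
#' Euclidean norm of the velocity; traveling distance \eqn{s(n)} as the
#' cumulative path length; and moving range \eqn{R(n)} as the running
#' maximum displacement from the first position. \eqn{R(n) \le s(n)} always.
NULL

#' Extract the trajectory matrix from a TRJ store
#'
#' @param trj a (trimmed) `trj` store.
#' @return A `trajectory_matrix` object: list with `entries`
#'   (counter x nframe integer matrix of per-frame vesicle indices, 0 when
#'   the trajectory is absent) and `lives` (per-row non-zero count).
#' @export
extract_matrix <- function(trj) {
  M <- matrix(0L, trj$counter, trj$nframe)
  for (id in seq_len(trj$counter)) {
    m <- trj$dat[[id]]
    if (any(duplicated(m[, 1]))) {
      stop("integrity error: trajectory ", id, " has two rows for one frame")
    }
    M[id, m[, 1]] <- m[, 3]
  }
  structure(list(entries = M, lives = as.integer(rowSums(M != 0L))),
            class = "trajectory_matrix")
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat(sprintf("<trajectory_matrix: %d trajectories x %d frames>\n",
              nrow(x$entries), ncol(x$entries)))
  invisible(x)
}

#' Drop short-lived trajectories
#'
#' @param M a [extract_matrix()] result.
#' @param min_life minimum number of frames a trajectory must span; rows
#'   with fewer are removed (order of survivors preserved). Short-lived
#'   trajectories are the typical signature of noise blobs that passed the
#'   size filter in isolated frames.
#' @return A filtered `trajectory_matrix` carrying `source_rows`, the
#'   original row indices of the survivors.
#' @export
filter_by_life <- function(M, min_life = 1L) {
  if (min_life < 1) stop("min_life must be >= 1")
  keep <- which(M$lives >= min_life)
  prev_src <- if (is.null(M$source_rows)) seq_len(nrow(M$entries)) else M$source_rows
  structure(list(entries = M$entries[keep, , drop = FALSE],
                 lives = M$lives[keep],
                 source_rows = prev_src[keep]),
            class = "trajectory_matrix")
}

#' Velocity by finite differences
#'
#' Forward difference at the first sample, central difference at interior
#' samples, backward difference at the last:
#' \deqn{v(1) = (x(2)-x(1))/\Delta t,\quad
#'       v(n) = (x(n+1)-x(n-1))/(2\Delta t),\quad
#'       v(N) = (x(N)-x(N-1))/\Delta t.}
#' All three stencils coincide on uniform motion; the central stencil is
#' exact for quadratic motion at interior samples.
#'
#' @param positions n x 2 matrix of (row, col) positions, px.
#' @param dt frame interval, seconds.
#' @return n x 2 matrix of velocity components, px/s. A single-sample input
#'   is an error; callers handling life-1 trajectories should report null
#'   kinematics instead of calling this.
#' @export
velocity <- function(positions, dt) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (dt <= 0) stop("dt must be > 0")
  if (n < 2) stop("velocity undefined for fewer than 2 positions")
  v <- matrix(NA_real_, n, 2)
  v[1, ] <- (positions[2, ] - positions[1, ]) / dt
  if (n > 2) {
    v[2:(n - 1), ] <- (positions[3:n, , drop = FALSE] -
                       positions[1:(n - 2), , drop = FALSE]) / (2 * dt)
  }
  v[n, ] <- (positions[n, ] - positions[n - 1, ]) / dt
  v
}

#' Speed: the magnitude of the velocity
#'
#' @param v n x 2 velocity matrix, px/s.
#' @return Numeric n-vector of Euclidean norms.
#' @export
speed <- function(v) {
  v <- as.matrix(v)
  sqrt(rowSums(v * v))
}

#' Traveling distance along a trajectory
#'
#' \eqn{s(1) = 0}; \eqn{s(n)} is the sum of consecutive step lengths up to
#' sample n. Non-decreasing by construction.
#'
#' @param positions n x 2 position matrix, px.
#' @return Numeric n-vector, px.
#' @export
traveling_distance <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n == 1) return(0)
  steps <- sqrt(rowSums((positions[-1, , drop = FALSE] -
                         positions[-n, , drop = FALSE])^2))
  c(0, cumsum(steps))
}

#' Moving range (displacement) along a trajectory
#'
#' \eqn{R(1) = 0}; \eqn{R(n)} is the running maximum of
#' \eqn{\|x(i) - x(1)\|} over \eqn{1 < i \le n}. Non-decreasing, and never
#' exceeds the traveling distance.
#'
#' @param positions n x 2 position matrix, px.
#' @return Numeric n-vector, px.
#' @export
moving_range <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n == 1) return(0)
  disp <- sqrt(rowSums((positions - matrix(positions[1, ], n, 2, byrow = TRUE))^2))
  c(0, cummax(disp[-1]))
}

#' Position sequence of one matrix row
#'
#' @param M a `trajectory_matrix`.
#' @param t row index in `M`.
#' @param all_detections list of `detection_set`.
#' @return Data frame frame/row/col over the row's non-zero block.
#' @export
matrix_row_coords <- function(M, t, all_detections) {
  frames <- which(M$entries[t, ] != 0L)
  pos <- matrix(NA_real_, length(frames), 2)
  for (i in seq_along(frames)) {
    f <- frames[i]; v <- M$entries[t, f]
    if (f > length(all_detections) || v > n_detections(all_detections[[f]])) {
      stop("integrity error: matrix row ", t, " references vesicle ", v,
           " in frame ", f)
    }
    pos[i, ] <- all_detections[[f]]$positions[v, ]
  }
  data.frame(frame = frames, row = pos[, 1], col = pos[, 2])
}

#' Per-frame kinematics of every trajectory
#'
#' @param M a `trajectory_matrix` (already life-filtered if desired).
#' @param all_detections list of `detection_set`.
#' @param dt frame interval, seconds.
#' @param pixel_size optional pixel edge length in micrometers; when given,
#'   lengths are additionally reported in micrometers (columns with a
#'   `_um` suffix). Internally everything stays in px.
#' @return Data frame with columns trajectory_id, frame, row, col, vx, vy,
#'   speed, s, R. Life-1 trajectories get NA velocity/speed and zero s, R.
#' @export
compute_kinematics <- function(M, all_detections, dt, pixel_size = NULL) {
  out <- vector("list", nrow(M$entries))
  ids <- if (is.null(M$source_rows)) seq_len(nrow(M$entries)) else M$source_rows
  for (t in seq_len(nrow(M$entries))) {
    cc <- matrix_row_coords(M, t, all_detections)
    pos <- as.matrix(cc[, c("row", "col")])
    n <- nrow(pos)
    if (n >= 2) {
      v <- velocity(pos, dt)
      sp <- speed(v)
    } else {
      v <- matrix(NA_real_, n, 2)
      sp <- rep(NA_real_, n)
    }
    df <- data.frame(trajectory_id = ids[t], frame = cc$frame,
                     row = cc$row, col = cc$col,
                     vx = v[, 1], vy = v[, 2], speed = sp,
                     s = traveling_distance(pos), R = moving_range(pos))
    if (!is.null(pixel_size)) {
      df$speed_um <- df$speed * pixel_size
      df$s_um <- df$s * pixel_size
      df$R_um <- df$R * pixel_size
    }
    out[[t]] <- df
  }
  if (length(out) == 0) {
    return(data.frame(trajectory_id = integer(0), frame = integer(0),
                      row = numeric(0), col = numeric(0), vx = numeric(0),
                      vy = numeric(0), speed = numeric(0), s = numeric(0),
                      R = numeric(0)))
  }
  do.call(rbind, out)
}

#' Per-trajectory movement summary
#'
#' One row per surviving trajectory: life (frames spanned), mean speed
#' (mean of the per-frame speed over the trajectory's life — the magnitude
#' is averaged, not the velocity vector, since the vector mean of an
#' oscillating vesicle is near zero), final moving range and final
#' traveling distance. The population — the number of surviving
#' trajectories — is attached as an attribute and equals `nrow` of the
#' returned table.
#'
#' @param M a `trajectory_matrix`.
#' @param all_detections list of `detection_set`.
#' @param dt frame interval, seconds.
#' @param min_life life filter applied before summarizing.
#' @param pixel_size optional micrometers per pixel (adds `_um` columns).
#' @return Data frame trajectory_id, life, mean_speed, final_range,
#'   final_distance, with attribute `population`.
#' @export
summarize_trajectories <- function(M, all_detections, dt, min_life = 1L,
                                   pixel_size = NULL) {
  Mf <- filter_by_life(M, min_life)
  kin <- compute_kinematics(Mf, all_detections, dt, pixel_size)
  ids <- if (is.null(Mf$source_rows)) seq_len(nrow(Mf$entries)) else Mf$source_rows
  rows <- lapply(seq_len(nrow(Mf$entries)), function(t) {
    sub <- kin[kin$trajectory_id == ids[t], , drop = FALSE]
    data.frame(trajectory_id = ids[t],
               life = Mf$lives[t],
               mean_speed = if (Mf$lives[t] >= 2) mean(sub$speed) else NA_real_,
               final_range = sub$R[nrow(sub)],
               final_distance = sub$s[nrow(sub)])
  })
  res <- if (length(rows) == 0) {
    data.frame(trajectory_id = integer(0), life = integer(0),
               mean_speed = numeric(0), final_range = numeric(0),
               final_distance = numeric(0))
  } else {
    do.call(rbind, rows)
  }
  if (!is.null(pixel_size) && nrow(res) > 0) {
    res$mean_speed_um <- res$mean_speed * pixel_size
    res$final_range_um <- res$final_range * pixel_size
    res$final_distance_um <- res$final_distance * pixel_size
  }
  attr(res, "population") <- nrow(res)
  res
}

#' Write the trajectory matrix as CSV
#'
#' @param M a `trajectory_matrix`.
#' @param path output path. Plain integer matrix, one row per trajectory,
#'   one column per frame, 0 = absent; a comment header records dimensions.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vestrack trajectory matrix (rows = trajectories, cols = frames, 0 = absent)",
               sprintf("# dim=%dx%d", nrow(M$entries), ncol(M$entries))), con)
  utils::write.table(M$entries, con, sep = ",", row.names = FALSE,
                     col.names = paste0("f", seq_len(ncol(M$entries))))
  invisible(path)
}

#' Basic trajectory overlay plot
#'
#' Draws each trajectory's path over the first frame of the movie.
#'
#' @param frames list of [grayscale_frame()] (only the first is drawn);
#'   may be `NULL` for a blank background.
#' @param M a `trajectory_matrix`.
#' @param all_detections list of `detection_set`.
#' @param ... passed to [graphics::lines()].
#' @return Invisibly, `NULL`.
#' @export
plot_trajectories <- function(M, all_detections, frames = NULL, ...) {
  if (!is.null(frames)) {
    img <- frames[[1]]$pixels
    graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(64),
                    axes = FALSE, useRaster = TRUE)
    h <- nrow(img); w <- ncol(img)
    to_xy <- function(pos) cbind((pos[, 2] - 1) / (w - 1), 1 - (pos[, 1] - 1) / (h - 1))
  } else {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "col", ylab = "row")
    to_xy <- function(pos) cbind(pos[, 2], pos[, 1])
  }
  for (t in seq_len(nrow(M$entries))) {
    cc <- matrix_row_coords(M, t, all_detections)
    xy <- to_xy(as.matrix(cc[, c("row", "col")]))
    graphics::lines(xy[, 1], xy[, 2], col = t, ...)
  }
  invisible(NULL)
}
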