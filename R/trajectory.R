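#' @name trajectory
#' @title The compound trajectory store (TRJ) and the tracing loop
#'
#' @description
#' The number of trajectories in a movie is generally not the number of
#' vesicles: trajectories can be complete, incomplete, branched or merged.
#' The store therefore keeps, per trajectory, an ordered list of segment
#' rows `[iframe, pid1, pid2]`, where `iframe` is the current image index
#' and `pid1`/`pid2` are vesicle indices in the previous/current image
#' (0 encodes absence). Indices are per-frame, because the detector numbers
#' vesicles independently in every image.
#'
#' Tracing processes frames in order. Every first-frame detection seeds a
#' trajectory. For each later frame: link the two frames' detections
#' (multi-cutoff), resolve merges among the live tails (trajectories
#' sharing an identical tail are compared by length; only the longest
#' survives, ties to the lowest id), then insert the new segments —
#' extending live trajectories, spawning new ones for begin segments and
#' for the extra arms of branches, and closing those that received an end
#' segment. A final merge resolution and a capacity trim complete the run.
NULL

#' Initialize an empty trajectory store
#'
#' @param expected capacity hint: anticipated number of trajectories. Growth
#'   past the hint is transparent. A practical hint is 4x the per-frame
#'   detection count, since branches inflate the trajectory count.
#' @param nframe number of images the tracing run will cover.
#' @return A `trj` object: list with `counter`, `nframe`, `dat` (list of
#'   3-column matrices `[iframe, pid1, pid2]`), `alive` (logical), `capacity`.
#' @export
trj_init <- function(expected, nframe) {
  if (!is.numeric(expected) || expected < 1) stop("expected must be >= 1")
  if (!is.numeric(nframe) || nframe < 1) stop("nframe must be >= 1")
  structure(
    list(counter = 0L, nframe = as.integer(nframe),
         dat = vector("list", as.integer(expected)),
         alive = logical(as.integer(expected)),
         capacity = as.integer(expected)),
    class = "trj"
  )
}

#' @export
print.trj <- function(x, ...) {
  cat(sprintf("<trj: %d trajectories (%d live) over %d frames>\n",
              x$counter, sum(x$alive[seq_len(x$counter)]), x$nframe))
  invisible(x)
}

.trj_row <- function(iframe, pid1, pid2) {
  matrix(as.integer(c(iframe, pid1, pid2)), 1, 3,
         dimnames = list(NULL, c("iframe", "pid1", "pid2")))
}

#' Add a new trajectory
#'
#' @param trj a [trj_init()] store.
#' @param head head segment row, a length-3 integer vector
#'   `c(iframe, pid1, pid2)` with `pid2 > 0`. `pid1` is 0 for a genuinely
#'   new appearance and positive for a branch-spawned child (its head
#'   records the branch point).
#' @return The updated store.
#' @export
trj_new <- function(trj, head) {
  if (length(head) != 3 || head[3] <= 0) {
    stop("trajectory head must be c(iframe, pid1, pid2) with pid2 > 0")
  }
  n <- trj$counter + 1L
  if (n > trj$capacity) {
    grow <- max(trj$capacity, 8L)
    trj$dat <- c(trj$dat, vector("list", grow))
    trj$alive <- c(trj$alive, logical(grow))
    trj$capacity <- trj$capacity + grow
  }
  trj$dat[[n]] <- .trj_row(head[1], head[2], head[3])
  trj$alive[n] <- TRUE
  trj$counter <- n
  trj
}

#' Tails of live trajectories, with merge resolution
#'
#' A trajectory is live while its end has not been identified (its last
#' segment has `pid2 > 0` and it has not been killed). Live trajectories
#' whose tails coincide (same frame, same vesicle) have merged: they are
#' compared by length (number of stored rows) and only the longest stays
#' alive; a length tie keeps the lowest trajectory id. The killed rows stay
#' in the store — marked dead — so population counts and the trajectory
#' matrix still show them.
#'
#' @param trj the store.
#' @return List with `trj` (the store after merge resolution) and `tails`,
#'   a data frame with columns traj_id, tail_frame, tail_pid2 — one row per
#'   surviving live trajectory.
#' @export
trj_tails <- function(trj) {
  live <- which(trj$alive[seq_len(trj$counter)])
  if (length(live) == 0) {
    return(list(trj = trj, tails = data.frame(traj_id = integer(0),
                                              tail_frame = integer(0),
                                              tail_pid2 = integer(0))))
  }
  info <- t(vapply(live, function(id) {
    m <- trj$dat[[id]]
    c(m[nrow(m), 1], m[nrow(m), 3], nrow(m))
  }, integer(3)))
  key <- paste(info[, 1], info[, 2])
  for (k in unique(key[duplicated(key)])) {
    grp <- which(key == k)
    lens <- info[grp, 3]
    winner <- grp[order(-lens, live[grp])[1]]
    losers <- setdiff(grp, winner)
    trj$alive[live[losers]] <- FALSE
  }
  live2 <- which(trj$alive[seq_len(trj$counter)])
  keep <- match(live2, live)
  list(trj = trj,
       tails = data.frame(traj_id = live2,
                          tail_frame = info[keep, 1],
                          tail_pid2 = info[keep, 2]))
}

#' Insert one frame's link segments into the store
#'
#' Segments with `pid1 > 0` extend the live trajectory whose tail vesicle is
#' `pid1`; when several segments share one `pid1` (a branch), the parent
#' continues along the smallest-distance arm and each other arm spawns a new
#' trajectory headed by the branch segment. Segments with `pid1 = 0` and
#' `pid2 > 0` create new trajectories. Segments with `pid2 = 0` close their
#' trajectory. Merge resolution is *not* performed here; it happens in
#' [trj_tails()] before the next insertion.
#'
#' @param trj the store; all live tails must sit at frame `links$iframe - 1`.
#' @param links a `link_set` for the transition into frame `links$iframe`.
#' @return The updated store.
#' @export
trj_insert <- function(trj, links) {
  iframe <- links$iframe
  seg <- links$segments
  live <- which(trj$alive[seq_len(trj$counter)])
  tail_frame <- integer(0); tail_pid <- integer(0)
  if (length(live) > 0) {
    tinfo <- t(vapply(live, function(id) {
      m <- trj$dat[[id]]
      c(m[nrow(m), 1], m[nrow(m), 3])
    }, integer(2)))
    tail_frame <- tinfo[, 1]; tail_pid <- tinfo[, 2]
    if (any(tail_frame != iframe - 1L)) {
      stop("sequencing error: live tail not at frame ", iframe - 1L)
    }
  }
  owner_of <- function(pid) {
    hit <- live[tail_pid == pid]
    if (length(hit) == 0) {
      stop("no live trajectory has tail vesicle ", pid, " at frame ", iframe - 1L)
    }
    hit[1]  # tails are unique after merge resolution
  }

  linked <- seg[seg$pid1 > 0 & seg$pid2 > 0, , drop = FALSE]
  for (p1 in unique(linked$pid1)) {
    arms <- linked[linked$pid1 == p1, , drop = FALSE]
    # parent continues along the nearest arm; ties to the smaller pid2
    arms <- arms[order(arms$distance, arms$pid2), , drop = FALSE]
    id <- owner_of(p1)
    trj$dat[[id]] <- rbind(trj$dat[[id]], .trj_row(iframe, p1, arms$pid2[1]))
    if (nrow(arms) > 1) {
      for (j in 2:nrow(arms)) {
        trj <- trj_new(trj, c(iframe, p1, arms$pid2[j]))
      }
    }
  }
  for (p2 in seg$pid2[seg$pid1 == 0 & seg$pid2 > 0]) {
    trj <- trj_new(trj, c(iframe, 0L, p2))
  }
  for (p1 in seg$pid1[seg$pid2 == 0 & seg$pid1 > 0]) {
    trj$alive[owner_of(p1)] <- FALSE
  }
  trj
}

#' Extract a trajectory's coordinates
#'
#' @param trj the store.
#' @param trajectory_id trajectory index, 1..counter.
#' @param all_detections list of `detection_set`, one per frame.
#' @return Data frame with columns frame, row, col: the centroid of each
#'   row's current-frame vesicle, in frame order.
#' @export
trj_coords <- function(trj, trajectory_id, all_detections) {
  if (trajectory_id < 1 || trajectory_id > trj$counter) {
    stop("no trajectory with id ", trajectory_id)
  }
  m <- trj$dat[[trajectory_id]]
  coords <- matrix(NA_real_, nrow(m), 2)
  for (r in seq_len(nrow(m))) {
    f <- m[r, 1]; v <- m[r, 3]
    if (f < 1 || f > length(all_detections) ||
        v < 1 || v > n_detections(all_detections[[f]])) {
      stop("integrity error: trajectory ", trajectory_id,
           " references vesicle ", v, " in frame ", f)
    }
    coords[r, ] <- all_detections[[f]]$positions[v, ]
  }
  data.frame(frame = as.vector(m[, 1]), row = coords[, 1], col = coords[, 2])
}

#' Trace all trajectories through a detection sequence
#'
#' @param all_detections list of `detection_set`, one per frame, frame order.
#' @param cutoffs ascending cutoff schedule for [multi_cutoff_link()],
#'   in px. Default `c(5, 10, 20)`.
#' @param expected capacity hint; default 4x the maximum per-frame count.
#' @return A trimmed `trj` store; merges at the final frame are resolved.
#' @export
trace_all <- function(all_detections, cutoffs = c(5, 10, 20), expected = NULL) {
  n_img <- length(all_detections)
  if (n_img < 1) stop("need at least one frame of detections")
  if (is.null(expected)) {
    expected <- max(4L * max(vapply(all_detections, n_detections, integer(1))), 1L)
  }
  trj <- trj_init(expected, n_img)
  for (k in seq_len(n_detections(all_detections[[1]]))) {
    trj <- trj_new(trj, c(1L, 0L, k))
  }
  if (n_img > 1) {
    for (f in 2:n_img) {
      prev <- all_detections[[f - 1]]
      curr <- all_detections[[f]]
      links <- multi_cutoff_link(prev, curr, cutoffs, iframe = f)
      trj <- trj_tails(trj)$trj
      trj <- trj_insert(trj, links)
    }
  }
  trj <- trj_tails(trj)$trj  # resolve merges at the final frame
  trj_trim(trj)
}

#' Trim unused store capacity
#'
#' @param trj the store.
#' @return The store with capacity reduced to `counter`; contents unchanged.
#' @export
trj_trim <- function(trj) {
  n <- trj$counter
  trj$dat <- trj$dat[seq_len(n)]
  trj$alive <- trj$alive[seq_len(n)]
  trj$capacity <- n
  trj
}

#' Per-trajectory segment table
#'
#' @param trj the store.
#' @return Data frame with columns trajectory_id, iframe, pid1, pid2, alive.
#' @export
trj_as_data_frame <- function(trj) {
  if (trj$counter == 0) {
    return(data.frame(trajectory_id = integer(0), iframe = integer(0),
                      pid1 = integer(0), pid2 = integer(0), alive = logical(0)))
  }
  do.call(rbind, lapply(seq_len(trj$counter), function(id) {
    m <- trj$dat[[id]]
    data.frame(trajectory_id = id, iframe = as.vector(m[, 1]),
               pid1 = as.vector(m[, 2]), pid2 = as.vector(m[, 3]),
               alive = trj$alive[id])
  }))
}

#' Write / read a TRJ store as CSV
#'
#' @param trj the store.
#' @param path CSV path.
#' @return `path` invisibly (write); a `trj` object (read).
#' @export
write_trj_csv <- function(trj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vestrack trajectory store",
               sprintf("# nframe=%d", trj$nframe)), con)
  utils::write.csv(trj_as_data_frame(trj), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trj_csv
#' @param nframe frame count; if `NULL`, recovered from the file header.
#' @export
read_trj_csv <- function(path, nframe = NULL) {
  if (is.null(nframe)) {
    hdr <- readLines(path, n = 5)
    m <- regmatches(hdr, regexpr("nframe=[0-9]+", hdr))
    nframe <- as.integer(sub("nframe=", "", m[m != ""][1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  n <- if (nrow(df) == 0) 0L else max(df$trajectory_id)
  trj <- trj_init(max(n, 1L), max(nframe, 1L))
  for (id in seq_len(n)) {
    sub <- df[df$trajectory_id == id, , drop = FALSE]
    sub <- sub[order(sub$iframe), , drop = FALSE]
    trj$counter <- id
    trj$dat[[id]] <- matrix(as.integer(c(sub$iframe, sub$pid1, sub$pid2)),
                            ncol = 3, dimnames = list(NULL, c("iframe", "pid1", "pid2")))
    trj$alive[id] <- sub$alive[1]
  }
  trj$nframe <- as.integer(nframe)
  trj_trim(trj)
}
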