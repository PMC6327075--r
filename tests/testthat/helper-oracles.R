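# Independent brute-force oracles. These deliberately share no code with the
# package: per-pixel BFS with an explicit one-at-a-time queue for labeling,
# and plain double loops over the distance definition for linking.

# Connected-component labeling by per-pixel BFS. Returns an integer label
# matrix; labels are assigned in row-major order of each component's first
# pixel, matching the package's documented discovery order.
oracle_label <- function(binary, connectivity) {
  h <- nrow(binary); w <- ncol(binary)
  labels <- matrix(0L, h, w)
  nb <- if (connectivity == 4L) {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  } else {
    list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L),
         c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  }
  lab <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (binary[r, c] == 1L && labels[r, c] == 0L) {
      lab <- lab + 1L
      queue <- list(c(r, c))
      labels[r, c] <- lab
      while (length(queue) > 0) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in nb) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= h && q[2] >= 1 && q[2] <= w &&
              binary[q[1], q[2]] == 1L && labels[q[1], q[2]] == 0L) {
            labels[q[1], q[2]] <- lab
            queue[[length(queue) + 1]] <- q
          }
        }
      }
    }
  }
  labels
}

# Label matrix from the package's blob list, for partition comparison.
blobs_to_labels <- function(blobs, h, w) {
  labels <- matrix(0L, h, w)
  for (i in seq_along(blobs)) {
    labels[blobs[[i]]$pixels] <- i
  }
  labels
}

# Exhaustive nearest-neighbor link classification straight from the
# definition: per-row and per-column minima by scanning, validity by strict
# cutoff, categories by counting multiplicities.
oracle_classify <- function(prev_pos, curr_pos, cutoff) {
  P <- nrow(prev_pos); C <- nrow(curr_pos)
  d <- function(i, j) sqrt(sum((prev_pos[i, ] - curr_pos[j, ])^2))
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(P)) {
    best <- 0L; bestd <- Inf
    for (j in seq_len(C)) if (d(i, j) < bestd) { bestd <- d(i, j); best <- j }
    if (best > 0L && bestd < cutoff) pairs <- rbind(pairs, c(i, best))
  }
  for (j in seq_len(C)) {
    best <- 0L; bestd <- Inf
    for (i in seq_len(P)) if (d(i, j) < bestd) { bestd <- d(i, j); best <- i }
    if (best > 0L && bestd < cutoff) pairs <- rbind(pairs, c(best, j))
  }
  pairs <- unique(pairs)
  cat_of <- character(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    if (sum(pairs[, 2] == pairs[k, 2]) >= 2) cat_of[k] <- "merge"
    else if (sum(pairs[, 1] == pairs[k, 1]) >= 2) cat_of[k] <- "branch"
    else cat_of[k] <- "regular"
  }
  seg <- data.frame(pid1 = pairs[, 1], pid2 = pairs[, 2], category = cat_of)
  for (i in setdiff(seq_len(P), seg$pid1)) {
    seg <- rbind(seg, data.frame(pid1 = i, pid2 = 0L, category = "end"))
  }
  for (j in setdiff(seq_len(C), seg$pid2)) {
    seg <- rbind(seg, data.frame(pid1 = 0L, pid2 = j, category = "begin"))
  }
  seg <- seg[order(seg$pid1, seg$pid2), ]
  rownames(seg) <- NULL
  seg
}

# Random sparse binary image with a mix of isolated pixels and small patches.
random_binary <- function(h, w, p = 0.35) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# Wrap a bare position matrix as a detection_set-alike for linking functions.
as_detections <- function(pos, frame_index = 1L) {
  pos <- matrix(pos, ncol = 2, dimnames = list(NULL, c("row", "col")))
  structure(list(frame_index = as.integer(frame_index), positions = pos,
                 sizes = rep(1L, nrow(pos))),
            class = "detection_set")
}

# Strip cutoff_level/distance so link sets from different routes compare.
seg_core <- function(link_set) {
  s <- link_set$segments[, c("pid1", "pid2", "category")]
  s <- s[order(s$pid1, s$pid2), ]
  rownames(s) <- NULL
  s
}

# Reverse a detection sequence in time (frame indices renumbered).
reverse_detections <- function(detections) {
  n <- length(detections)
  out <- rev(detections)
  for (i in seq_len(n)) out[[i]]$frame_index <- i
  out
}

# Count branch-spawned trajectories (head row records a branch point) and
# merge-killed ones (dead, with the tail row duplicated in another
# trajectory at the same frame).
count_branch_children <- function(trj) {
  sum(vapply(seq_len(trj$counter), function(id) trj$dat[[id]][1, 2] > 0L, logical(1)))
}
count_merge_killed <- function(trj) {
  n <- 0L
  for (id in seq_len(trj$counter)) {
    if (trj$alive[id]) next
    m <- trj$dat[[id]]
    tail_row <- m[nrow(m), ]
    shared <- any(vapply(seq_len(trj$counter), function(other) {
      if (other == id) return(FALSE)
      mo <- trj$dat[[other]]
      any(mo[, 1] == tail_row[1] & mo[, 3] == tail_row[3])
    }, logical(1)))
    if (shared) n <- n + 1L
  }
  n
}
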