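#' @name linking
#' @title Frame-to-frame connectivity through the distance matrix
#'
#' @description
#' Vesicles cannot be individually tagged, so identity across consecutive
#' frames rests on two criteria: the two detections are mutually closest
#' among all candidates, and their distance is below a cutoff corresponding
#' to the maximum plausible per-frame displacement. All pairwise Euclidean
#' distances between the previous and current frame's detections form the
#' distance matrix; row minima give each previous vesicle's forward nearest
#' neighbor, column minima each current vesicle's backward nearest neighbor.
#' Five segment categories result: regular (mutual, unique), merge (several
#' previous vesicles share one current nearest neighbor), branch (one
#' previous vesicle is nearest to several current ones), end (no valid
#' forward neighbor) and begin (no valid backward neighbor).
#'
#' Because vesicle speeds vary widely, a single cutoff is a poor fit: small
#' cutoffs lose fast vesicles, large ones mix up slow neighbors. The
#' multi-cutoff search runs the classification at ascending cutoffs,
#' freezing matches made at smaller cutoffs and removing the matched
#' vesicles from later levels, so slow-vesicle links keep precedence.
NULL

#' Pairwise distance matrix between two detection sets
#'
#' @param prev detection set of the previous frame (P vesicles).
#' @param curr detection set of the current frame (C vesicles).
#' @return A `distance_matrix` object: list with `values` (P x C Euclidean
#'   distances), `row_min_idx` (per-row argmin column) and `col_min_idx`
#'   (per-column argmin row). Ties break to the smallest index.
#' @export
build_distance_matrix <- function(prev, curr) {
  p <- prev$positions; q <- curr$positions
  P <- nrow(p); C <- nrow(q)
  dr <- outer(p[, 1], q[, 1], "-")
  dc <- outer(p[, 2], q[, 2], "-")
  values <- sqrt(dr * dr + dc * dc)
  dimnames(values) <- NULL
  structure(
    list(values = values,
         row_min_idx = if (C > 0) unname(apply(values, 1, which.min)) else integer(P),
         col_min_idx = if (P > 0) unname(apply(values, 2, which.min)) else integer(C)),
    class = "distance_matrix"
  )
}

.empty_segments <- function() {
  data.frame(pid1 = integer(0), pid2 = integer(0), distance = numeric(0),
             category = character(0), cutoff_level = integer(0),
             stringsAsFactors = FALSE)
}

#' Classify frame-pair links at a single cutoff
#'
#' The segment set is the union of all valid (distance `<` cutoff)
#' row-minimum links and all valid column-minimum links. Categories follow
#' from multiplicity: segments sharing a current vesicle (`pid2`) form a
#' merge; segments sharing a previous vesicle (`pid1`) form a branch; a
#' lone mutual pair is regular. Previous vesicles with no valid forward
#' neighbor become end segments (`pid2 = 0`); current vesicles with no
#' valid backward neighbor become begin segments (`pid1 = 0`). The validity
#' comparison is strict `<`.
#'
#' @param D a [build_distance_matrix()] result.
#' @param cutoff maximum plausible displacement, px, `> 0`.
#' @param iframe current frame index recorded on the result.
#' @return A `link_set`: list with `iframe` and `segments`, a data frame
#'   with columns pid1, pid2, distance, category, cutoff_level.
#' @export
classify_links <- function(D, cutoff, iframe = NA_integer_) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  V <- D$values
  P <- nrow(V); C <- ncol(V)

  pairs <- matrix(integer(0), 0, 2)
  if (P > 0 && C > 0) {
    fwd_ok <- V[cbind(seq_len(P), D$row_min_idx)] < cutoff
    bwd_ok <- V[cbind(D$col_min_idx, seq_len(C))] < cutoff
    pairs <- rbind(
      cbind(which(fwd_ok), D$row_min_idx[fwd_ok]),
      cbind(D$col_min_idx[bwd_ok], which(bwd_ok))
    )
    pairs <- unique(pairs)
  }

  if (nrow(pairs) > 0) {
    seg <- data.frame(pid1 = pairs[, 1], pid2 = pairs[, 2],
                      distance = V[pairs], category = "regular",
                      cutoff_level = 1L, stringsAsFactors = FALSE)
    merge_targets <- as.integer(names(which(table(seg$pid2) >= 2)))
    branch_sources <- as.integer(names(which(table(seg$pid1) >= 2)))
    seg$category[seg$pid2 %in% merge_targets] <- "merge"
    seg$category[seg$category == "regular" & seg$pid1 %in% branch_sources] <- "branch"
    seg <- seg[order(seg$pid1, seg$pid2), , drop = FALSE]
  } else {
    seg <- .empty_segments()
  }

  ended <- setdiff(seq_len(P), seg$pid1)
  begun <- setdiff(seq_len(C), seg$pid2)
  if (length(ended) > 0) {
    seg <- rbind(seg, data.frame(pid1 = ended, pid2 = 0L, distance = NA_real_,
                                 category = "end", cutoff_level = 1L))
  }
  if (length(begun) > 0) {
    seg <- rbind(seg, data.frame(pid1 = 0L, pid2 = begun, distance = NA_real_,
                                 category = "begin", cutoff_level = 1L))
  }
  seg <- seg[order(seg$pid1, seg$pid2), , drop = FALSE]
  rownames(seg) <- NULL
  structure(list(iframe = iframe, segments = seg), class = "link_set")
}

#' @export
print.link_set <- function(x, ...) {
  tab <- table(x$segments$category)
  cat(sprintf("<link_set frame %s: %s>\n", x$iframe,
              paste(names(tab), as.integer(tab), sep = "=", collapse = " ")))
  invisible(x)
}

#' Link two frames with an ascending multi-cutoff schedule
#'
#' Runs [classify_links()] at each cutoff from smallest to largest on the
#' vesicles not yet resolved at earlier levels. Linked matches (including
#' merge and branch segments) made at a smaller cutoff are frozen and their
#' vesicles removed from later levels; vesicles still unmatched after the
#' last level become end/begin segments. Smaller cutoffs take precedence so
#' that a fast interloper passing near a slow pair cannot steal its link.
#'
#' @param prev,curr detection sets of the two consecutive frames.
#' @param cutoffs strictly ascending vector of cutoff distances, px.
#' @param iframe current frame index.
#' @return A `link_set` covering every vesicle of both frames.
#' @export
multi_cutoff_link <- function(prev, curr, cutoffs, iframe = NA_integer_) {
  if (length(cutoffs) == 0 || any(cutoffs <= 0) ||
      (length(cutoffs) > 1 && any(diff(cutoffs) <= 0))) {
    stop("cutoffs must be strictly ascending and positive")
  }
  P <- nrow(prev$positions); C <- nrow(curr$positions)
  active_p <- seq_len(P); active_c <- seq_len(C)
  out <- .empty_segments()

  for (lvl in seq_along(cutoffs)) {
    if (length(active_p) == 0 || length(active_c) == 0) break
    sub_prev <- list(positions = prev$positions[active_p, , drop = FALSE])
    sub_curr <- list(positions = curr$positions[active_c, , drop = FALSE])
    ls <- classify_links(build_distance_matrix(sub_prev, sub_curr), cutoffs[lvl])
    seg <- ls$segments
    linked <- seg[seg$pid1 > 0 & seg$pid2 > 0, , drop = FALSE]
    if (nrow(linked) > 0) {
      linked$pid1 <- active_p[linked$pid1]
      linked$pid2 <- active_c[linked$pid2]
      linked$cutoff_level <- lvl
      out <- rbind(out, linked)
      active_p <- setdiff(active_p, linked$pid1)
      active_c <- setdiff(active_c, linked$pid2)
    }
  }

  if (length(active_p) > 0) {
    out <- rbind(out, data.frame(pid1 = active_p, pid2 = 0L,
                                 distance = NA_real_, category = "end",
                                 cutoff_level = length(cutoffs)))
  }
  if (length(active_c) > 0) {
    out <- rbind(out, data.frame(pid1 = 0L, pid2 = active_c,
                                 distance = NA_real_, category = "begin",
                                 cutoff_level = length(cutoffs)))
  }
  out <- out[order(out$pid1, out$pid2), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(iframe = iframe, segments = out), class = "link_set")
}
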