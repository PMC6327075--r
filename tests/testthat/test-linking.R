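test_that("distance matrix holds Euclidean distances with smallest-index tie-breaks", {
  same <- as_detections(rbind(c(2, 3)))
  D <- build_distance_matrix(same, same)
  expect_equal(D$values, matrix(0, 1, 1))
  expect_identical(unname(D$row_min_idx), 1L)
  expect_identical(unname(D$col_min_idx), 1L)

  D2 <- build_distance_matrix(as_detections(rbind(c(0, 0))),
                              as_detections(rbind(c(3, 4))))
  expect_equal(D2$values[1, 1], 5)

  # equidistant tie: both columns at distance 5, argmin must pick column 1
  D3 <- build_distance_matrix(as_detections(rbind(c(0, 0))),
                              as_detections(rbind(c(3, 4), c(4, 3))))
  expect_identical(unname(D3$row_min_idx), 1L)

  set.seed(13)
  for (rep in 1:20) {
    p <- matrix(runif(12, 0, 50), 6, 2)
    q <- matrix(runif(8, 0, 50), 4, 2)
    D <- build_distance_matrix(as_detections(p), as_detections(q))
    for (i in 1:6) {
      ds <- apply(q, 1, function(x) sqrt(sum((p[i, ] - x)^2)))
      expect_equal(unname(D$values[i, ]), unname(ds))
      expect_identical(unname(D$row_min_idx[i]), which.min(ds))
    }
    for (j in 1:4) {
      ds <- apply(p, 1, function(x) sqrt(sum((x - q[j, ])^2)))
      expect_identical(unname(D$col_min_idx[j]), which.min(ds))
    }
  }
})

test_that("classify_links reproduces the five categories on constructed geometries", {
  link <- function(p, q, cutoff) {
    classify_links(build_distance_matrix(as_detections(p), as_detections(q)), cutoff)
  }
  # two stationary well-separated points: two regular segments
  s <- seg_core(link(rbind(c(0, 0), c(50, 50)), rbind(c(1, 0), c(50, 51)), 10))
  expect_identical(s$category, c("regular", "regular"))
  expect_identical(s$pid2, c(1L, 2L))

  # merge: two previous share the nearest current
  s <- seg_core(link(rbind(c(0, 0), c(10, 0)), rbind(c(5, 0)), 6))
  expect_identical(s$category, c("merge", "merge"))
  expect_identical(s$pid2, c(1L, 1L))

  # branch: mirror of the merge
  s <- seg_core(link(rbind(c(5, 0)), rbind(c(0, 0), c(10, 0)), 6))
  expect_identical(s$category, c("branch", "branch"))
  expect_identical(s$pid1, c(1L, 1L))

  # too far: one end plus one begin
  s <- seg_core(link(rbind(c(0, 0)), rbind(c(100, 100)), 6))
  expect_identical(sort(s$category), c("begin", "end"))

  expect_error(classify_links(build_distance_matrix(
    as_detections(rbind(c(0, 0))), as_detections(rbind(c(1, 1)))), 0), "cutoff")
})

test_that("classify_links matches the exhaustive oracle on random frames", {
  set.seed(23)
  for (rep in 1:100) {
    P <- sample(1:7, 1); C <- sample(1:7, 1)
    p <- matrix(runif(2 * P, 0, 40), P, 2)
    q <- matrix(runif(2 * C, 0, 40), C, 2)
    cutoff <- runif(1, 3, 25)
    got <- seg_core(classify_links(build_distance_matrix(
      as_detections(p), as_detections(q)), cutoff))
    expect_identical(got, oracle_classify(p, q, cutoff))
  }
})

test_that("mirrored inputs swap merges and branches (and ends and begins)", {
  # The duality is structural: swapping prev/curr transposes the linked
  # pair set, swaps end and begin, and turns shared-pid2 groups (merges)
  # into shared-pid1 groups (branches). Per-segment labels of segments that
  # belong to both a merge and a branch group follow a fixed merge-first
  # priority, so the comparison is made on the group structure itself.
  set.seed(31)
  for (rep in 1:50) {
    p <- matrix(runif(10, 0, 30), 5, 2)
    q <- matrix(runif(8, 0, 30), 4, 2)
    fwd <- seg_core(classify_links(build_distance_matrix(
      as_detections(p), as_detections(q)), 12))
    bwd <- seg_core(classify_links(build_distance_matrix(
      as_detections(q), as_detections(p)), 12))
    fl <- fwd[fwd$pid1 > 0 & fwd$pid2 > 0, ]
    bl <- bwd[bwd$pid1 > 0 & bwd$pid2 > 0, ]
    # linked pairs transpose exactly
    expect_identical(paste(fl$pid1, fl$pid2)[order(fl$pid1, fl$pid2)],
                     paste(bl$pid2, bl$pid1)[order(bl$pid2, bl$pid1)])
    # ends <-> begins
    expect_setequal(fwd$pid1[fwd$category == "end"],
                    bwd$pid2[bwd$category == "begin"])
    expect_setequal(fwd$pid2[fwd$category == "begin"],
                    bwd$pid1[bwd$category == "end"])
    # merge groups (by pid2) forward == branch groups (by pid1) mirrored
    fwd_merge_groups <- sort(unique(fl$pid2[duplicated(fl$pid2)]))
    bwd_branch_groups <- sort(unique(bl$pid1[duplicated(bl$pid1)]))
    expect_identical(fwd_merge_groups, bwd_branch_groups)
    fwd_branch_groups <- sort(unique(fl$pid1[duplicated(fl$pid1)]))
    bwd_merge_groups <- sort(unique(bl$pid2[duplicated(bl$pid2)]))
    expect_identical(fwd_branch_groups, bwd_merge_groups)
  }
  # on the canonical two-point geometries the labels swap outright
  m <- seg_core(classify_links(build_distance_matrix(
    as_detections(rbind(c(0, 0), c(10, 0))), as_detections(rbind(c(5, 0)))), 6))
  b <- seg_core(classify_links(build_distance_matrix(
    as_detections(rbind(c(5, 0))), as_detections(rbind(c(0, 0), c(10, 0)))), 6))
  expect_identical(m$category, c("merge", "merge"))
  expect_identical(b$category, c("branch", "branch"))
})

test_that("a single-cutoff list reduces multi_cutoff_link to classify_links", {
  set.seed(47)
  for (rep in 1:100) {
    P <- sample(1:6, 1); C <- sample(1:6, 1)
    p <- matrix(runif(2 * P, 0, 40), P, 2)
    q <- matrix(runif(2 * C, 0, 40), C, 2)
    cutoff <- runif(1, 3, 25)
    a <- multi_cutoff_link(as_detections(p), as_detections(q), cutoff)
    b <- classify_links(build_distance_matrix(as_detections(p), as_detections(q)),
                        cutoff)
    expect_identical(seg_core(a), seg_core(b))
  }
})

test_that("ascending cutoffs keep the slow pair and recover the fast pair", {
  prev <- as_detections(rbind(c(0, 0), c(100, 0)))
  curr <- as_detections(rbind(c(2, 0), c(120, 0)))
  both <- multi_cutoff_link(prev, curr, c(5, 25))$segments
  linked <- both[both$pid1 > 0 & both$pid2 > 0, ]
  expect_identical(nrow(linked), 2L)
  expect_identical(linked$cutoff_level, c(1L, 2L))

  single <- multi_cutoff_link(prev, curr, 5)$segments
  expect_identical(sort(single$category), c("begin", "end", "regular"))
})

test_that("a frozen slow link is never re-assigned to a fast interloper", {
  # slow pair at distance 1; an interloper 8 px from the slow previous point;
  # at cutoff 20 alone the interloper could grab the slow point's link
  prev <- as_detections(rbind(c(0, 0), c(15, 0)))
  curr <- as_detections(rbind(c(1, 0), c(8, 0)))
  seg <- multi_cutoff_link(prev, curr, c(2, 20))$segments
  slow <- seg[seg$pid1 == 1, ]
  expect_identical(slow$pid2, 1L)
  expect_identical(slow$cutoff_level, 1L)
  inter <- seg[seg$pid1 == 2, ]
  expect_identical(inter$pid2, 2L)

  expect_error(multi_cutoff_link(prev, curr, c(10, 5)), "ascending")
})

test_that("empty frames produce all-begin or all-end link sets", {
  none <- as_detections(matrix(numeric(0), 0, 2))
  some <- as_detections(rbind(c(1, 1), c(5, 5)))
  s1 <- multi_cutoff_link(none, some, c(5, 10))$segments
  expect_identical(s1$category, c("begin", "begin"))
  s2 <- multi_cutoff_link(some, none, c(5, 10))$segments
  expect_identical(s2$category, c("end", "end"))
})

test_that("every vesicle is covered and no link exceeds the largest cutoff", {
  set.seed(59)
  for (rep in 1:50) {
    P <- sample(0:6, 1); C <- sample(0:6, 1)
    p <- matrix(runif(2 * P, 0, 60), P, 2)
    q <- matrix(runif(2 * C, 0, 60), C, 2)
    seg <- multi_cutoff_link(as_detections(p), as_detections(q), c(5, 10, 20))$segments
    expect_setequal(seg$pid1[seg$pid1 > 0], seq_len(P))
    expect_setequal(unique(seg$pid2[seg$pid2 > 0]), seq_len(C))
    linked <- seg[seg$pid1 > 0 & seg$pid2 > 0, ]
    expect_true(all(linked$distance < 20))
  }
})

test_that("linking recovers identity exactly on well-separated synthetic drift", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    # spacing > 2*cutoff, displacement < cutoff/2 with cutoff 10
    base <- cbind(seq(0, by = 25, length.out = n), runif(n, 0, 100))
    shift <- matrix(runif(2 * n, -3.5, 3.5), n, 2)
    perm <- sample(n)
    seg <- multi_cutoff_link(as_detections(base),
                             as_detections((base + shift)[perm, , drop = FALSE]),
                             10)$segments
    expect_identical(nrow(seg), n)
    expect_true(all(seg$category == "regular"))
    expect_identical(order(perm)[seg$pid1], seg$pid2)
  }
})
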