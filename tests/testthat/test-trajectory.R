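make_links <- function(iframe, pid1, pid2, distance = NA_real_) {
  structure(list(
    iframe = iframe,
    segments = data.frame(pid1 = as.integer(pid1), pid2 = as.integer(pid2),
                          distance = distance,
                          category = "regular", cutoff_level = 1L)),
    class = "link_set")
}

test_that("trj_init creates an empty store and grows past its capacity hint", {
  trj <- trj_init(100, 10)
  expect_identical(trj$counter, 0L)
  expect_identical(trj$nframe, 10L)
  expect_error(trj_init(0, 5), "expected")
  expect_error(trj_init(5, 0), "nframe")

  small <- trj_init(2, 5)
  for (k in 1:7) small <- trj_new(small, c(1L, 0L, k))
  expect_identical(small$counter, 7L)
  expect_identical(small$dat[[7]][1, ], c(iframe = 1L, pid1 = 0L, pid2 = 7L))
})

test_that("trj_new stores head segments and rejects dead heads", {
  trj <- trj_new(trj_init(4, 3), c(1L, 0L, 3L))
  expect_identical(trj$counter, 1L)
  expect_identical(unname(trj$dat[[1]]), matrix(c(1L, 0L, 3L), 1))
  expect_true(trj$alive[1])
  trj <- trj_new(trj, c(1L, 0L, 5L))
  expect_identical(trj$counter, 2L)
  expect_error(trj_new(trj, c(2L, 1L, 0L)), "pid2 > 0")
})

test_that("trj_tails resolves merges: longest survives, ties to the lowest id", {
  # trajectory 1 has 3 rows, trajectory 2 has 1 row, same tail (frame 4, vesicle 7)
  trj <- trj_init(4, 6)
  trj <- trj_new(trj, c(2L, 0L, 1L))
  trj$dat[[1]] <- rbind(trj$dat[[1]], c(3L, 1L, 2L), c(4L, 2L, 7L))
  trj <- trj_new(trj, c(4L, 0L, 7L))
  res <- trj_tails(trj)
  expect_identical(res$tails$traj_id, 1L)
  expect_false(res$trj$alive[2])
  expect_true(res$trj$alive[1])

  # equal lengths: lowest id survives
  trj2 <- trj_new(trj_init(4, 4), c(2L, 0L, 5L))
  trj2 <- trj_new(trj2, c(2L, 0L, 5L))
  res2 <- trj_tails(trj2)
  expect_identical(res2$tails$traj_id, 1L)
  expect_identical(res2$trj$alive[1:2], c(TRUE, FALSE))

  # distinct tails: both kept
  trj3 <- trj_new(trj_new(trj_init(4, 4), c(1L, 0L, 1L)), c(1L, 0L, 2L))
  expect_identical(trj_tails(trj3)$tails$traj_id, c(1L, 2L))
})

test_that("trj_insert extends, spawns, branches and closes", {
  trj <- trj_new(trj_init(8, 6), c(3L, 0L, 2L))
  trj <- trj_insert(trj, make_links(4L, 2L, 5L, 1.0))
  expect_identical(nrow(trj$dat[[1]]), 2L)
  expect_identical(trj$dat[[1]][2, ], c(iframe = 4L, pid1 = 2L, pid2 = 5L))

  # begin segment creates a new trajectory
  trj <- trj_insert(trj, make_links(5L, c(5L, 0L), c(1L, 9L), c(0.5, NA)))
  expect_identical(trj$counter, 2L)
  expect_identical(trj$dat[[2]][1, ], c(iframe = 5L, pid1 = 0L, pid2 = 9L))

  # branch: parent continues along the nearest arm, the other arm spawns
  trjb <- trj_new(trj_init(8, 6), c(3L, 0L, 1L))
  trjb <- trj_insert(trjb, make_links(4L, c(1L, 1L), c(2L, 3L), c(2.0, 1.0)))
  expect_identical(trjb$counter, 2L)
  expect_identical(trjb$dat[[1]][2, "pid2"], c(pid2 = 3L))  # nearest arm
  expect_identical(trjb$dat[[2]][1, ], c(iframe = 4L, pid1 = 1L, pid2 = 2L))

  # end segment closes the trajectory
  trje <- trj_new(trj_init(4, 6), c(3L, 0L, 1L))
  trje <- trj_insert(trje, make_links(4L, 1L, 0L))
  expect_false(trje$alive[1])

  # frame discontinuity is a sequencing error
  expect_error(trj_insert(trjb, make_links(9L, 3L, 1L, 1)), "sequencing")
})

test_that("trj_coords extracts centroids in frame order and flags dangling indices", {
  det <- list(as_detections(rbind(c(10, 20), c(30, 40))),
              as_detections(rbind(c(11, 21))))
  det[[2]]$frame_index <- 2L
  trj <- trj_new(trj_init(4, 2), c(1L, 0L, 2L))
  cc <- trj_coords(trj, 1, det)
  expect_equal(cc, data.frame(frame = 1L, row = 30, col = 40))

  trj$dat[[1]] <- rbind(trj$dat[[1]], c(2L, 2L, 1L))
  cc2 <- trj_coords(trj, 1, det)
  expect_identical(nrow(cc2), 2L)
  expect_equal(cc2$row, c(30, 11))

  trj$dat[[1]][2, 3] <- 99L
  expect_error(trj_coords(trj, 1, det), "integrity")
  expect_error(trj_coords(trj, 5, det), "no trajectory")
})

test_that("trace_all seeds from frame 1 and recovers independent drifting tracks", {
  # 1 frame: every detection seeds a one-row trajectory
  one <- trace_all(list(as_detections(rbind(c(1, 1), c(5, 5), c(9, 9)))), c(5))
  expect_identical(one$counter, 3L)
  expect_true(all(vapply(one$dat, nrow, integer(1)) == 1L))

  # 2 tracks drifting apart over 10 frames
  det <- lapply(1:10, function(f) {
    as_detections(rbind(c(10 + f, 10), c(60, 60 + 2 * f)), f)
  })
  trj <- trace_all(det, c(5, 10, 20))
  expect_identical(trj$counter, 2L)
  expect_true(all(trj$alive))
  expect_true(all(vapply(trj$dat, nrow, integer(1)) == 10L))
  # frame continuity within every trajectory
  for (id in 1:2) expect_identical(unique(diff(trj$dat[[id]][, 1])), 1L)
  # identity: trajectory 1 follows the first scripted point
  cc <- trj_coords(trj, 1, det)
  expect_equal(cc$row, 10 + 1:10)
})

test_that("every detection appears as pid2 in some trajectory (conservation)", {
  set.seed(71)
  det <- lapply(1:8, function(f) {
    as_detections(matrix(runif(2 * sample(2:6, 1), 0, 80), ncol = 2), f)
  })
  trj <- trace_all(det, c(5, 10, 20))
  df <- trj_as_data_frame(trj)
  for (f in 1:8) {
    seen <- df$pid2[df$iframe == f]
    expect_true(all(seq_len(nrow(det[[f]]$positions)) %in% seen))
  }
  # live tails are unique after the final merge resolution
  tails <- trj_tails(trj)$tails
  expect_identical(anyDuplicated(paste(tails$tail_frame, tails$tail_pid2)), 0L)
})

test_that("reversing a movie swaps merge-killed and branch-spawned counts", {
  # asymmetric event mix: two merges, one branch; detections taken straight
  # from the scripted truth (coincident merge partners collapse to one spot,
  # exactly as a detector would see them)
  script <- make_script(6, 8, motion = "oscillate", oscillate_radius = 0.5,
                        events = list(list(type = "merge", tracks = c(1, 2), frame = 4),
                                      list(type = "merge", tracks = c(3, 4), frame = 3),
                                      list(type = "branch", track = 5, frame = 5)),
                        seed = 97)
  truth <- script_truth(script)
  det <- lapply(1:8, function(f) {
    pts <- unique(round(as.matrix(truth[truth$frame == f, c("row", "col")]), 6))
    as_detections(pts, f)
  })
  fwd <- trace_all(det, c(10, 20))
  bwd <- trace_all(reverse_detections(det), c(10, 20))
  expect_identical(count_merge_killed(fwd), 2L)
  expect_identical(count_branch_children(fwd), 1L)
  expect_identical(count_merge_killed(bwd), 1L)
  expect_identical(count_branch_children(bwd), 2L)
})

test_that("trj_trim drops spare capacity, preserves contents, and is idempotent", {
  trj <- trj_init(1000, 4)
  for (k in 1:7) trj <- trj_new(trj, c(1L, 0L, k))
  before <- trj$dat[1:7]
  tr <- trj_trim(trj)
  expect_identical(tr$counter, 7L)
  expect_identical(tr$capacity, 7L)
  expect_identical(tr$dat, before)
  expect_identical(trj_trim(tr), tr)
  empty <- trj_trim(trj_init(50, 2))
  expect_identical(empty$counter, 0L)
})

test_that("TRJ CSV round-trips", {
  d <- withr::local_tempdir()
  det <- lapply(1:5, function(f) as_detections(rbind(c(10 + f, 10), c(50, 50)), f))
  trj <- trace_all(det, c(5, 10))
  p <- file.path(d, "trj.csv")
  write_trj_csv(trj, p)
  back <- read_trj_csv(p)
  expect_identical(back$counter, trj$counter)
  expect_identical(back$nframe, trj$nframe)
  for (id in seq_len(trj$counter)) {
    expect_identical(unname(back$dat[[id]]), unname(trj$dat[[id]]))
  }
  expect_identical(back$alive, unname(trj$alive))
})
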