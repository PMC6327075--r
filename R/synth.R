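#' @name synth
#' @title Synthetic ground-truth movies
#'
#' @description
#' The generator scripts point tracks — oscillating in a small region or
#' drifting with constant speed, with optional scripted merge and branch
#' events, births and deaths — and renders them as isotropic Gaussian
#' spots on a dark background with additive Gaussian noise, clipped to
#' \[0, 254\]. Every downstream stage (detection, linking, tracing,
#' kinematics) can thus be validated against exact scripted truth without
#' any experimental data. Fixed seed implies byte-identical output.
NULL

#' Script a set of ground-truth tracks
#'
#' Anchors are laid out on a jittered grid honoring `min_spacing`, so that
#' non-event tracks never approach each other; scripted merge partners and
#' branch children are the only exceptions. A merge partner approaches its
#' target at `approach_step` px/frame and coincides with it from the merge
#' frame on; a branch child appears one small offset away from its parent
#' at the branch frame and recedes at `branch_step` px/frame.
#'
#' @param n_tracks number of primary tracks (merge partners count; branch
#'   children are appended as extra tracks).
#' @param n_frames number of frames.
#' @param motion `"oscillate"` (jitter within `oscillate_radius` of the
#'   anchor) or `"drift"` (constant velocity `drift_speed` px/frame,
#'   reflecting at the margins).
#' @param oscillate_radius small-region oscillation radius, px.
#' @param drift_speed drift speed, px/frame.
#' @param events list of event specs: `list(type = "merge", tracks = c(a, b),
#'   frame = f)` makes track b converge onto track a and coincide from frame
#'   f on; `list(type = "branch", track = a, frame = f)` spawns a new track
#'   splitting off a at frame f.
#' @param shape image dimensions c(height, width), px.
#' @param min_spacing minimum anchor spacing, px. Keep above twice the
#'   largest linking cutoff for unambiguous ground truth.
#' @param spot_sigma rendered Gaussian spot scale, px (match the detector's
#'   `log_sigma`).
#' @param peak spot peak intensity above background.
#' @param background background level.
#' @param noise_sd additive Gaussian noise standard deviation (0 = none).
#' @param approach_step,branch_step per-frame step of merge partners /
#'   branch children, px. Both must sit above the detector's resolving
#'   separation for the rendered spot scale (about 4 x `spot_sigma`, else
#'   the pre-merge pair blurs into one blob and the event lands on the
#'   wrong frame) and below a single linking cutoff level, so the two arms
#'   of the event are matched at the same level. The defaults suit
#'   `spot_sigma = 2` with a first cutoff of 10 px.
#' @param branch_offset parent-to-child separation at the branch frame, px;
#'   same constraints as `branch_step`.
#' @param seed RNG seed; fixed seed gives a byte-identical script and movie.
#' @return A `track_script`: list with `tracks` (list of per-track records:
#'   `birth`, `death`, `pos` — an `n_frames x 2` matrix, NA outside life),
#'   `events`, and all rendering parameters.
#' @export
make_script <- function(n_tracks, n_frames,
                        motion = c("oscillate", "drift"),
                        oscillate_radius = 2, drift_speed = 1.5,
                        events = list(),
                        shape = c(256L, 256L), min_spacing = 48,
                        spot_sigma = 2, peak = 200, background = 10,
                        noise_sd = 0, approach_step = 8.5, branch_step = 3,
                        branch_offset = 9, seed = 1L) {
  motion <- match.arg(motion)
  if (n_tracks < 1 || n_frames < 1) stop("need n_tracks >= 1 and n_frames >= 1")
  n_frames <- as.integer(n_frames)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  margin <- max(20, oscillate_radius + 4 * spot_sigma + 2)
  gr <- seq(margin, shape[1] - margin, by = min_spacing)
  gc <- seq(margin, shape[2] - margin, by = min_spacing)
  cells <- expand.grid(row = gr, col = gc)
  if (nrow(cells) < n_tracks) {
    stop(sprintf("cannot place %d tracks with spacing %g in a %dx%d image",
                 n_tracks, min_spacing, shape[1], shape[2]))
  }
  anchors <- as.matrix(cells[sample(nrow(cells), n_tracks), c("row", "col")])

  clamp <- function(p) {
    c(min(max(p[1], margin / 2), shape[1] - margin / 2),
      min(max(p[2], margin / 2), shape[2] - margin / 2))
  }
  base_track <- function(anchor) {
    pos <- matrix(NA_real_, n_frames, 2, dimnames = list(NULL, c("row", "col")))
    if (motion == "oscillate") {
      for (n in seq_len(n_frames)) {
        theta <- stats::runif(1, 0, 2 * pi)
        rad <- oscillate_radius * sqrt(stats::runif(1))
        pos[n, ] <- anchor + rad * c(cos(theta), sin(theta))
      }
    } else {
      theta <- stats::runif(1, 0, 2 * pi)
      step <- drift_speed * c(cos(theta), sin(theta))
      p <- anchor
      for (n in seq_len(n_frames)) {
        pos[n, ] <- p
        p2 <- p + step
        # reflect at the margins so tracks stay in frame
        for (d in 1:2) {
          lim <- c(margin / 2, shape[d] - margin / 2)
          if (p2[d] < lim[1]) { p2[d] <- 2 * lim[1] - p2[d]; step[d] <- -step[d] }
          if (p2[d] > lim[2]) { p2[d] <- 2 * lim[2] - p2[d]; step[d] <- -step[d] }
        }
        p <- p2
      }
    }
    list(birth = 1L, death = n_frames, pos = pos)
  }
  tracks <- lapply(seq_len(n_tracks), function(i) base_track(anchors[i, ]))

  for (ev in events) {
    if (ev$type == "merge") {
      a <- ev$tracks[1]; b <- ev$tracks[2]; f <- ev$frame
      if (f < 2 || f > n_frames) stop("merge frame out of range")
      # b coincides with a from frame f on, and approaches it beforehand
      tracks[[b]]$pos[f:n_frames, ] <- tracks[[a]]$pos[f:n_frames, , drop = FALSE]
      u <- tracks[[b]]$pos[1, ] - tracks[[a]]$pos[f, ]
      u <- if (sqrt(sum(u^2)) < 1e-9) c(0, 1) else u / sqrt(sum(u^2))
      # radii shrink by 0.8*approach_step per frame while the final gap is a
      # full approach_step: the partner's own previous position is then
      # always strictly nearer than the target's, so the pre-merge frames
      # link cleanly and the merge happens on the scripted frame only
      for (n in seq_len(f - 1)) {
        radius <- approach_step * (1 + 0.8 * (f - 1 - n))
        tracks[[b]]$pos[n, ] <- clamp(tracks[[a]]$pos[f, ] + u * radius)
      }
    } else if (ev$type == "branch") {
      a <- ev$track; f <- ev$frame
      if (f < 2 || f > n_frames) stop("branch frame out of range")
      theta <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(theta), sin(theta))
      pos <- matrix(NA_real_, n_frames, 2, dimnames = list(NULL, c("row", "col")))
      for (n in f:n_frames) {
        pos[n, ] <- clamp(tracks[[a]]$pos[f - 1, ] + u * (branch_offset + branch_step * (n - f)))
      }
      tracks[[length(tracks) + 1L]] <- list(birth = as.integer(f),
                                            death = n_frames, pos = pos)
    } else {
      stop("unknown event type: ", ev$type)
    }
  }

  structure(
    list(tracks = tracks, events = events, n_frames = as.integer(n_frames),
         shape = as.integer(shape), spot_sigma = spot_sigma, peak = peak,
         background = background, noise_sd = noise_sd, seed = as.integer(seed),
         motion = motion),
    class = "track_script"
  )
}

#' @export
print.track_script <- function(x, ...) {
  cat(sprintf("<track_script: %d tracks, %d frames, %d events, %s motion>\n",
              length(x$tracks), x$n_frames, length(x$events), x$motion))
  invisible(x)
}

#' Ground-truth position table of a script
#'
#' @param script a [make_script()] result.
#' @return Data frame with columns frame, track_id, row, col — one row per
#'   live track per frame.
#' @export
script_truth <- function(script) {
  if (length(script$tracks) == 0) {
    return(data.frame(frame = integer(0), track_id = integer(0),
                      row = numeric(0), col = numeric(0)))
  }
  rows <- list()
  for (id in seq_along(script$tracks)) {
    tr <- script$tracks[[id]]
    fr <- tr$birth:tr$death
    rows[[id]] <- data.frame(frame = fr, track_id = id,
                             row = tr$pos[fr, 1], col = tr$pos[fr, 2])
  }
  out <- do.call(rbind, rows)
  out[order(out$frame, out$track_id), ]
}

#' Render a script into grayscale frames
#'
#' Each frame is `background` plus the sum of isotropic Gaussian spots of
#' scale `spot_sigma` and amplitude `peak` at the scripted positions, plus
#' seeded additive Gaussian noise, clipped to \[0, 254\].
#'
#' @param script a [make_script()] result.
#' @return List with `frames` (list of [grayscale_frame()]) and `truth`
#'   (the [script_truth()] table).
#' @export
render_movie <- function(script) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(script$seed + 1L)  # distinct stream from the script's own draws

  h <- script$shape[1]; w <- script$shape[2]
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  frames <- vector("list", script$n_frames)
  for (f in seq_len(script$n_frames)) {
    img <- matrix(script$background, h, w)
    for (tr in script$tracks) {
      if (f < tr$birth || f > tr$death) next
      p <- tr$pos[f, ]
      d2 <- (rr - p[1])^2 + (cc - p[2])^2
      near <- d2 < (6 * script$spot_sigma)^2  # truncate far tails for speed
      img[near] <- img[near] +
        script$peak * exp(-d2[near] / (2 * script$spot_sigma^2))
    }
    if (script$noise_sd > 0) {
      img <- img + stats::rnorm(h * w, 0, script$noise_sd)
    }
    img <- pmin(pmax(img, 0), 254)
    frames[[f]] <- grayscale_frame(img, f)
  }
  list(frames = frames, truth = script_truth(script))
}
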