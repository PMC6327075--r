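# vestrack

Single-vesicle tracking for undyed grayscale confocal movies: spot
detection, frame-to-frame trajectory tracing with merge/branch handling,
and per-trajectory kinematics.

## What it does, and for whom

Cell-bound membrane vesicles can be imaged label-free: in a confocal
time-lapse they are point-like bright spots of roughly uniform size on a
dark, noisy background. Because nothing tags an individual vesicle, its
identity over time must be inferred from geometry alone. `vestrack` is for
anyone who has such a movie (a numbered TIFF sequence or a multi-page
stack) and wants, per vesicle: its trajectory, speed, traveling distance,
moving range, and the tracked population.

The pipeline:

1. **Detection** — each frame is convolved with a (sign-flipped, zero-sum)
   Laplacian-of-Gaussian kernel of scale σ, the response is normalized to
   [0, 1] and thresholded, foreground blobs are labeled (iterative flood
   fill, 4- or 8-connectivity), size-filtered, and reduced to centroids.
2. **Linking** — for each consecutive frame pair the full distance matrix
   is built; valid (distance < cutoff) row and column minima classify
   segments as *regular*, *merge* (≥2 previous → 1 current), *branch*
   (1 previous → ≥2 current), *end*, or *begin*. An ascending multi-cutoff
   schedule (default 5, 10, 20 px) freezes matches made at small cutoffs so
   slow vesicles are never stolen by fast interlopers.
3. **Tracing** — trajectories are segment lists `[iframe, pid1, pid2]`;
   merged trajectories are compared by length and only the longest stays
   alive; branches continue the parent along the nearest arm and spawn new
   trajectories for the rest.
4. **Kinematics** — from positions x(n) and frame interval Δt:
   velocity by forward/central/backward differences,
   speed v(n) = ‖v⃗(n)‖, traveling distance s(n) = Σᵢ‖x(i) − x(i−1)‖,
   moving range R(n) = max_{i≤n} ‖x(i) − x(1)‖, plus a life filter that
   removes short-lived noise-born tracks.

A synthetic-movie generator (scripted tracks rendered as Gaussian spots
with seeded noise, including scripted merge/branch events) provides exact
ground truth; the whole pipeline is validated against it. See the vignette
`vignettes/vesicle-tracking.Rmd` for the model, the parameter meanings,
and the design decisions.

## Worked example

```r
library(vestrack)

# a ground-truth movie: 5 vesicles drifting at 1.2 px/frame, mild noise
script <- make_script(n_tracks = 5, n_frames = 15, motion = "drift",
                      drift_speed = 1.2, noise_sd = 8, seed = 42)
movie  <- render_movie(script)

dets   <- detect_sequence(movie$frames, detection_params())
trj    <- trace_all(dets, cutoffs = c(5, 10, 20))
M      <- extract_matrix(trj)
summ   <- summarize_trajectories(M, dets, dt = 0.5, min_life = 3)
print(summ, digits = 3)
#>   trajectory_id life mean_speed final_range final_distance
#> 1             1   15       2.30        12.1           16.9
#> 2             2   15       2.39        16.8           16.9
#> 3             3   15       2.40        16.8           16.9
#> 4             4   15       2.43        16.9           17.0
#> 5             5   15       2.40        16.8           16.9
attr(summ, "population")
#> [1] 5
```

All five scripted tracks are recovered for the full 15 frames. Speeds are
in px/s: the scripted 1.2 px/frame at dt = 0.5 s is 2.4 px/s, and the
recovered mean speeds sit within a few percent of it (the residual is
centroid discretization error). `final_distance` is the path length over
14 steps (≈ 14 × 1.2 ≈ 16.9 px); `final_range` is the net displacement,
smaller for the one track whose drift reflected off the image margin.

## Command line

```sh
Rscript inst/cli/vestrack.R simulate --output_dir run1 --seed 7
Rscript inst/cli/vestrack.R detect   --input run1/frames --output_dir run1
Rscript inst/cli/vestrack.R track    --input run1/frames --output_dir run1
Rscript inst/cli/vestrack.R analyze  --input run1/frames --output_dir run1 --dt 0.5 --min_life 3
Rscript inst/cli/vestrack.R sweep    --input run1/frames --output_dir run1
```

(after installation, the script lives at
`system.file("cli", "vestrack.R", package = "vestrack")`). Outputs are
plain CSV — `detections.csv`, `trj.csv`, `trajectory_matrix.csv`,
`kinematics.csv`, `summary.csv` — with provenance headers. A flat
key=value config file can replace the flags (`--config run.cfg`); any key
can be overridden on the command line. Identical config and input give
byte-identical outputs.

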