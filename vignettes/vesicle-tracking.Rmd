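---
title: "Tracking undyed membrane vesicles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking undyed membrane vesicles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vestrack)
```

## The problem

Membrane vesicles bound to a cell surface can be followed in time-lapse
confocal movies without any fluorescent label: they appear as point-like
bright spots of roughly uniform size against a dark, noisy background, and
their identity across frames has to be inferred purely from geometry —
nothing tags an individual vesicle. The quantities of biological interest
are per-vesicle movement statistics: speed, traveling distance, moving
range (maximum displacement), and the population of tracked vesicles.

`vestrack` implements that pipeline in three stages — per-frame spot
detection, frame-to-frame linking, and trajectory assembly — plus a
kinematics layer and a synthetic-movie generator that provides exact
ground truth for every stage.

## Detection model

Each frame is filtered with a Laplacian-of-Gaussian (LOG) kernel. The
analytic LOG of scale $\sigma$,

$$\nabla^2 G(x,y) = \frac{1}{\pi\sigma^4}
  \left(\frac{x^2+y^2}{2\sigma^2} - 1\right)
  e^{-(x^2+y^2)/2\sigma^2},$$

is negative at its center, so the kernel is sign-flipped to make bright
blobs respond positively, and mean-subtracted so it sums exactly to zero
(a constant frame maps to an identically zero response). The response is
affinely normalized to $[0,1]$, thresholded at `response_lower_bound`
(comparison is `>=`; the boundary pixel belongs to the foreground — a fixed
convention, since either choice is defensible), and the foreground is
partitioned into connected blobs. Blobs smaller than `min_blob_size`
pixels are discarded as noise; each survivor's position is the unweighted
mean of its pixel coordinates. Intensity weighting is not used because the
binarization has already discarded intensity; sub-pixel accuracy on
synthetic spots is nevertheless about 0.1 px RMSE.

Parameters that matter:

| parameter | default | unit | why |
|---|---|---|---|
| `log_sigma` | 2 | px | matched to a spot a few pixels across; set to the apparent spot radius |
| `log_kernel_size` | `2*ceiling(3*sigma)+1` | px | covers the kernel support to 3σ |
| `response_lower_bound` | 0.5 | — | calibrated by eye; `cmd_threshold_sweep()` writes overlay images for tuning |
| `min_blob_size` | 4 | px | roughly the area of the smallest true vesicle |
| `connectivity` | 8 | — | the rim of a round LOG response is often only diagonally connected |

Two nearby spots are separated by the LOG zero-crossing rather than by a
watershed; empirically two $\sigma=2$ spots resolve at a separation of
about $7$ px ($\approx 3.5\sigma$) at the default threshold. Convolution
pads by edge replication, because zero padding manufactures strong spurious
responses along the frame border. Labeling uses an iterative frontier
flood fill — output identical to the classic recursive formulation, but
immune to stack exhaustion on large blobs — with seeds scanned in
row-major order so vesicle indices are deterministic.

## Linking model

For consecutive frames with $P$ and $C$ detections, the $P \times C$
distance matrix holds all pairwise Euclidean distances. Row minima give
each previous vesicle's nearest current neighbor; column minima the
reverse. A minimum is valid when strictly below the cutoff distance (the
maximum plausible per-frame displacement). Segments are the union of all
valid row-minimum and column-minimum links; categories follow from
multiplicity:

* **regular** — a mutual, unique nearest-neighbor pair;
* **merge** — two or more segments sharing one current vesicle;
* **branch** — two or more segments sharing one previous vesicle;
* **end** — a previous vesicle with no valid forward neighbor;
* **begin** — a current vesicle with no valid backward neighbor.

The union rule also covers asymmetric constellations (A's nearest is B,
but B's nearest is a third vesicle): such a non-mutual link always lands
in a merge or branch group rather than being dropped, and "end"/"begin"
reduce exactly to "row minimum invalid"/"column minimum invalid". A
segment can belong to both a merge group and a branch group; its single
label then follows a fixed merge-first priority, which is why the
merge/branch mirror duality is a statement about group structure, not
about individual labels. Equidistant minima break to the smallest index,
for determinism across platforms.

Because vesicle speeds vary widely, a single cutoff is a poor compromise:
small cutoffs lose fast vesicles, large cutoffs mix up slow neighbors. The
multi-cutoff search runs the classification at an ascending schedule
(default `c(5, 10, 20)` px; the original values were experiment-calibrated
and not published), freezing matches made at smaller cutoffs and removing
those vesicles from later levels. Ascending order with freeze-and-remove
is a design choice: it gives slow-vesicle links precedence, which is the
stated motivation for multiple cutoffs in the first place. One documented
consequence: a merge whose two arms have very different lengths (one arm
below the first cutoff, the other above it) is resolved as a regular link
plus a separate event rather than as a merge, because the short arm is
frozen before the long arm is considered. Event geometry in the synthetic
generator keeps both arms within one level for this reason.

## Trajectory store

A trajectory is an ordered list of segment rows `[iframe, pid1, pid2]` —
frame index plus vesicle indices in the previous and current frame (0 =
absent). Indices are per-frame because the detector numbers vesicles
independently in each image. The tracing loop per frame: link, resolve
merges among live tails, insert.

Decisions where the design was genuinely open:

* **Frame-1 seeding.** Every first-frame detection becomes a trajectory
  head with `pid1 = 0`.
* **Merge resolution.** Live trajectories sharing an identical tail are
  compared by number of stored rows; only the longest survives, ties to
  the lowest id. Losers stay in the store marked dead, so population
  counts and the trajectory matrix still show them; their matrix row
  simply stops at the merge column. Resolution runs at the start of each
  frame iteration and once more after the last frame.
* **Branch continuation.** The parent continues along the
  smallest-distance arm (ties to the smaller vesicle index); every other
  arm spawns a new trajectory whose head row records the branch point
  (`pid1 > 0`). This preserves the longest coherent path deterministically.
* **End segments.** A trajectory that receives no valid link is marked
  dead without storing a `pid2 = 0` row, so every stored row carries a
  resolvable vesicle index and coordinate extraction needs no special
  case. The trajectory matrix is identical either way.

## Kinematics

For a trajectory's positions $x(n)$ (px) at frame interval $\Delta t$ (s):

$$v(n) = \begin{cases}
 (x(2)-x(1))/\Delta t & n = 1\\
 (x(n{+}1)-x(n{-}1))/2\Delta t & 1 < n < N\\
 (x(N)-x(N{-}1))/\Delta t & n = N
\end{cases}$$

speed is $\lVert v(n)\rVert$; traveling distance $s(n)$ is the cumulative
path length; moving range $R(n)$ is the running maximum of
$\lVert x(i)-x(1)\rVert$. Always $R(n) \le s(n)$, both non-decreasing. The
central stencil is exact for quadratic motion at interior samples; all
three stencils coincide on uniform motion.

The per-trajectory summary reports **mean speed as the mean of the speed
magnitudes**, not the magnitude of the mean velocity — the vector mean of
an oscillating vesicle is near zero and would be meaningless. Life-1
trajectories have undefined velocity; they are reported with null
kinematics rather than failing the batch, since they are precisely the
noise-born tracks the life filter (`min_life`, default 3 frames) removes.
Positions are in px and dt in seconds, so speeds are px/s; an optional
`pixel_size` (µm/px) adds converted output columns without changing any
internal value. `dt` defaults to 1.0 s with a loud run-time warning,
because the acquisition interval is experiment-specific and silently wrong
speeds are worse than a nag.

## The synthetic generator

`make_script()` scripts tracks (oscillation within a small radius, or
constant-speed drift with reflection at the margins) on a jittered anchor
grid honoring a minimum spacing, with optional merge and branch events;
`render_movie()` renders isotropic Gaussian spots of scale `spot_sigma`
plus seeded additive Gaussian noise, clipped to $[0, 254]$ — the intensity
range of the target acquisition format. Fixed seed gives byte-identical
movies.

Event geometry is constrained by the detector's resolving power: a merge
partner approaches its target along radii that shrink by
`0.8 * approach_step` per frame with a final gap of one full
`approach_step` (default 8.5 px), so (a) the pre-merge pair stays above
the ~7 px resolving separation and detection collapses them exactly on the
scripted frame, and (b) each partner's own previous position is strictly
nearer than the target's, so no spurious branch precedes the merge. A
branch child appears `branch_offset` (9 px) from its parent and recedes at
`branch_step` (3 px/frame). Both arms of an event stay below one linking
cutoff level (use a first cutoff of 10 px for event movies).

What the generator does **not** emulate: photobleaching, point-spread
asymmetry, camera-specific (Poisson/readout) noise, intensity variation
between vesicles, background structure from the cell body, and focal
drift. A green end-to-end test therefore establishes that the algorithms
are implemented correctly against their own model of the data — not that
the default parameters suit any particular microscope; the threshold sweep
and the cutoff schedule must still be calibrated per experiment.

## Numerical and interface conventions

* Coordinates are 1-based `(row, col)`, row increasing downward, in every
  structure and CSV (recorded in each CSV header).
* Intensities are kept in $[0, 254]$, matching the acquisition format's
  stated range; 8- and 16-bit TIFF are both accepted and never rescaled.
* Only uncompressed TIFF is supported on disk (single- or multi-page);
  the package carries its own minimal baseline codec so it runs with no
  image-IO dependency. PNG is not supported.
* Degenerate inputs: a constant frame yields zero detections with a
  warning; an empty previous (current) frame makes every current
  (previous) vesicle a begin (end); a single-frame movie produces
  one-row trajectories with null kinematics.

## Known limitations

Links are made only between consecutive frames: a vesicle lost for one
frame returns as a new trajectory (no gap closing). Assignment is
nearest-neighbor with cutoffs, not a global optimum (no Hungarian
algorithm) and has no motion model (no Kalman prediction). Touching
vesicles below the resolving separation are one blob — the merge/branch
machinery, not a splitting step, accounts for them.
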