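---
title: "Acoustic–optical fish sizing: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Acoustic–optical fish sizing: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A monocular camera measures fish in pixels; without depth those pixels are
meaningless in meters. An echosounder measures range precisely but knows
nothing about shape. aosizer combines the two: the echogram supplies, for
each fish pass, a *trace* whose fitted range line gives `Z(t)`, and the
camera supplies per-frame silhouette measurements `y(t)` in pixels. The
pinhole relation `Y = y·Z/f` then yields metric sizes, aggregated per fish
with a trimmed mean over the tracked frames, and the model length is
converted to snout–fork length with the published linear relation
`SFL = 1.0312·ML + 0.065641` (meters). The fish is assumed roughly
perpendicular to the camera axis; a swimming tilt of θ foreshortens the
projection by cos θ, which is why tilted fish must be detected (via the
acoustic STI) and discarded.

## Coordinate and unit conventions

* Images are numeric matrices, row = y (downward), column = x (rightward),
  1-based, pixel centers at integer coordinates. Angles are degrees in
  image coordinates; headings lie in (−180, 180].
* Echograms store pings as rows and range samples as columns; all indices
  are 1-based (R convention). Cell (p, s) covers the half-open time and
  range intervals starting at its grid point.
* The STI is expressed in meters per ping. The interval bounds used by the
  tilt filter are therefore *relative to the acoustic configuration*; see
  "Tilt and the STI gain" below.

## The deformable silhouette model

`M = [sx, sy, l, α, θb, w, lp, sp]`: snout tip position, spine arc length,
head angle, global bending, widths vector (head→tail, `w[1]` maximal),
and the caudal closing segment (length `lp`, slope `sp`). Design choices
where the model family was genuinely open:

* **Spine as a circular arc.** A single global bending angle admits a
  one-parameter curvature family; the arc is the minimal such model. The
  tangent turns linearly from α to α + θb along the arc.
* **Width profile.** `w` has a configurable length (default 6) applied at
  fixed spine fractions 0.20 … 0.97; a natural cubic spline through
  (0, 0), the stations, and (1, lp/2) gives the half-width profile. The
  profile is linear in the knot values, which the fitter exploits via a
  precomputed spline basis.
* **Caudal peduncle.** The silhouette is closed at the tail by a straight
  segment of length `lp` rotated by `atan(sp)` about the spine normal; the
  peduncle is *excluded* from the spine length, which is why the SFL
  relation has a positive slope above 1 and a positive intercept.

## Fitting: objective, initialization, determinism

The published score is the FEI: mean squared distance from model contour
points to their nearest edge point, normalized by `l²`. Two numerical
facts drove the implementation:

1. **The one-directional FEI is nearly flat in `l`.** A slightly shorter
   model can place its whole contour on the true boundary, so minimizing
   FEI alone biases spine length by several percent. The optimizer
   therefore minimizes the *symmetrized* chamfer distance (model→edge plus
   edge→model, both normalized by `l²`); the reported acceptance score
   remains the FEI as defined.
2. **Edge pixels sit inside the continuous outline.** Boundary-pixel
   centers lie ~0.5 px inside the true silhouette boundary, shrinking
   naive fits. The model outline is inset by 0.5 px (spine and widths)
   before comparison, removing the bias.

Initialization is deterministic from the edge cloud's principal axis
(position, length, orientation, a quadratic midline fit for bending, and
binned half-widths); the head/tail ambiguity is resolved by evaluating the
objective on both orientations. Refinement is Nelder–Mead (a pose-only
stage, then all parameters), so identical inputs give identical fits — no
randomness anywhere in the fitting path. Acceptance uses `FEI ≤ 0.002`
(normalized), a default chosen so clean renders pass with a wide margin
while grossly wrong fits fail.

## The synthetic world

The generator emulates the stated observation conditions: fish of SFL
0.5–1 m (width 0.24·SFL), ranges 2–6 m, 20 pings/s, 35 fps, a 7° nominal
beam, a bright uniform back panel with Gaussian noise and darker fish.
Fish travel in straight image-plane lines at constant speed (2.5–3.5
px/frame), with mild body bending (±10°); their spine length in pixels is
`ML·cos(tilt)·f/Z(t)` with `ML = (SFL − 0.065641)/1.0312`, so the rendered
fish *is* a realization of the deformable model family. Consequences for
interpreting green tests:

* Round-trip accuracy bounds reflect rasterization and optimizer error,
  not model mis-specification; real fish deviate from the template, and
  the FEI acceptance threshold is what guards against that in practice.
* Segmentation is exercised with ideal contrast (levels 210 vs 60, σ = 3).
  Turbidity, lighting gradients and reflections are out of scope.
* The echogram trace is a thickened band (≥5 samples) around the range
  line with Gaussian jitter (σ = 1 cm) — no beam pattern, TS-vs-length or
  scattering physics.

**Tilt and the STI gain.** The trace range line has slope
`gain·tan(tilt)` m/ping. The default gain is the physically consistent
`speed/ping_rate`, which makes the acoustic range line identical to the
optical `Z(t)` — required for end-to-end fusion correctness. With that
gain the STI magnitudes are on the order of 10⁻³ m/ping, so the interval
bounds 0.3/0.4 keep everything; this matches the finding that the paper's
intervals are unitless labels tied to its own acoustic configuration. For
the acoustic-only classification experiment the generator is configured
with `sti_gain = 2.0`, chosen a priori so the 10° class boundary maps to
STI ≈ 0.35 — between the two studied interval bounds and of the same
order as the printed example STIs (0.07 and 0.53). Neither value was tuned
against test outcomes.

## Numerical and procedural choices

* **Otsu** maximizes between-class variance over 256 equal-width bins of
  the dB values (a dB echogram is what gets displayed and thresholded);
  ties take the first maximum; the threshold is the bin edge, foreground
  is `≥` threshold.
* **Solidity** divides cell count by the area of the convex hull of the
  cells' unit squares (hull over the 4 corners of every cell). This gives
  exactly 1.0 for solid rectangles and 6/7 for the 3-cell L, and keeps
  solidity ≤ 1 always.
* **Isolation** inflates each trace to a 1000 ms × 8 m rectangle centered
  on its time center and mean range; any intersection with another
  trace's extent discards *both* (order-independent).
* **Trimming** acts on the per-entry metric values `y_i·Z_i/f` (outliers
  are defined in meters, where the sum of the published trimmed mean
  lives), sorted ascending — the printed formula indexes `p+1 … n−p`,
  which only makes sense on ordered values. Default `p = ⌊0.1·n⌋` per
  tail; the paper leaves `p` free. Width uses the same machinery as
  length ("sized in two dimensions").
* **Frame→ping association** takes the nearest ping by timestamp; the
  range is then the trace's fitted line evaluated at that ping
  (extrapolation allowed within the window).
* **Tilt classification** uses closed-interval membership (the intervals
  are printed as closed), and the classifier is a pluggable function —
  the CNN alternative of the study is out of scope, its interface is not.
* **Beam projection** is a disk of constant angular radius
  `narrowing·f·tan(half-angle)` whose center follows the extrinsic
  calibration table (principal point when co-axial). Spatial
  correspondence is pixel-level disk intersection — grazing counts.
* **Region of interest.** Blobs whose bounding box lies farther from the
  beam axis than `radius + margin + blob half-length` are skipped before
  fitting: such fish can never intersect the beam disk, so no sizing
  result can change. This, together with the acoustic trigger (vision
  runs only inside the 1 s windows), is the package's computational
  analog of the study's throughput argument, and is validated as an
  equivalence property (windowed vs all frames), not as a wall-clock
  claim.

## Known limitations

* The vision stage assumes the ventral perspective and the model's
  bilateral symmetry; dorsal use would work unchanged, lateral would not.
* Overlapping fish merge into one blob; such frames simply contribute no
  accepted fit, and two candidate tracks in one beam window discard the
  trace ("never guess").
* Fits near the image border are flagged (`truncated`) but not corrected.
* The tilt filter's intervals must be calibrated to the acoustic
  configuration (ping rate, fish speed); the defaults are only meaningful
  relative to the synthetic gain documented above.
* Rendering has no anti-aliasing; sub-pixel accuracy below ~0.5 px per
  edge is not claimed, which bounds the round-trip criteria.

## On-disk formats

Scenes are plain text: echogram as CSV plus a JSON sidecar (timestamps,
sample ranges), frames as ASCII PGM (P2) with a CSV timestamp manifest,
truth and results as CSV, calibration and run manifests as JSON (no
HDF5/PNG writers are assumed available). Run manifests store the
configuration, its hash and per-stage counts, making reruns comparable.
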