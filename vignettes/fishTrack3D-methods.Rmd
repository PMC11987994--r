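---
title: "Motion-gated two-view fish tracking: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-gated two-view fish tracking: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishTrack3D)
```

## The problem

A single fish swims in a rectangular glass tank filmed at one frame per
second by two orthogonal cameras: one facing the front wall, one looking
straight down. Each camera delivers a 2D projection of the fish's position;
combined, they give a full 3D trajectory from which locomotor endpoints —
per-second speed, windowed speed means, cumulative swim distance, spatial
occupancy — can be derived and compared between treatment groups (the
motivating application is behavioural suppression of juvenile sturgeon under
ammonia exposure). The package implements the whole chain: per-frame
detection, two-view fusion, trajectory metrics, nonparametric group
statistics, and a synthetic scene generator that provides ground truth for
validating every stage without real footage.

## Coordinate conventions and calibration

The tank frame is right-handed with the origin at the front-left-bottom
corner: X along the 540 mm long side, Y up from the tank bottom, Z along the
370 mm short side. The usable Y extent is the 200 mm water column, not the
400 mm wall height — the fish cannot occupy dry glass, and using water
height makes vertical occupancy plots directly interpretable. The front view
images X and Y; the top view images X and Z. Both views therefore measure X
independently, which is what makes fusion (and a per-frame quality check)
possible.

Calibration is a per-axis linear map between a crop rectangle (ROI, 0-based,
half-open) and the tank extents, with the front view's vertical axis flipped
so that image row 0 is the water surface. Pixel coordinates are continuous,
with pixel $(u, v)$ covering $[u, u+1) \times [v, v+1)$; this single
convention is used by the renderer, the blob centroid and all tests. No
lens-distortion or water-refraction model is applied: the cameras sit 80–95
cm from a 54 cm tank, and without measured intrinsics a refraction model
would add unverifiable precision. The approximation is logged as such, and
mapped coordinates that overshoot the tank by a pixel's worth (edge
detections can) are clamped and flagged rather than rejected.

## Per-frame detection

Detection reproduces a classical motion-gated pipeline, stage by stage:

1. **Reference subtraction.** The per-pixel absolute difference against an
   empty-tank reference image removes everything static — tank, lighting,
   and critically any constant camera reflection in the glass. The
   difference is converted to luminance.
2. **Dense optical flow.** Displacement between consecutive difference
   images is estimated with a polynomial-expansion model: each
   neighbourhood is approximated by a local quadratic under a Gaussian
   applicability, and the displacement that maps one expansion onto the
   other is solved by windowed least squares, coarse-to-fine over an image
   pyramid with bilinear warping. At 1 frame/s the fish moves tens of
   pixels between frames; the pyramid (4 levels by default) is what makes
   such displacements recoverable. Implemented in C++ (`src/flow.cpp`);
   brightness offsets cancel in the linear term, so global illumination
   changes produce essentially zero flow (tested).
3. **Motion mask.** Pixels with flow magnitude $\ge$ 1 px/frame (inclusive
   threshold) count as moving.
4. **Edges and dilation.** The difference image is gated by the motion mask
   and passed to Canny edge detection (Gaussian $\sigma = 1$, Sobel
   gradients, non-maximum suppression, 50/150 hysteresis), then dilated
   twice with a 3×3 disc brush so the fish outline closes into a solid
   region. Gating the *grayscale* rather than the flow magnitude keeps the
   measured shape anchored to the current frame's silhouette: the flow blob
   spans old and new positions, but the reference-subtracted image only
   shows the fish where it is now. This choice is switchable in principle
   but is the default because it measurably centres the blob on the true
   position.
5. **Blob measurement.** The largest 8-connected component with at least 50
   px is enclosed in the convex hull of its pixel squares — the minimal
   convex polygon covering the detected area. The hull's area centroid is
   the fish position (sub-pixel), its area the fish's apparent size, and
   the long side of its minimum-area enclosing rectangle the orientation,
   reported in $[0°, 180°)$. Equal-area ties break deterministically
   (uppermost-leftmost bounding box).

Detection is deliberately *motion-gated*: an immobile fish produces no flow
and therefore `status = "missing"`. This is not a failure mode but a
semantic choice — no motion means no displacement — and the fusion stage
fills such gaps by carrying the last known position forward with zero speed
contribution. It is conservative in exactly the right direction for studies
whose endpoint is reduced movement: measured motion is never invented.

Default thresholds (flow ≥ 1 px, Canny 50/150, 3×3 brush × 2, min area
50 px) are standard starting points for 8-bit footage; the synthetic
acceptance suite pins the resulting behaviour. All are overridable per run.

## Fusion and the carry-forward rule

Detections from the two views taken at the same second are joined on the
exact timestamp (duplicates are an error naming the offending time;
one-sided gaps are reported). For a matched pair, X is the mean of the two
views' estimates with the absolute disagreement logged as `x_delta_mm` — a
per-frame quality signal; discrepancies above 50 mm warn but do not reject.
Y comes from the front view, Z from the top view. If either view is missing
the previous point is repeated (`source = "carried"`); leading missing pairs
before the first full detection are dropped. Because the first frame has no
flow predecessor, a track always starts one second into the footage.

## Trajectory metrics

Speed at point $i$ is the 3D Euclidean step distance divided by the elapsed
time, with speed 0 at the first point by convention. That convention is
load-bearing: a 10-hour, 1 Hz experiment then yields exactly 36,000 speed
samples and, after averaging over non-overlapping 10-second windows (the
statistical unit; trailing partial windows are dropped), exactly 3,600
windowed means — the count the downstream statistics are built around. The
alternative (35,999 displacement values) cannot produce 3,600 full windows.
Total distance is the integral of speed over time; occupancy grids are 3D
histograms of positions over time slices (default two-hour), conserving
point counts.

## Group statistics

Windowed mean speeds are compared across groups with a nonparametric
battery:

- **Descriptives**: mean, sample SD ($n-1$), extrema per group.
- **KS screen**: one-sample Kolmogorov–Smirnov against a normal with the
  sample's own mean and SD. With estimated parameters this test is
  anti-conservative (the Lilliefors effect); it is used only as a gate for
  choosing nonparametric tests, never as an inference surface, and the
  package documents rather than corrects the bias.
- **Kruskal–Wallis** omnibus (via `stats::kruskal.test`), tie-corrected,
  $\chi^2$ approximation with $k-1$ df. The fully tied sample is defined as
  $H = 0$, $p = 1$.
- **Dunn post hoc with Bonferroni**: pairwise z-statistics on mean ranks
  with tie correction, two-sided p multiplied by $k(k-1)/2$ (6 for four
  groups) and capped at 1; unit diagonal; $\alpha = 0.05$. It is computed
  unconditionally with the omnibus significance stored alongside, so the
  caller can apply the conventional "only after a significant omnibus"
  sequence without recomputation.

No installed package provides the Dunn test, so it is implemented from the
standard formulas and cross-checked in the tests against a brute-force
oracle that sorts, mid-ranks and enumerates tie groups explicitly
(agreement to $10^{-10}$ on random instances, as is the Kruskal–Wallis H).

The synthetic group generator draws from normals truncated at zero. Its
default template is the four-group effect pattern of the motivating study
(means 91.24/83.87/52.11/24.22 mm/s, SDs 39.90/23.88/22.95/9.34, n = 3600
per group): at that size the battery flags every pair involving the two
higher doses in essentially all replicates, which is the qualitative
pattern the package's power harness asserts. The published
control-vs-lowest-dose non-significance depends on the real data's
dependence structure and is deliberately not asserted.

## The synthetic scene generator

The generator exists so the full pipeline can be validated end-to-end with
known truth. It has two halves.

**Motion.** A bounded correlated random walk at 1 Hz: horizontal heading
with wrapped-normal increments of sd $(1-\text{persistence})\pi$
(default persistence 0.92), a mean-reverting pitch whose set point encodes
a bottom/surface preference, zero-truncated normal step speeds, reflecting
walls with a 25 mm stand-off (so the rendered body never clips the view
edge), and an optional attractor point. The attractor plus a surface-shifted
pitch implement `doseProfile()`: suppression scales mean speed by
$(1-s)$; aggregation pulls the fish toward a near-surface point in the
upper-rear region — the late-exposure confinement pattern seen under high
doses. The MotionConfig carries the attractor fields explicitly because
confinement is not expressible through speed and bias alone. Simulated
speeds default to ~15 mm/s so that, at the rendered scales below, per-frame
image displacement stays within the flow pyramid's range; this coupling
between capture rate, speed and pyramid depth is a real constraint of
1 frame/s footage, not an artifact of the simulator.

**Rendering.** Orthographic projection (consistent with the linear
calibration): the fish is a filled ellipse (default semi-axes 18×7 px)
oriented along its projected heading, dark on a lighter background, drawn
at `mmToPx(position)` in each view; an optional static bright patch is
drawn identically in every frame *and* the reference, emulating a constant
camera reflection; optional i.i.d. Gaussian pixel noise is added last.
Frames can be rendered in memory or streamed to timestamp-named grayscale
PNGs (`YYYYMMDD_HHMMSS.png`), which is also how multi-hundred-frame
validation scenes stay within memory.

What the generator does *not* emulate — perspective, refraction at the
water surface, caustics and moving glints, body articulation and shape
change, multi-fish occlusion — bounds what passing tests show: they
validate the geometry, the estimator chain and the statistics, not
robustness to real-world optics. The static-reflection test covers the one
optical nuisance the reference-subtraction design specifically claims to
handle.

## Numerical choices and degenerate inputs

- Flow solves its 2×2 systems with a $10^{-6}$ ridge; prev == cur yields
  magnitudes at machine-zero level.
- The motion threshold is inclusive (≥), pinned by test.
- Blob ties, hull orientation and the continuous pixel convention are fixed
  as above and oracle-tested; hull areas of pixel squares are exact
  (multiples of ½).
- Empty masks, all-missing sequences and empty time slices produce typed
  "missing"/empty results, never errors; duplicate timestamps, shape
  mismatches, non-monotone time and degenerate SDs fail loudly.
- Single-observation groups report SD 0 with a warning rather than NA, so
  descriptive tables stay rectangular.
- All simulation is seed-deterministic; identical config + seed gives
  byte-identical CSV outputs (tested), with plots excluded.

## Validation scales

The test-bench validates at reduced scale to keep runs fast: tracking
recovery uses a 600-frame, 640×360 two-view scene (detection rate,
mean fused position error in px-equivalents, distance recovery within 5%),
static-artifact rejection uses 100 frames, the type-I simulation uses 2,000
four-group replicates at n = 100, and the dose–response harness renders
240-frame scenes at suppression {0, 0.1, 0.45, 0.75} plus a 200-replicate
power simulation at the full n = 3600 template. Full-resolution
(1920×1080) footage runs through the identical code path; only the pixel
scales change.

## Known limitations

Single fish only — no identity maintenance, no occlusion handling. No
camera-intrinsic or refraction calibration. The flow estimator assumes the
inter-frame displacement is within the pyramid's reach (~60 px at default
settings); faster subjects need more levels or a higher capture rate. The
carry-forward rule underestimates distance when the subject moves below the
flow threshold for long spans; this bias is conservative for
suppression-type endpoints and is quantified by the recovery tests. The KS
screen's estimated-parameter bias is documented, not corrected. The 1 Hz
statistics treat 10-s windows as exchangeable units; autocorrelation-aware
modelling is out of scope.
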