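# fishTrack3D

Non-invasive tracking of a single fish in a rectangular glass tank filmed
at 1 frame/s by two orthogonal cameras (front and top), with 3D trajectory
metrics and nonparametric group statistics. The package targets behavioural
assays in which locomotor activity is the endpoint — the motivating
application is suppression of swimming in juvenile sturgeon
(*Acipenser gueldenstaedtii*) under increasing ammonia doses — and includes
a synthetic two-view scene generator with known ground truth so the entire
pipeline is testable without any real footage.

## Method

Per-frame detection is motion-gated and uses no learning:

1. subtract the empty-tank **reference image** (removes the tank, lighting
   and any constant camera reflection), convert to grayscale;
2. estimate **dense optical flow** between consecutive frames with a
   polynomial-expansion model (local quadratic fits under a Gaussian
   applicability, solved coarse-to-fine over an image pyramid) — at 1
   frame/s the fish moves tens of pixels per frame;
3. threshold the flow magnitude into a **motion mask** (default ≥ 1
   px/frame);
4. run **Canny edge detection** on the motion-gated difference image and
   **dilate** (3×3 disc, ×2) until the outline closes;
5. enclose the largest 8-connected component in its **convex hull**: hull
   centroid = position (sub-pixel), hull area = apparent size, long side of
   the minimum-area enclosing rectangle = orientation.

Front and top detections at the same second are fused into millimetre 3D
coordinates (X = mean of both views with the disagreement logged, Y from
the front view, Z from the top view); missing detections — an immobile fish
produces no flow — carry the last position forward with zero speed. Speeds
are per-second Euclidean steps ($v_0 = 0$, so 10 h at 1 Hz gives 36,000
samples), reduced to non-overlapping 10-s window means (3,600 per
experiment) that feed the statistical battery: descriptives, a one-sample
Kolmogorov–Smirnov normality screen, the Kruskal–Wallis omnibus test and
Dunn's post hoc test with Bonferroni correction ($\alpha = 0.05$).

## Worked example

Simulate a one-minute swim, render both views, track, fuse and measure:

```r
library(fishTrack3D)

geom  <- TankGeometry()                      # 540 x 370 x 400 mm, 200 mm water
scene <- SceneConfig(geom, width_px = 640, height_px = 360)
mc    <- MotionConfig(duration_s = 60, mean_speed_mm_s = 15,
                      speed_sd = 4, seed = 42)

gt   <- simulateTrajectory(mc, geom)
r    <- renderViews(gt, scene)
detF <- trackFrames(r$front, r$reference_front, scene@cal_front)
detT <- trackFrames(r$top,   r$reference_top,   scene@cal_top)
track <- fuseTracks(matchByTimestamp(detF, detT),
                    scene@cal_front, scene@cal_top, geom)
track
#> FishTrack: 59 points, 58 s span, 0 carried (0.0%)

speeds <- stepSpeeds(track)
sprintf("total distance: %.1f mm (truth %.1f mm)",
        totalDistance(speeds), gt$distance_mm)
#> "total distance: 812.2 mm (truth 828.8 mm)"
head(windowMeans(speeds, 10), 3)
#>   window_index mean_speed_mm_s
#> 1            1        13.11429
#> 2            2        13.82799
#> 3            3        14.66174
```

The track has 59 points because the first frame has no flow predecessor;
the recovered distance sits within 2% of the simulated truth. Group
statistics on four synthetic dose groups (zero-truncated normals with the
study's effect-size template, n = 3600 windows each):

```r
g   <- synthSpeedGroups(n = 3600, seed = 1)
rep <- statsReport(g)
rep$descriptives
#>     group    n  mean     sd    min    max
#> 1 control 3600 93.24 39.507 0.0591 243.27
#> 2     100 3600 83.29 23.760 6.6753 170.42
#> 3     200 3600 52.70 21.771 0.1649 129.61
#> 4     400 3600 24.13  9.187 0.1034  59.04
rep$omnibus$H            # 8378.8 on 3 df, p far below any alpha
signif(rep$pairwise$p.adjusted["control", ], 3)
#>  control      100      200      400
#> 1.00e+00 4.86e-04 0.00e+00 0.00e+00
```

Every pair involving the two higher doses is flagged; mean speed and its
spread fall monotonically with dose.

A thin command-line wrapper over the same functions ships in
`inst/scripts/fishtrack3d` (subcommands `simulate`, `track`, `fuse`,
`stats`, `report`, `all`, driven by a YAML config).

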