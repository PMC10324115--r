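# comflow

Quantifies segmental left-ventricular wall motion from echocardiogram-like
grayscale image sequences. The package implements a confidence-optimized
multiresolution (COM) optical-flow estimator together with everything
needed to turn dense flow into clinically interpretable per-segment
displacement curves: wall-segment geometry, radial/circumferential motion
decomposition, dynamic ROI tracking, wall-motion grading, flow-error
metrics, and a ground-truth phantom simulator.

## The method

Dense motion between consecutive frames is estimated coarse-to-fine: an
exponential-scale image pyramid (coarsest level 30 % of the original size)
is traversed from coarse to fine, and at each level the accumulated flow
warps the second frame toward the first ("image correction") before a
linearized brightness-constancy + quadratic-smoothness increment
*(du, dv)* is solved. The level's flow is updated as

    u <- u + s * du ,   v <- v + s * dv ,

where *s* ∈ [0, 1] is a per-pixel confidence map: the level-1 wavelet
approximation of the level's image, reconstructed and min–max normalized.
Low-information regions — acoustic shadows, dropout — receive small *s*,
damping unreliable updates. The per-level energy uses a local–global data
term (a Gaussian-integrated motion tensor, scale `rho`) solved by
Jacobi-preconditioned conjugate gradients; with *s* ≡ 1 the estimator is
the plain pyramid warping flow, and single-level Horn–Schunck and
Lucas–Kanade baselines are included for comparison.

Wall motion is then extracted per segment: a traced endocardial contour is
split into 6 (or 12) equal-arc segments, each with a circumferential
tangent *t* and a cavity-directed radial normal *n*; the flow over each
segment's ROI is projected onto *n* (positive = contraction), the ROI is
advected along the flow so it follows the moving wall, and the cumulative
mean radial displacement per frame gives the segment's motion curve.
Peak displacement in millimetres maps onto the clinical grading scale
(> 5 mm grade 0, 2–5 mm grade 1, 0–2 mm grade 2, negative grade 3).

Flow accuracy is measured as endpoint RMSE (px) and mean space-time
angular error (degrees) over the wall ROI against the phantom's exact
ground truth.

## Worked example

```r
library(comflow)

## ground-truth phantom: left wall +2 px, right wall -2 px, all 1 px down,
## acoustic shadow over the right wall
gp <- phantom_experiment(shadow = TRUE)
run_comparison(gp)
#>        method rmse_px ae_deg n_pixels
#> 1     pyramid  0.6149  10.05     7546
#> 2    com-gray  1.3280  15.36     7546
#> 3 com-wavelet  1.4209  15.32     7546
#> 4          hs  1.6166  38.86     7546
#> 5          lk  1.8552  44.90     7546
```

Each row is one estimator run on the same frame pair and evaluated over
the wall region: the multiresolution variants are 2–3× more accurate than
the single-level Horn–Schunck / Lucas–Kanade baselines, whose single
linearization cannot follow the 2-pixel wall excursion. (On this
textureless binary phantom the confidence-off `pyramid` row is the most
accurate variant — see the methods vignette for why the confidence
reweighting needs speckle-bearing tissue to pay off. Without the shadow it
reaches 0.177 px RMSE and 2.86° angular error.)

```r
## segmental displacement curves over a simulated contraction-relaxation cycle
p <- make_u_phantom(160, 160, wall_thickness = 14, cavity_width = 40)
segs <- split_six(phantom_contour(p), p$wall_mask)
cyc <- synth_cycle(p, n_frames = 12, peak_left_dx = 2, peak_right_dx = -2,
                   peak_dy = 1)
curves <- track_sequence(cyc$seq, segs,
                         flow_fn = function(a, b)
                           com_flow(a, b, use_confidence = FALSE))
curves
#> segment_curves: 6 segments over 12 frames (1 mm/px)
#>   segment peak_mm grade
#> 1       1   2.007     1
#> 2       2   1.997     2
#> 3       3   0.503     2
#> 4       4   0.476     2
#> 5       5   1.995     2
#> 6       6   2.007     1
```

`peak_mm` is each segment's peak cumulative radial displacement (here in
pixels, since `mm_per_px = 1`): the basal and mid segments on both limbs
recover the simulated ~2 px contraction to well within 2 %, while the two
apical segments move mostly downward with the whole wall and so have small
radial peaks. With a real calibration of, say, 2.5 mm/px the ~2 px peaks
correspond to ~5 mm of motion at the normal/reduced boundary.
`plot(curves)` draws the per-segment arches; `write_curves()` exports a
tidy CSV.

A thin command-line front end with `simulate`, `flow`, `compare` and
`curves` verbs is installed at `inst/cli/comflow.R`.

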