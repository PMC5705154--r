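# hyoidtrack

Semi-automatic tracking, smoothing, calibration and phase segmentation of
hyoid bone motion in videofluoroscopic swallowing studies (VFSS).

The hyoid bone's elevation and anterior excursion during a swallow are key
kinematic markers of swallowing function: reduced excursion is associated
with dysphagia and aspiration. Extracting the trajectory by clicking every
frame of a fluoroscopy loop is slow and tiring, and naive trackers lose the
hyoid when the mandible sweeps over it. `hyoidtrack` is for clinicians and
dysphagia researchers who want the full measurement chain — from a directory
of fluoroscopy frames to calibrated, phase-segmented swallow loops and
agreement statistics — as a tested R package with a matching command-line
tool.

## The method

Each seeded anatomical point (hyoid target, two mandible-edge points, the
anterior-inferior borders of C2 and C4) carries a square ROI that is matched
frame-to-frame on its Sobel edge characteristics. The matching error for a
pose with shift (x̃, ỹ) and rotation θ̃ about the template centre is

    Δ(x̃, ỹ; θ̃) = (1/N) Σ (Ex_ref − Ex_cur)² + (Ey_ref − Ey_cur)²

summed over the N retained template pixels and minimized over a bounded box
(±5 px, ±2.5°) by a coarse grid plus simplex refinement. When the mandible
chord — the line through the two tracked mandible points — crosses the hyoid
ROI, the masked part is clipped from both template and current ROI, so the
average runs over the visible pixels only and tracking survives the
occlusion. A third-order motion predictor flags tracking failures (deviation
≥ 8 px), which can be resumed from a corrected seed.

Raw tracks are denoised with cubic smoothing splines
(p·Σresid² + (1−p)·∫f″², default p = 0.3) and calibrated into the
patient-centric frame: origin at C4, +y toward C2, anterior +x, distances in
cervical units (CU = |C2−C4| px, recomputed each frame), yielding the six
standard variants Raw / RawNC / RawNCC / Smo / SmoNC / SmoNCC. One swallow
loop is then segmented at the three interior local minima of the velocity
amplitude v(t) = √(x′² + y′²) with the highest splitting scores
SS = FSS + BSS, where FSS/BSS measure the velocity drop relative to the
neighbouring maxima — giving the elevation, anterior-movement, descending
and returning phases.

A ground-truthed synthetic phantom (moving hyoid blob, vertebral landmarks,
occluding mandible band, head motion, noise) stands in for clinical videos
throughout the tests, and agreement statistics (range of motion, relative
errors, per-axis Pearson r, ICC(A,1) for two raters) reproduce the usual
validation tables.

## Worked example

Simulate a default phantom swallow (90 frames, 30 fps, 256×256 px, 5-frame
mandible occlusion), track all five points from their first-frame positions,
calibrate, and segment:

```r
library(hyoidtrack)
library(dplyr)

sim   <- simulate_vfss(phantom_spec(seed = 1))
seeds <- sim$truth$trajectories |> filter(frame == 0) |> select(point, x, y)
run   <- track_sequence(sim$frames, seeds)
run
#> <vfss_track> 90 frames, 5 points (C2, C4, hyoid, mandible1, mandible2)
#>   statuses: 60 ok, 30 masked, 0 interpolated, 0 failed
```

The 30 `masked` frames are the stretch where the mandible band crosses the
hyoid ROI and matching runs on the clipped pixel set; none failed. Calibrate
into cervical units and segment the loop:

```r
variants <- tidy(run) |>
  (\(tr) calibrate_variants(
     tr |> filter(point == "hyoid") |> select(frame, x, y),
     tr |> filter(point == "C2")    |> select(frame, x, y),
     tr |> filter(point == "C4")    |> select(frame, x, y), p = 0.3))()

seg <- variants |> filter(variant == "SmoNCC") |> extract_loop() |> segment_loop()
seg
#> <phase_segmentation> outcome: auto4; loop (1, 88); splits: 20, 45, 65
#> # A tibble: 4 × 7
#>   phase             t_start t_end duration      dx      dy displacement
#>   <chr>               <dbl> <dbl>    <dbl>   <dbl>   <dbl>        <dbl>
#> 1 elevation               1    20       19  0.0835  0.467         0.474
#> 2 anterior movement      20    45       25  0.471   0.0296        0.472
#> 3 descending              45    65       20 -0.0898 -0.469         0.477
#> 4 returning               65    88       23 -0.466  -0.0295        0.467
```

The three automatic splits (frames 20, 45, 65) land exactly on the phantom's
constructed phase junctions, and the per-phase displacements read in
cervical units: the hyoid rises ~0.47 CU during elevation, advances ~0.47 CU
anteriorly, then retraces both legs. `rom()` on the same variant gives the
loop's range of motion (0.57 CU in x, 0.51 CU in y, 0.76 CU in 2D).
`autoplot()` methods draw the six variants and the segmented velocity
profile; `tidy()`/`glance()` return everything as tibbles.

The same pipeline is scriptable from a shell via `exec/vfsstrack`
(`simulate`, `track`, `process`, `segment`, `validate` subcommands; run it
with no arguments for usage).

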