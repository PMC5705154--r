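---
title: "Tracking, smoothing and segmenting hyoid bone motion: methods"
author: "hyoidtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking, smoothing and segmenting hyoid bone motion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyoidtrack)
library(dplyr)
```

## The problem

In a videofluoroscopic swallowing study (VFSS) the hyoid bone is the most
widely used kinematic marker of swallow function: its elevation and anterior
excursion correlate with dysphagia severity and aspiration risk. Manual
frame-by-frame clicking is accurate but impractically slow, and plain
template trackers break in two characteristic ways: the mandible sweeps over
the hyoid and masks it for a few frames, and occasional fast motion or glare
makes the target momentarily unrecognizable. `hyoidtrack` implements a
semi-automatic pipeline that addresses both, then converts the raw pixel
track into anatomically calibrated coordinates and segments one swallow
into its four phases.

The pipeline has five stages, each exposed as ordinary functions over data
frames:

1. **Edge-template tracking** (`track_sequence()`): each seeded point (the
   hyoid target, two mandible-edge points, the anterior-inferior borders of
   C2 and C4) carries a square ROI whose Sobel edge characteristics are
   matched from frame to frame under a bounded rotation-and-shift search.
2. **Occlusion handling**: when the chord through the two tracked mandible
   points crosses the hyoid ROI, the masked part is clipped from both the
   template and the current ROI, and the matching error is averaged over
   the retained pixels only.
3. **Failure monitoring**: a third-order motion predictor flags frames
   whose tracked position deviates from the prediction by at least 8 px;
   tracking can be resumed from a corrected seed (`resume_tracking()`).
4. **Smoothing and calibration** (`calibrate_variants()`): cubic smoothing
   splines denoise each coordinate series, and a per-frame rigid transform
   maps the hyoid into the patient-centric C2–C4 frame, measured in
   cervical units (CU), removing head motion and making subjects
   comparable.
5. **Segmentation** (`extract_loop()`, `segment_loop()`): the velocity
   amplitude of one swallow loop is analysed for local minima; the three
   minima with the highest splitting scores divide the loop into the
   elevation, anterior-movement, descending and returning phases.

## Tracking model

Let $E_x, E_y$ be the horizontal and vertical 3×3 Sobel responses of a
frame (reflect padding at the borders). For a template anchored at frame
$i_0$ with pixel offsets $\{(u,v)\}$ and a candidate pose with shift
$(\tilde x, \tilde y)$ and rotation $\tilde\theta$ about the template
centre, the matching error is

$$\Delta(\tilde x,\tilde y;\tilde\theta) \;=\; \frac{1}{N}\sum_{(u,v)\in
\mathrm{ROI}'}\big(E_x^{ref}-E_x^{cur}\big)^2+\big(E_y^{ref}-E_y^{cur}\big)^2,$$

where the current-frame responses are sampled by bilinear interpolation at
the rotated and shifted offsets and $N$ is the number of retained pixels
(the full square when nothing is masked). Matching edge responses rather
than intensities makes $\Delta$ invariant to global brightness offsets,
which drift freely in fluoroscopy. The search is bounded to
$\pm 5$ px and $\pm 2.5^\circ$ per step — swallows at 30 fps stay well
inside this box — and minimized by an exhaustive coarse grid (1 px,
0.5°) followed by a Nelder–Mead refinement clamped to the box. A seeded
real-coded genetic algorithm (population 50) is available as an
alternative global stage (`optimizer = "ga"`); both agree with a fine-grid
scan to high precision on test scenes, and the grid route is the default
because it is deterministic without qualification.

**Reference-template policy.** The reference appearance is anchored at the
seed frame by default (`template_update = "fixed"`), with only the ROI
*position* updated each frame. Re-sampling the template every frame
(`"each_ok"`, also provided) adapts to slow appearance change but
accumulates subpixel interpolation drift — on rigid phantoms it inflates
the hyoid RMS error by an order of magnitude — and a drifting mandible
track then corrupts the occlusion clipping. With the fixed policy the
per-frame search box still only needs to cover per-frame *displacement*,
because the ROI is recentred on the current estimate at every step.

**Rotation centre.** Rotation is taken about the template centre (the
target point). At the small angles allowed by the box this is the only
choice that keeps shift and rotation identifiable.

## Occlusion handling

The two mandible points define an infinite line; the mandible side is the
side of greater $y$ (superior, in the bottom-left-origin convention), and
pixels exactly on the line count as masked so that the retained count is
deterministic. Frames whose ROI crosses the line are matched on the
retained set only, with the same retained offsets applied to the reference
template so the two pixel sets stay comparable.

Two numerical guards surround the geometric rule:

* **Clip margin** (`clip_margin`, default 3 px): the tracker clips a few
  pixels beyond the geometric boundary, because the occluder's Sobel
  response bleeds about 2 px past its edge (3×3 support plus bilinear
  sampling) and the chord itself carries ~1 px of tracking error. Without
  the margin the matcher locks onto the strong band edge and follows the
  mandible instead of the hyoid.
* **Totally-masked rule**: a frame is declared totally masked when fewer
  than `min_clip_frac` (10%) of the ROI pixels survive the clip *or* the
  target point itself lies more than `mask_center_depth` (2 px) inside the
  mandible side. In either case the clipped ROI can hold no usable
  evidence of the target; the position is left open and later filled by
  cubic interpolation from up to four tracked samples on each side
  (`stats::spline` with Forsythe–Malcolm–Moler end conditions, which
  reproduce cubic paths exactly). Gaps touching the sequence ends cannot
  be extrapolated and are reported as failures instead.

## Failure monitoring

The monitor predicts the next hyoid position by a third-order Taylor step,
$\tilde H(i{+}1) \approx H + \dot H\,\Delta t + \tfrac12\ddot H\,\Delta t^2 +
\tfrac16\dddot H\,\Delta t^3$ with $\Delta t = 1$ frame. The derivatives
are taken from the interpolating cubic through the last four accepted
positions, which makes the sum equal the Newton backward extrapolation
$H + \nabla + \nabla^2 + \nabla^3$ and therefore *exact* on any cubic
path; plugging raw backward differences directly into the Taylor form
would not have this property. The displacement error is the Euclidean
distance between prediction and tracked position; a step fails when it
reaches the threshold (8 px by default). The monitor requires four clean,
contiguous `ok` frames of history, so it stays silent for the first steps
after any (re)seed and across masked or interpolated stretches, where the
prediction would otherwise extrapolate over a gap. `locate_failure()`
re-evaluates the check backwards and forwards around a flagged frame to
name the first failed frame; `resume_tracking()` splices a fresh track from
a corrected seed, leaving earlier samples untouched.

## Smoothing and calibration

The smoothing spline minimizes
$p\sum_i (y_i - f(t_i))^2 + (1-p)\int f''(t)^2\,dt$, the convention in
which $p = 1$ interpolates and $p = 0$ degenerates to the least-squares
line; useful trajectory smoothing lives around $p \in [0.15, 0.45]$ and the
default is the midpoint, $p = 0.3$. The fit is computed by the Reinsch
band algorithm at the sample frames, and the object evaluates $f$, $f'$
and $f''$ anywhere in range from the per-interval cubic coefficients —
the derivative evaluators are what the velocity analysis consumes.
`stats::smooth.spline` solves the same problem on a rescaled axis and is
used as an independent cross-check in the tests, not as the
implementation.

Calibration builds, **per video frame**, the rigid map that sends C4 to the
origin and the C4→C2 direction to $+y$, then points the anterior direction
to $+x$ (`anterior = "left"` for the standard left-facing lateral
projection; flip for mirrored recordings), and finally divides by the
cervical unit $|C2-C4|$ (in px) when scaled coordinates are requested. One
cervical unit is recomputed each frame rather than frozen at a reference
frame, so slow magnification change is absorbed along with head motion.
The rotation angle is computed with `atan2`, which keeps the contract
valid in every quadrant. A verbatim historical variant of the rotation
(with a $\pi/2$ offset that sends C2 to the $x$-axis instead) is retained
behind `compat = "printed"` for comparison; it does not satisfy the
C2→(0,1) contract and is never used by the pipeline.

The six processing variants follow the standard comparison design:

| variant  | smoothing | new frame | scaled to CU |
|----------|-----------|-----------|--------------|
| `Raw`    | –         | –         | –            |
| `RawNC`  | –         | yes       | –            |
| `RawNCC` | –         | yes       | yes          |
| `Smo`    | yes       | –         | –            |
| `SmoNC`  | yes       | yes       | –            |
| `SmoNCC` | yes       | yes       | yes          |

Smoothed variants smooth the C2/C4 landmark series as well, before the
per-frame transform. By construction the NCC variants are invariant under
any global rigid motion plus uniform scaling of the scene — the package's
head-motion phantom checks this to 1e-9.

## Loop extraction and phase segmentation

One swallow loop is a window $(t_A, t_B)$ containing one elevation peak of
$y(t)$ and one anterior-excursion extremum of $x(t)$ (a valley in image
coordinates, a peak in patient-centric coordinates where anterior is
$+x$), with endpoints as close together in the plane as possible. Manual
endpoints are validated; automatic suggestion scans endpoint pairs
bracketing the global peak pair and minimizes the endpoint distance.

Over the loop, the velocity amplitude is
$v(t) = \sqrt{x'(t)^2 + y'(t)^2}$ with derivatives from the coordinate
splines on the frame grid. Candidate splitting points are the interior
local minima of $v$: roots of $v'$ (sign-change bracketing at 0.1-frame
resolution, refined by bisection on a spline fitted to $v$) at which
$v'' > 0$. Two numerical details matter on real, discrete data. First,
each root is snapped to the smallest sampled $v$ within one frame.
Second, that sample must itself be a local minimum of the sampled
profile; a smoothing spline develops numerically flat ripples along
plateau stretches whose roots would otherwise surface as spurious
candidates.

Each candidate $t_i$ (with chronological neighbours $t_{i-1}, t_{i+1}$,
the loop endpoints standing in at the ends) is scored by

$$\mathrm{FSS}(t_i) = \max_{t\in[t_{i-1},\,t_i]} v(t) - v(t_i),\qquad
\mathrm{BSS}(t_i) = \max_{t\in[t_i,\,t_{i+1}]} v(t) - v(t_i),$$

and $\mathrm{SS} = \mathrm{FSS} + \mathrm{BSS}$, the "turning intensity"
of the minimum. The maxima are taken over the sampled frame grid. The
three highest-SS candidates (ties broken toward the earlier frame, so the
output is deterministic) split the loop into four phases labelled purely
by chronological order: elevation, anterior movement, descending,
returning. Outcomes mirror clinical practice: `auto4` when at least three
candidates exist, `three_phase` with exactly two, `abnormal` below that,
and `manual4` when the user overrides the splits. The labels are not
geometrically verified beyond a warning flag when the first phase does
not actually ascend.

## The synthetic phantom

Clinical VFSS videos cannot ship with a package, so every tracking claim
is validated against a ground-truthed phantom (`phantom_spec()`,
`simulate_vfss()`) that emulates the structures the tracker relies on:

* a Gaussian hyoid-like blob (radius 6 px) riding a closed four-phase loop
  built from four constant-speed legs joined by cosine deceleration ramps,
  with a range of motion of ~45 px per axis — the pixel scale of adult
  swallows in clinical lateral projections;
* two static high-contrast square landmarks for C2 and C4 (separation
  ~85 px, the cervical unit);
* a bright mandible band whose lower edge is the chord through two
  trackable marker points, dipping across the hyoid for a contiguous
  occlusion window (default 5 frames, reached through 10-frame cosine
  ramps so the mandible points stay inside the per-frame search box);
* slow global head motion — a sinusoidal translation of a few px and a
  0.5° rotation about the image centre over the sequence — which the
  NCC calibration must remove;
* additive Gaussian noise (σ = 0.02 on [0,1] intensities, a mid-range
  value for exported fluoroscopy loops), after which frames are quantized
  to 8-bit levels exactly as a video export would be.

Default sequences are 90 frames at 30 fps (3 s, a typical thin-fluid
swallow) of 256×256 px; geometry scales with the image size. Every
generated sequence is bit-reproducible from `(spec, seed)`.

What the phantom does *not* emulate: textured soft-tissue background,
scatter and beam hardening, appearance change of the hyoid with rotation,
out-of-plane motion, or inter-subject anatomical variation. Passing the
phantom suite therefore demonstrates the algorithmic contracts — occlusion
survival, calibration invariance, junction recovery — not clinical
accuracy, which requires validation against expert manual tracking on real
recordings.

## Agreement statistics

`rom()` reports per-axis coordinate ranges and a 2D range defined as the
trajectory diameter (maximum pairwise distance). The diameter is adopted
because it is the unique natural scalar bounded between
$\max(\mathrm{ROM}_x, \mathrm{ROM}_y)$ and
$\sqrt{\mathrm{ROM}_x^2+\mathrm{ROM}_y^2}$. Relative error is
$|\mathrm{ROM}_a - \mathrm{ROM}_b| / \mathrm{ROM}_b \times 100\%$.
Group summaries (`summarize_agreement()`) compute per-loop ROMs, relative
errors and per-axis Pearson correlations, then average per-loop values
across each group's loops. Inter-rater reliability uses the
single-measure, absolute-agreement, two-way random-effects intraclass
correlation — ICC(A,1) — with the F-based confidence interval; absolute
agreement is the right form for two raters clicking the same landmark,
since a systematic offset between raters must count against reliability.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline on the
default 90-frame phantom plus several 12–60-frame variants; a complete
five-point track of the default phantom takes well under a minute on one
core, with the matching kernel in compiled code. All stochastic elements
(phantom noise, the GA optimizer, simulated raters) are seeded, and
repeated runs with one seed are bit-identical, including the CLI file
outputs.

## Known limitations

* Tracking assumes the target stays within ±5 px and ±2.5° per frame;
  faster motion trips the monitor by design and needs a manual reseed
  rather than silent recovery.
* The fixed reference template assumes the target's appearance is stable
  over the clip; long recordings with appearance drift should use
  `template_update = "each_ok"` and accept the drift trade-off.
* The mandible edge is modelled as a straight chord; strongly curved
  occluder boundaries would need more landmarks or a shape model.
* Phase labels are chronological; anatomically atypical loops can carry
  misleading labels (flagged, not corrected).
* Only PNG/TIFF frame directories are read; video containers must be
  exported to frames first.
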