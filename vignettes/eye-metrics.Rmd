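---
title: "Quantifying ptosis and ocular misalignment from telehealth video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ptosis and ocular misalignment from telehealth video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgceye)
```

## The problem

Two exercises of the standardized telemedicine examination for myasthenia
gravis (MG) stress the ocular muscles: a 61-second sustained up-gaze, which
elicits progressive drooping of the upper eyelid (ptosis), and a 61-second
sustained lateral gaze, during which fatigue of the extra-ocular muscles may
misalign the two eyes and produce double vision (diplopia). Both signs are
graded visually today, which misses slow dynamics: a 15% decline of the lid
opening over a minute is close to invisible to an observer watching the
patient, yet is a clinically meaningful fatigue signature.

`mgceye` turns a recorded clip of either exercise into per-frame geometric
measurements and filtered one-minute time series. The design constraint is
the telehealth setting: consumer cameras, compressed video, frames as small
as 450x800 px at 30 FPS, an eye occupying perhaps a tenth of the frame, and
no control over lighting. The package therefore prioritizes robustness and
explicit per-frame validity checking over accuracy achievable in controlled
conditions, and aims for 2-pixel localization of the anatomic interfaces —
about the best achievable when an interface is projected onto a discrete
pixel grid, and a target that is independent of image resolution.

## The hybrid measurement model

A single measurement chain runs per frame:

1. **Coarse localization.** A 68-point facial landmark model (an external,
   pluggable provider; the package never trains one) supplies the eye
   regions: the hexagon of points 37–42 for the right eye and 43–48 for the
   left. These landmarks are robust but not accurate — the lower-lid points
   in particular often sit well off the true contour, the hexagon can
   degenerate to a pentagon, and the model occasionally locks onto the
   nares. `validate_eye_localization()` rejects gross failures with three
   geometric rules (eyes in the upper half of the face box, plausible
   inter-ocular distance, near-horizontal inter-ocular line). The thresholds
   (0.15/0.8 of face width, 25 degrees) are config-exposed; the failure modes
   are observed facts but no published rule exists, so these are this
   package's operationalization.

2. **Coarse metrics.** From the hexagon alone: the eyelid distance ED
   (mean vertical distance between the paired upper/lower lid landmarks),
   the eye area (shoelace area of the hexagon), and the eye length EL
   (corner-to-corner horizontal distance). ED and area are normalized by EL
   and EL², which makes them quasi-invariant to small head translation and
   to resolution; the per-frame EL (not a baseline EL) is used for the same
   reason. Blinks are detected as dips of ED below half of a 2-second
   rolling median, lasting at most 0.5 s; frames with no ED (a fully closed
   eye degenerates the hexagon) bridge a dip rather than splitting it.

3. **Local interface refinement.** Each anatomic interface is re-segmented
   inside a small rectangle derived from the landmarks: the lower lid around
   its two landmarks (±0.15·EL vertical padding), the upper lid likewise,
   the iris bottom in the box spanning the upper-lid landmarks horizontally
   and reaching the lower-lid landmarks vertically, and — for the lateral
   exercise — a box from the eye corner opposite the gaze to the lid
   landmarks on the gaze side, crossed vertically by the lateral iris
   boundary. Inside each rectangle the problem reduces to finding a single
   interface between two regions of distinct intensity:

   * percentile contrast stretch (1st–99th percentile to full range);
   * a seeded two-cluster k-means partition of the intensities, with a
     separation score (centroid distance over pooled within-cluster
     standard deviation, minimum 2.0) guarding against contrast-free
     patches;
   * conversion of the label field to a single-valued sub-pixel curve (one
     sample per column/row; midpoint of the label change after a 3x3
     majority cleanup);
   * refinement by an open active contour (snake) that displaces each
     sample within ±3 px along the crossing normal to maximize the smoothed
     image gradient minus a curvature penalty (weight 0.3, config-exposed;
     chosen so the 2-pixel localization property holds on synthetic
     frames), followed by parabolic sub-pixel interpolation of the gradient
     peak — without it the snake sticks to the interpolation nodes of the
     piecewise-linear gradient field at roughly 0.5 px resolution, which
     visibly staircases slow lid motion.

4. **Hypothesis validation.** A candidate curve is accepted only when:
   H1, it is smooth (no step above 2 px, total variation at most half the
   rectangle extent); H2, it crosses the rectangle fully, with at most 20%
   of columns ambiguous in the underlying partition; H3, iris-boundary arcs
   are convex in the direction of an iris bulging into the sclera (quadratic
   fit, residuals at most 2 px); H4, each cluster's largest 4-connected
   component holds at least 90% of its pixels (reflecting light and lighting
   gradients typically fragment a cluster). Additionally the clustering
   curve and the snake curve must concur within 2 px on average — two
   independent algorithms agreeing is the acceptance signal — and the
   intensity polarity across the curve must match the target's anatomy
   (sclera above skin at the lower lid, iris above sclera at the iris
   bottom, dark iris on the gaze side of the lateral boundary). The
   polarity prior is this package's addition: the prescribed lower-lid
   rectangle legitimately contains both the iris/sclera and sclera/skin
   interfaces whenever the visible scleral strip is narrower than the
   padding, and H1–H4 cannot tell the two apart.

5. **Retry and shrink.** On failure the clustering is re-seeded (twice),
   then the rectangle is shrunk by 0.8 about its anchor landmark (up to five
   times, never below 4 px), which is what resolves rectangles straddling
   two interfaces; if nothing is accepted the frame is skipped for that
   metric. The lateral-iris box anchors its shrinking at the lid landmarks
   on the gaze side (at the eye-center row) rather than at the corner: the
   visible iris edge lies inside the aperture, and shrinking toward the
   corner would discard it in favour of the corner's sclera/skin wedge.

## Per-frame exam metrics

On the vertical line through the ROI center the pipeline reports the lid
opening (`lid_to_lid`) and the iris-bottom-to-lower-lid distance
(`iris_to_lowerlid`, which verifies the patient is actually holding the
up-gaze), both EL-normalized. For lateral gaze, the misalignment coordinate
is barycentric: `alpha = |x(P) − x(anchor corner)| / EL`, where P is the
visible lateral iris-boundary point and the anchor is the corner the search
box starts from (the corner opposite the gaze). The choice of that corner as
the anchor is one of two readings of the construction; it is the one
consistent with the search-box definition, and since the clinically used
quantity is the drift of `alpha_left − alpha_right` from its own baseline,
the anchor convention cancels. A constant inter-eye offset is not drift; the
baseline is the median over the first 5 s of valid frames, and a deviation
above 0.05 (config-exposed; reported alongside the raw series so the
physician decides) raises the misalignment flag.

The iris circle is fitted to accepted boundary arcs by an algebraic fit
refined with a few Gauss–Newton steps on the radial residuals (the algebraic
fit alone biases small on noisy partial arcs); arcs subtending less than 60
degrees are flagged unreliable. The pupil center is approximated by the iris
center — valid in primary gaze — and two 0–3 grading helpers mirror the
clinical scales: one from droop-onset time (onset beyond 45 s grades 0,
11–45 s grades 1, 1–10 s grades 2, within a second grades 3), one from the
lid margin's position relative to the pupil (above the iris top, above the
pupil, at the pupil within a quarter-diameter, below). "Visible ptosis" is
nowhere quantified clinically; the onset definition used here — the filtered
normalized lid opening falling below 90% of its initial value — and the
quarter-diameter band for "at pupil" are config-exposed conventions of this
package.

## Time series

Frames failing any validity check are removed before series assembly, in a
fixed priority: head motion (median landmark displacement above 0.1·EL
between consecutive frames), lighting (a rectangle failing H4), landmark
instability (eye-hexagon centroid jumping above 0.2·EL while the face moves
less than 0.05·EL), and blink (detected events widened by one frame). All
four thresholds quantify qualitative failure modes and are config-exposed.
The exercise window is found from gaze labels — the sclera-majority region's
position relative to the iris within each hexagon, majority-voted over 1 s,
with the two eyes required to agree — as the longest run of the expected
label; since the exercises are nominally 61 s, windows outside 40–80 s are
flagged atypical. The gaze labeling uses a robust intensity threshold (the
midpoint of the 10th/90th percentile) rather than a seeded clustering: it is
deterministic and the hexagon interior is guaranteed bimodal when an eye is
open.

Holes up to 1 s are filled by linear interpolation on the native acquisition
grid (no value ever leaves the hull of its bracketing samples); longer holes
are first-class gaps — they often mean the patient rested their gaze — and
are reported, never interpolated, and never bridged by the filter. Each
contiguous segment of at least 4 s is low-pass filtered: resampled uniformly
at its mean frame rate, detrended by the line through its endpoints, the
residual extended to twice its length by point reflection (the residual
vanishes at both ends, so the extension is periodic and C1-continuous,
avoiding both the periodicity mismatch of a raw FFT and the spectral leakage
of a plain mirror), sharply cut at 0.5 Hz, inverted, truncated and
re-trended. This construction passes a pure linear ramp exactly and is
idempotent to within 1%; the specific realization (detrend + odd extension +
sharp cutoff, cutoff config-exposed) is this package's choice of a
Fourier-for-nonperiodic-series smoother, since fatigue dynamics of interest
live well below 0.5 Hz while blink residue and segmentation jitter live
above. Trends are ordinary least squares against time normalized to the
exercise window, so the slope reads directly as total change over the
exercise; the lid-opening decay is reported as `−slope/intercept`.

## The synthetic data generator

Every stage above is testable without patient data through
`synthetic_eye_spec()` / `render_frame()` / `render_sequence()`: a
face-scale gray frame with two eyes built from parabolic lid curves, a
scleral aperture, and an iris disk clipped to the aperture, with three flat
intensity classes plus a linear illumination ramp and additive Gaussian
noise — deliberately minimal, because the documented failure modes of the
measurement chain are low contrast and lighting, both representable this
way. Programmed effects: linear upper-lid droop (in normalized-ED units per
second; `droop_rate_for_decay()` converts a target relative decay), gaze
direction, lateral iris drift for misalignment ramps, symmetric triangular
blinks (0.2 s by default, per-event durations allowed so a long voluntary
closure can be scripted), and per-frame head jitter. Every frame exports
exact ground truth (lid/iris interface curves, the 68-point landmark layout
with plausible jaw/brow/nose/mouth positions, ED/EL/area/alpha), and
rendering is bit-deterministic given the spec and seed, with per-frame
streams derived from the seed and frame index so sampling does not change
individual frames.

Defaults were chosen once to sit inside the acquisition envelope of real
telehealth recordings: 360x640 px frames, eye length 36 px, lid apex heights
7/5 px (a ~12 px aperture — the low end of what consumer setups deliver),
iris radius 7 px, skin/sclera/iris intensities 0.55/0.95/0.20, noise sigma
0.02, 30 FPS. What the generator does *not* emulate — compression artifacts,
eyelashes, specular reflections on the iris, out-of-plane head rotation,
true landmark-model bias — bounds what green tests mean: they certify the
geometry and signal chain, not performance against every real-world
nuisance. The fixture landmark provider can inject systematic bias (e.g.
pushing the lower-lid points off the contour) to emulate the dominant real
provider error.

## Numerical conventions and degenerate inputs

Images are numeric matrices in `[0, 1]`, rows = y (growing downward),
columns = x, pixel centers at integer coordinates; interfaces are placed at
the midpoint between the last pixel of one region and the first of the
other, so a step between rows 7 and 8 reads 7.5. Search rectangles are
half-open integer boxes that also carry continuous bounds, so repeated
shrinking is strictly monotone (integer rounding alone can stall), and
shrunk bounds round inward so an excluded structure stays excluded. A fully
closed aperture renders and is flagged degenerate; a degenerate hexagon
(coincident vertices within 1 px) makes the coarse metrics unavailable
rather than zero. Constant patches short-circuit with a contrast failure.
All stochastic stages (cluster initialization, noise, jitter) draw from
seeds derived deterministically from a single base seed, and the pipeline's
outputs are byte-identical across reruns.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script verify, on the generator: exact
frame-count arithmetic of 2-second sampling; 2-pixel mean-absolute-error
localization of the three ptosis interfaces on 100 frames spanning 25 seeds
and four exercise phases (noise sigma 0.05, programmed 15% droop); pixelwise
agreement of the two-cluster partition with a brute-force optimal-threshold
oracle on 50 seeded two-tone patches; recovery of programmed 10/15/30%
lid-opening decays within ±0.03 by the full pipeline on 60 s clips sampled
at 2 Hz; detection of exactly three programmed blinks per eye with
left/right synchrony on a 30 s clip at full frame rate; translation
invariance of alpha under (±5, ±3) px whole-frame shifts; ramp preservation
and 20-fold 5 Hz attenuation of the filter; and byte-identical reruns.
These sizes keep a full run in the low minutes on one core while exercising
every acceptance-relevant path; larger clips scale linearly.

## Known limitations

Videos must be exploded to PNG frames upstream (any standard media tool can
do this); the package ingests frame directories and in-memory synthetic
clips. The external landmark provider is an adapter interface — none is
bundled, and the geometric validity rules are a stand-in for failure modes a
better provider would not exhibit. Misalignment is reported as a geometric
quantity; whether it corresponds to experienced double vision involves
central compensation and remains a clinical judgement. The anatomic grading
assumes the pupil sits at the iris center, which is only valid near primary
gaze.
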