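# mgceye

Quantitative ptosis and ocular-misalignment metrics from telehealth video
frames, for the two ocular exercises of the Myasthenia Gravis Core
Examination (MG-CE): 61 s of sustained up-gaze (eliciting eyelid droop) and
61 s of sustained lateral gaze (eliciting ocular misalignment). The package
is aimed at researchers and engineers building objective readouts for
telemedicine neurology exams, where video is low-resolution, compressed and
poorly lit, and the eye may span only tens of pixels.

## Method

The pipeline is hybrid: a 68-point facial landmark model (external,
pluggable) gives robust but inaccurate eye regions — the hexagons of points
37–42 (right eye) and 43–48 (left eye) — and local computer vision then
refines each anatomic interface inside a small rectangle around the
landmark positions:

* contrast stretch, two-cluster k-means partition of the intensities, and
  conversion of the label boundary to a single-valued sub-pixel curve;
* refinement by an open snake maximizing the image gradient along the
  curve, with parabolic sub-pixel peak interpolation;
* acceptance only when the curve is smooth (H1), crosses the rectangle
  fully (H2), iris arcs have the anatomically correct convexity (H3), both
  clusters are connected regions (H4), the two algorithms concur within
  2 px, and the intensity polarity across the curve matches the target
  anatomy; otherwise the clustering is re-seeded, then the rectangle shrunk
  about its anchor landmark until acceptance or exhaustion.

Per frame this yields the eyelid distance ED, eye area, lid-to-lid and
iris-bottom-to-lower-lid distances (all normalized by the eye length EL =
corner-to-corner distance, making them quasi-invariant to head translation
and resolution), and — for lateral gaze — the barycentric misalignment
coordinate of each eye,

```
alpha = |x(P) − x(anchor corner)| / EL,
```

where P is the visible lateral iris-boundary point. Diplopia risk is read
from the drift of `alpha_left − alpha_right` away from its baseline. Frames
are rejected for head motion, lighting artifacts, landmark instability or
blinks; the surviving samples form gap-aware time series in which holes
≤ 1 s are linearly interpolated, longer gaps are reported (never bridged),
and each contiguous segment is low-pass filtered with a mirror-extended
Fourier filter that passes linear trends exactly. Least-squares trends on
normalized time give the lid-opening decay over the exercise, and two 0–3
grading helpers mirror the clinical scales (droop-onset time; lid margin
relative to the pupil).

A fully parameterized synthetic eye generator (`synthetic_eye_spec()`)
renders ground-truthed face-scale clips — programmable droop, gaze, blinks,
iris drift, noise, illumination gradient, head jitter — so the entire
pipeline is testable without patient data.

## Worked example

Render a 60 s up-gaze clip with a programmed 15% lid-opening decay and run
the ptosis pipeline on it, sampling two frames per second:

```r
library(mgceye)

spec <- synthetic_eye_spec(
  duration = 60, noise_sigma = 0.02, seed = 42,
  droop_rate = droop_rate_for_decay(0.15, list(duration = 60)))
print(spec)
#> synthetic eye clip: 60s @ 30 FPS, 360x640 px, gaze=up, EL=36 px,
#>   droop=0.000833333 ED/s, 0 blink(s)

res <- run_pipeline(clip_descriptor(spec, sample_every = 0.5), "ptosis",
                    base_seed = 1, window = "full")
res$summary$disposition$used          # 120 of 120 frames usable
dec <- res$summary$lid_opening_relative_decay
sprintf("lid-opening decay: right %.3f, left %.3f",
        dec$lid_to_lid_norm_right, dec$lid_to_lid_norm_left)
#> "lid-opening decay: right 0.152, left 0.151"
res$summary$droop_onset_s             # 39
res$summary$grade_ptosis_time         # 1
print(res$series$lid_to_lid_norm_right)
#> measurement series 'lid_to_lid_norm_right': 120 samples, 0 gap(s) > 1 s,
#>   trend slope -0.050
```

The programmed 15% decay — nearly invisible to an observer — is recovered
as 0.152/0.151; the filtered series crosses 90% of its initial value at
39 s, which grades 1 (visible ptosis within 11–45 s) on the time-based
scale. The raw trend slope (−0.050) is in channel units (lid opening / EL)
per exercise; divided by the intercept it gives the relative decay.

Real clips are ingested as directories of gray PNG frames with a
`manifest.csv` (`file, frame, timestamp[, fps]`), plus an optional
`landmarks.csv` with one row of 68 x,y pairs per frame; run
`run_pipeline("path/to/clip", "ptosis", ...)` or, for lateral gaze,
`run_pipeline(..., "diplopia", gaze = "left")`. A thin CLI wrapping these
functions ships at `inst/cli/mgceye` (subcommands `synth`, `ptosis`,
`diplopia`, `report`).

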