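---
title: "Measuring continuous intervertebral motion with qfkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring continuous intervertebral motion with qfkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Quantitative fluoroscopy (QF) measures how adjacent lumbar vertebrae move
relative to one another during a controlled trunk motion, from a low-dose
fluoroscopic image sequence of several hundred frames.  Plain end-range
radiographs only show where a segment ends up; continuous sequences show
how it gets there, which is what distinguishes a lax segment, a stiff one
and one that moves out of phase with its neighbours.  qfkin implements the
full measurement chain — template tracking, corner-based registration of
vertebral position, and derivation of the consensus motion indices — plus a
ground-truthed synthetic phantom so that every stage can be validated
without patient data.

The seven indices reported per intervertebral level are: range of
intervertebral rotation; range of translation; directional coherence;
motion commencement sequence; neutral-zone laxity; the instantaneous axis
of rotation (IAR); and disc height.  Phase lag and motion sharing are
derived alongside.

## Acquisition protocol and its validation

`validate_protocol()` enforces the consensus acquisition minima: at least
12.5 frames/s, 8-bit depth, 512x512 pixels; motion-direction sweeps of
8-12 s with raised 0.5-1 s ramps, starting from neutral; standardised
outward ranges of 40 degrees (recumbent, all directions) and 60/20/40
degrees for weight-bearing flexion/extension/bends.  `make_motion_program()`
refuses out-of-protocol parameters at construction, so phantom sequences
are protocol-conformant by construction.

The trunk profile is a trapezoid with raised-cosine velocity ramps: ramp
shape is a free design choice (the protocol fixes only the ramp duration),
and the raised cosine avoids acceleration steps that would be unphysical
for a motorised table.  Ramp intervals are additional to the cruise time,
so a 10 s sweep at 15 fps yields 300 cruise frames plus ramp frames.  The
plateau velocity is `range / (sweep + ramp/2 + ramp/pi)`; the test suite
checks the whole profile against a numerically integrated oracle.

## Tracking model

Each vertebra is marked on frame 0 with a tracking polygon (five
independent markings per vertebra) and a linked four-corner reference
template.  Tracking is masked normalized cross-correlation (NCC) of the
frame-0 template against each successive frame:

* frames are rolling-averaged over a 2-frame window before correlation to
  damp frame noise;
* the template is resampled at candidate cumulative rotations
  (coarse +/-2 degrees in 0.25-degree steps about the velocity-extrapolated
  pose, then fine 0.05-degree steps), and shifts are searched on a lattice
  about the predicted position;
* NCC is computed on locally mean/variance-normalized intensities within
  the polygon support, which makes the tracker insensitive to the slowly
  varying intensifier-flare and soft-tissue fields;
* the correlation peak is refined to sub-pixel and sub-step by parabolic
  interpolation over shift and rotation;
* pixels inside marked metal-exclusion polygons carry zero weight
  (`mask_metal()`), and a support below 25% of the template is refused;
* frames whose peak falls below `peak_threshold` (default 0.5) are flagged
  `low_peak` and carry the previous pose forward; templates touching the
  field edge are flagged.

Two design choices deserve note.  First, the search is incremental
(frame-to-frame, about the extrapolated previous pose) but the *appearance*
correlated is always the frame-0 template: re-extracting the template each
frame accumulates interpolation drift with no benefit on rigid anatomy;
`template_update = "every_frame"` restores re-extraction for appearance
that genuinely evolves.  Second, two efficiency measures that do not alter
the estimator's support: the coarse sweep narrows to the predicted
neighbourhood once a velocity prior exists (per-frame increments under the
protocol are far below 1 degree), and the coarse/fine sweeps subsample the
template support (strides 3 and 2, relaxed automatically below 200
points).  Both are `tracker_config()` options.

Key-point series are smoothed with a zero-phase (forward-backward)
fourth-order Butterworth low-pass, cutoff 1 Hz by default: the trunk sweep
fundamental is 0.05-0.12 Hz under the protocol, so 1 Hz preserves motion
while removing frame-rate noise.  Ends are handled by odd-reflection
padding.  The test suite checks the realised response against the
closed-form digital Butterworth magnitude.

## Corner geometry

Rotation comes from the tracking templates directly.  Translation, disc
height and the IAR come from the four body corners, registered in the
style introduced by Frobin and colleagues: anterior and posterior edge
midpoints define the central axis and body depth; the relative rotation of
a pair is the angle between their axes; translation is the component of
the centre-to-centre vector along the *bisectrix* of the two axes,
reported as change from the neutral frame in percent of mean body depth;
disc height is the perpendicular component corrected for the half body
heights.  Because every quantity is built from corner geometry alone,
the translation and disc-height measures are invariant to global rigid
transforms of the image — the distortion tolerance that motivates
corner-based registration — and the percent-depth normalization removes
magnification.  This invariance is asserted to 1e-6 in the tests.

Two conventions the source methods leave open, fixed here: translation is
referenced to the bisectrix of the *current* frame (not the neutral one) —
the difference is second order in the intervertebral angle and the choice
is flagged for sensitivity analysis; and the sign convention makes flexion
and right-bend positive (extension therefore carries a negative global
slope in laxity plots).

`refine_corners()` verifies marked corners against the image, iterated
four times.  The literal "snap each corner to the strongest gradient in a
small window" estimator is biased wherever the true corner is rounded
(cortical silhouettes are; so is the phantom, by design): the gradient
maximum sits on the rounded arc, not at the ideal corner.  The
implementation therefore snaps points *along the two adjacent body edges*
to the gradient ridge (plateau-centred, quarter-pixel sampling, parabolic
refinement) within the 7x7 window, fits a total-least-squares line per
edge over the middle ~65% of its length, and intersects the two lines.
Per-iteration displacement stays bounded by the window radius; a flat,
edge-free neighbourhood leaves the corner unchanged and flagged.
`snap_contour()` applies the same edge-snapping to whole tracking
polygons, with bounded vertex-to-vertex displacement differences standing
in for an active contour's smoothness term.

## The instantaneous axis of rotation

`iar()` expresses the upper vertebra's motion in the lower vertebra's
frame between two positions, then intersects the perpendicular bisectors
of the displacement segments of the anterior and posterior midpoints —
the classical graphical (Reuleaux) construction.  Below a minimum relative
rotation (default 5 degrees) the construction is numerically unstable and
the result is flagged invalid rather than reported; pure translation has
no finite IAR.  The construction is cross-checked in the tests against an
independent SVD rigid-fit (Kabsch) oracle whose fixed point
`(I - R)^{-1} t` must agree within 0.5 px.

## Index definitions

The consensus names directional coherence, commencement and phase lag
without operational formulas; the package defines them explicitly and
reports them as such (all thresholds configurable in `motion_indices()`):

* **coherence** — fraction of frame steps in which the level's smoothed
  intervertebral angle moves in the same direction as the trunk; steps
  within a 0.05-degree deadband (either channel) are excluded;
* **commencement** — the absolute trunk angle at which a level first
  exceeds 10% of its own range; levels are ranked ascending, ties broken
  in anatomical order;
* **phase lag** — trunk angle at the level's maximum minus trunk angle at
  the global maximum, in degrees of trunk motion (the alternative, seconds,
  is recoverable through the frame rate);
* **motion sharing** — the level's maximum rotation range as a fraction of
  the sum over levels;
* **neutral-zone laxity** — the ratio of least-squares slopes of
  intervertebral and trunk angle over the outward frames within the first
  10 degrees of trunk motion.  Fewer than 5 frames in that window (an
  out-of-protocol, too-fast sweep) or a zero global slope is an error.
  When pose series are Butterworth-smoothed, the trunk channel is passed
  through the same filter before the fit so that the two slopes see
  identical linear processing; otherwise the filter's rounding of the
  ramp corner biases the ratio low by a few percent.

Maximum ranges are taken wherever they occur during trunk motion, not at
end range.  The central estimate over the 25 marking-combination curves is
the median (robust to a single bad marking); mean and envelope are kept,
and their agreement on clean phantoms is itself a tested property.

## The synthetic phantom

`render_sequence()` draws rigid vertebra-shaped bodies — convex
quadrilaterals with a mild posterior wedge, corners rounded by 10% of the
short side, a 2 px bright cortical rim, a graded interior, and edges
feathered over +/-1 px to emulate the imaging chain's point-spread blur
(which is also what makes sub-pixel edge estimators well-posed).  Six
bodies (L1-S1) by default; the sacrum is static, as in recumbent
acquisitions with a stabilised pelvis.  Each intervertebral level rotates
by its `motion_sharing` fraction of the trunk angle about a centre placed
in the posterior half of the disc space, with a coupled endplate
translation (default 0.15 mm per degree of intervertebral rotation,
chosen to give normal-range translations of 1-2 mm over a sweep).
Because intervertebral angle is exactly proportional to trunk angle, the
per-level laxity ratio is exactly the motion share — a convenient, exact
target for validation.

The truth channel stores exact pre-noise, pre-distortion geometry: rigid
poses, corner coordinates, and per-level curves obtained by applying the
same corner-based pose definitions to the exact corners, so that the
accuracy harness scores image-analysis error and not a definition
mismatch.  The programmed quantities (sharing, coupling, rotation
centres) are stored alongside.

`apply_degradations()` applies, in order: out-of-plane foreshortening
(anisotropic `cos(theta)` scale plus a first-order keystone — 5% across
the field at the nominal 10-degree tilt — implemented as an exact
homography whose forward map is stored so that initial landmarks can be
placed in the distorted geometry an observer would actually mark); a
static low-frequency soft-tissue field; motion blur proportional to
inter-frame displacement; Poisson photon noise (normal approximation above
50 counts) plus Gaussian read noise; and a radial intensifier-flare gain;
then clipping to the bit-depth range.  Defaults (`gaussian_sd = 2` grey
levels, `poisson_scale = 0.05`, 10% flare, 10 grey levels of tissue field)
are stand-ins chosen once to perturb tracking measurably while leaving it
viable; no signal-to-noise ratio is published for the original calibration
studies, and every report header says the phantom parameters are
synthetic stand-ins.

What the phantom does *not* emulate: anatomical texture, endplate
curvature, bowel gas, overlapping structures in the coronal plane, and
genuinely non-rigid appearance change.  Passing the harness therefore
demonstrates correctness of the measurement chain and robustness to the
modelled degradations — not clinical-grade accuracy on patients.

## Accuracy and repeatability harnesses

`accuracy_study()` generates degraded phantom sequences (every second one
tilted 10 degrees out of plane), marks them with five jittered markings
(0.5 px SD placement error), runs the full pipeline and pools the RMS
error of per-level maximum rotation and translation ranges against truth,
per direction and overall.  Translation is pooled over flexion/extension.
`repeatability_study()` emulates re-marking: the same rendered sequences
re-marked `n_runs` times with independent 1.5 px SD corner perturbations,
re-tracked, and the mean pairwise inter-run RMS difference of the range
estimates reported; within-run spread across the 25 marking combinations
gives the intra-run figure.  This quantifies robustness to
initialization; it is explicitly not a claim of equivalence to human
observers.

Default study sizes — 20 sequences for accuracy, 10 sequences x 3 runs
for repeatability, 8 s sweeps at 15 fps — are the package's desk-scale
choices within the protocol window; both scale up by argument.  All
randomness derives from a single master seed through fixed sub-seed
streams, so studies are reproducible bit for bit.

```{r example}
library(qfkin)

prog <- make_motion_program("flexion", 40, 10, 0.5, 15)
spec <- phantom_spec()
rs   <- render_sequence(spec, prog, seed = 1)
seqn <- apply_degradations(rs$sequence, spec, seed = 2)
lmk  <- phantom_landmarks(rs$truth, seqn, n_markings = 5,
                          jitter_sd = 0.5, seed = 3)

poses <- track_sequence(seqn, lmk, tracker_config())
kin   <- analyze_kinematics(poses, seqn$meta$trunk_angle_series)

tidy(kin)            # one row per level: the consensus indices
autoplot(kin)        # continuous curves with trunk overlay
plot_translation_path(kin, "L5-S1")
```

## Numerical choices and degenerate inputs

* Angles are degrees, positive anticlockwise on screen; pixel coordinates
  are 0-based, x rightward, y downward.  Anatomical signs are applied at
  program generation/reporting only.
* Sub-pixel parabola steps are clamped to half a grid cell; gradient
  plateaus (linear-ramp edges) are centred rather than taking the first
  maximal sample.
* Candidate poses whose support would sample off the field are excluded
  from the NCC maximum outright (a penalty below the valid range) rather
  than scored on partial support.
* Degenerate geometry errors are explicit: zero body depth, self-twisted
  corner quadrilaterals, antiparallel axes (rotation near 180 degrees),
  parallel IAR bisectors.
* An unknown frame rate is legal metadata but refuses every time-based
  operation (smoothing, laxity); unknown pixel spacing suppresses
  millimetre outputs while percent-depth results remain.

## Known limitations

* The simplified edge-refinement is a deliberate stand-in for a full
  energy-minimising active contour; it assumes locally straight, high
  contrast edges.
* Incremental tracking can drift on very long sequences if appearance
  changes; the multiple-marking spread reported by `verify_tracking()` is
  the intended early warning.
* S1 tracking in lateral projections is known to be fragile in practice;
  failures are flagged and reported, never silently repaired.
* The DICOM reader is minimal by design: uncompressed little-endian
  single-file (possibly multi-frame) or file-per-frame series only.
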