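---
title: "Methods: streamline clustering and multi-session reliability"
author: "tractrel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: streamline clustering and multi-session reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tractrel)
```

## Scope and model

`tractrel` analyses the *output* of probabilistic tractography: bundles of
streamlines (3D polylines in AC–PC-aligned millimetre space) reconstructed
for one subject, session, seed-to-target connection and hemisphere. It
does not perform tracking, registration or any image processing — the
package consumes tractograms (MRtrix TCK layout) and produces reliability
statistics. The six connections it parameterises run from the nucleus
accumbens to mPFC, ACC, HPC, AMY, VTA and dmT.

The underlying measurement model is simple: a connection has a true
central trajectory; each scan session yields a cloud of streamlines
scattered around it, contaminated by overlong tracks and occasional
detours over contralateral structures; and sessions differ by small,
approximately rigid spatial perturbations (positioning, movement,
susceptibility). Reliability is then the spatial agreement of the
per-session central trajectories.

## The pipeline

### Filtering

`filterByLength()` drops streamlines whose polygonal arc length exceeds
the connection's maximum fiber length — ACC 55, AMY 40, HPC 65, mPFC 55,
dmT 30, VTA 30 mm. The comparison is **inclusive**: a "maximum length" is
read as an upper bound that may be attained, so a 55 mm fiber survives a
55 mm cap. `filterByRoi()` additionally tests passage through a waypoint
region (axis-aligned box in mm, or a NIfTI binary mask). Membership tests
both vertices **and** segment–region intersection: a waypoint only a few
voxels thick can be crossed between two consecutive points at ordinary
point spacing, so a vertex-only test would silently leak. Both a
`require` mode (keep streamlines that traverse the region) and an
`exclude` mode (keep those that do not) are provided; which is
appropriate is a per-connection modelling choice, with `require` the
default. Filters are idempotent and preserve input order, and every
filter reports kept/removed counts — the bookkeeping that makes a
pipeline auditable.

### Landmark clustering

Each streamline is summarised by a **landmark signature**: its start
point, end point, the two interior points at 1/3 and 2/3 of arc length,
and its arc length. "Two equidistant points along the path" is read as
the two interior points that divide the arc into thirds, making the four
landmarks mutually equidistant along the path; no finer definition is
available, and thirds are the unique choice with that property. Two
streamlines are **compatible** when every one of the four landmark pairs
lies within `distThresh` (default 10 mm, inclusive) *and* the relative
length difference is at most `lenThresh` (default 10%, inclusive). Two
readings of that length criterion were possible; the denominator is taken
as the *shorter* of the two lengths, the strictest symmetric choice, and
the landmark criterion is applied per landmark rather than to a sum — a
single divergent landmark is enough to separate paths.

Two clustering algorithms operate over the same criteria:

* **leader** (default): one pass in input order; a streamline joins the
  first cluster whose *founding member* is compatible with it, else
  founds a new cluster. Cost O(n·k), deterministic for a fixed order;
  suitable for the 10^5–10^7 streamlines probabilistic tracking produces.
* **graph**: connected components of the pairwise compatibility graph
  (components computed with `igraph`). O(n²) but order-invariant; the
  reference semantics, and the mode the test suite checks against an
  independent brute-force union–find oracle.

On well-separated bundles the two agree exactly; on length continua
(e.g. truncation-induced length spread) graph mode chains clusters that
leader mode may split. Orientation is normalised first: every streamline
is kept or reversed to minimise start–start plus end–end distance to a
common reference streamline, with ties keeping the original orientation.

The **main pathway** is the largest cluster; ties go to the cluster whose
founder has the lowest input index, which makes the selection
deterministic.

### Centroid trajectories and distances

The centroid of a cluster is built in three steps: every member is
resampled to N points uniformly in *normalised* arc length, with
N = floor(median member length / step) + 1; the centroid is the
index-wise mean; and the mean polyline is finally resampled at `step`
(default 0.8 mm) so consecutive points are a fixed arc-length apart.
Normalised-arc resampling is the part that makes the mean well defined
when members have unequal lengths, and it reduces to the member's own
equidistant resampling when all members coincide.

Equidistant resampling places points at arc positions 0, step, …,
k·step with k = floor(L/step), then appends the original endpoint iff
its residual arc distance exceeds step/2 — keeping the fixed grid while
never discarding more than half a step of path. The floor is computed
with a 1e-9 slack so that exact multiples (8 mm at 0.8 mm steps) are not
lost to binary rounding.

Per subject, connection and hemisphere, the **shortest** centroid
trajectory is the reference (ties to the lowest session id). Distances
are computed **point by point at matching step indices** from the
streamline start, over the reference's point count (the reference is
shortest, so the pairing is total on its indices). Index pairing was
chosen over nearest-neighbour pairing deliberately: nearest-point
distances systematically understate deviations and would make the
statistics optimistic; index pairing matches a per-step reading of the
distance profile. The profile length convention means the distal tail of
a longer trajectory beyond the reference's length is not scored.

### The three statistics

* `session max` — max of a profile's distances (mm), per subject ×
  session × connection × hemisphere; the reference's self-distance is 0.
* `avg max` — mean of a subject's session maxima over the selected
  sessions.
* `max mean` — grand mean of session maxima over all subjects and
  selected sessions, per connection × hemisphere.

Whether the reference session's zero participates in the averages is
genuinely ambiguous; `tractrel` defaults to `exclude_ref` (a
self-distance of zero carries no information about reliability) and
offers `include_ref` for a literal all-sessions mean. The choice shifts
averages by a factor (s−1)/s for s sessions and is recorded in every
summary object.

## The synthetic study

`simulateBundle()` draws streamlines as noisy copies of a smooth
prototype (natural cubic spline through ≥4 control points, chord-length
parameterised, sampled at ≤0.4 mm):

* **perpendicular jitter**: two independent smooth Gaussian fields along
  the arc (white noise convolved with a Gaussian kernel of width
  `jitterSmoothness`, standardised to marginal sd `jitterSd`) displace
  each point in the local normal plane. Perpendicular rather than
  isotropic jitter keeps lengths comparable, so the 10% length criterion
  is exercised only by the explicit truncation parameter.
* **end truncation**: each end loses U(0, `lengthVarFrac`)·L of arc,
  emulating variable tracking termination.
* **outliers**: a fixed floor(`outlierFrac`·n) of streamlines detour
  through prototype-midpoint + `outlierOffset`, with a smooth Gaussian
  bump profile — the synthetic analogue of contralateral stray paths,
  removable by a waypoint ROI.

`simulateSessions()` repeats the bundle with fresh jitter per session
plus one rigid transform per session (translation sd `sessionShiftSd`,
rotation sd `sessionRotSd` about the bundle midpoint). Rigid perturbation
plus fresh jitter is the simplest session model with a known ground-truth
answer: a pure translation of magnitude d must be recovered as a session
max of exactly d.

Defaults — 500 streamlines, 1 mm jitter with 5 mm correlation length, 5%
truncation, 5% outliers at 12 mm offset, 7 sessions, 0.5 mm / 0.5°
session perturbation — are what we consider a realistic post-filtering
bundle at this anatomical scale, and they place the resulting statistics
in the 1–2 mm range typical of test-retest tractography. The shipped
prototype curves are *illustrative*: correct in scale and rough direction
for the six connections, with no finer anatomical claim.

What the simulator does **not** emulate: curving systematic biases
between sessions (only rigid ones), heteroscedastic jitter along the
tract (real uncertainty concentrates near seed and target), partial-volume
and crossing-fiber artifacts, and any imaging physics. Green tests
therefore demonstrate correctness of the *analysis* under its own model,
not fidelity of tractography itself.

## Numerical choices and degenerate inputs

* TCK I/O is bit-exact at 32-bit float precision (the on-disk format);
  geometry is held in doubles internally. The on-disk format of the
  intermediate tracts is an assumption documented here: TCK is what the
  MRtrix tool chain that produces such bundles writes.
* A streamline must have ≥2 points, finite coordinates and no zero-length
  segments; violations are refused at construction and on file read.
* Resampling a path shorter than one step, clustering an empty
  tractogram, selecting a reference among fewer than two sessions, and
  summarising an empty profile set are errors, not silent defaults.
* Centroid spacing validity allows a small curvature deficit (chords of a
  fixed arc step shorten where the path bends) but never an excess.
* All tie-breaks (orientation flip, main-cluster selection, reference
  selection) resolve toward the original orientation / lowest index /
  lowest session, making every stage deterministic.

## Problem sizes

The test suite and the acceptance script run the synthetic study at 200
streamlines × 7 sessions per connection (40–100 for targeted unit
checks), sizes at which the Monte-Carlo properties under test (centroid
convergence, shift recovery within 5%, monotonicity in jitter) are
comfortably resolved while the whole suite stays fast.

## Limitations

* Statistics are descriptive; no confidence intervals or tests are
  attached (none are defined for this workflow).
* Leader-mode partitions depend on streamline order; the order produced
  by the upstream tracker is treated as canonical. Graph mode is
  available when order invariance matters.
* Real per-subject reliability values from the motivating application
  cannot be recomputed without the original (undeposited) diffusion data;
  the package validates metric definitions and recovery properties on
  synthetic ground truth instead.
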