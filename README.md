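# tractrel

Test-retest reliability analysis of tractography streamline bundles.

## The problem

Deep-brain-stimulation planning based on diffusion MRI tractography is only
defensible if the reconstructed fiber tracts are *stable*: reconstructing
the same connection from repeated scans of the same person must land the
trajectory in (nearly) the same place. `tractrel` implements the
post-tractography half of that question for seed-to-target connections of
the nucleus accumbens (NAc) to six targets — mPFC, ACC, HPC, AMY, VTA and
dmT — across repeated scan sessions:

1. **Filtering.** Streamlines longer than a per-connection maximum fiber
   length (ACC 55, AMY 40, HPC 65, mPFC 55, dmT 30, VTA 30 mm) are
   discarded, and an optional thin waypoint ROI removes paths that detour
   over contralateral structures.
2. **Clustering.** Streamlines are grouped into clusters of similar paths.
   Two streamlines are compatible when each of four landmarks — start
   point, end point, and the two points at 1/3 and 2/3 of arc length —
   lies within a Euclidean distance of 10 mm of its counterpart, **and**
   the path lengths differ by at most 10% (relative to the shorter). The
   *main pathway* is the largest cluster.
3. **Centroid trajectories.** Each session's main pathway is reduced to
   its centroid path, resampled at 0.8 mm arc-length steps.
4. **Reliability statistics.** Per subject, connection and hemisphere, the
   *shortest* centroid trajectory is the reference; Euclidean distances to
   it are computed point by point at each 0.8 mm step. Three summaries are
   reported:
   - **session max** — the maximum distance of one session's trajectory to
     the reference;
   - **average max** — the mean of a subject's session maxima;
   - **maximum mean** — the grand mean of session maxima over all subjects
     and sessions, per connection and hemisphere.

Because raw multi-session diffusion data of this kind are not publicly
available, the package ships a synthetic multi-session bundle simulator
(`simulateBundle()`, `simulateSessions()`) with known ground truth: smooth
prototype curves per connection, perpendicular correlated jitter, end
truncation, a minority of outlier detours, and small rigid per-session
perturbations. Every stage of the pipeline is validated against it.

## Worked example

Simulate seven sessions of a right NAc–ACC bundle (200 streamlines, 1 mm
perpendicular jitter, 0.5 mm / 0.5° rigid session perturbations), then run
the full analysis:

```r
library(tractrel)

bs   <- bundleSpec(controlPoints = prototypeLibrary("R")[["ACC"]],
                   nStreamlines = 200, seed = 42)
ss   <- sessionSpec(nSessions = 7, seed = 42)
sims <- simulateSessions(bs, ss, connection = "ACC", hemisphere = "R")

res  <- analyzeConnection(lapply(sims$sessions, `[[`, "tractogram"))
summ <- summarizeReliability(res$profiles)
summ
#> ReliabilitySummary (exclude_ref)
#>   7 session-level maxima, 1 subject averages
#>   maximum mean distances (mm):
#>     ACC R: 1.207

head(sessionMax(summ))
#>   subject session connection hemisphere isReference maxDistance
#> 1   sim01       1        ACC          R       FALSE   1.3271014
#> 2   sim01       2        ACC          R       FALSE   0.8526320
#> 3   sim01       3        ACC          R        TRUE   0.0000000
#> 4   sim01       4        ACC          R       FALSE   1.8074834
#> 5   sim01       5        ACC          R       FALSE   0.9277144
#> 6   sim01       6        ACC          R       FALSE   1.2808598
```

Session 3 produced the shortest centroid trajectory and serves as the
reference (its self-distance is 0). The other sessions' centroids deviate
from it by at most 0.85–1.81 mm at the worst point along the path, and the
maximum mean distance of 1.21 mm summarises the connection's overall
session-to-session stability — small relative to the ~2 mm accuracy
usually quoted for stereotactic electrode placement.

The per-session centroid is itself an object worth inspecting:

```r
res$centroids[[1]]
#> CentroidTrajectory: 42 points, step 0.8 mm, 190 member(s)
#>    subject=sim01 session=1 connection=ACC hemisphere=R
```

Tractograms can be read from and written to MRtrix `.tck` files
(`readTck()` / `writeTck()`, bit-exact round trip at 32-bit precision),
with subject/session/connection/hemisphere metadata taken from header
keys or from a `<subject>_<session>_<connection>_<hemi>.tck` filename.
`runPipeline()` drives the whole workflow from a YAML configuration and
writes `clusters.json`, centroid `.tck` files, `profiles.csv`,
`summary.csv` and a log of per-stage streamline counts.

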