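Package: tractrel
Title: Test-Retest Reliability Analysis of Tractography Streamline Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-tractography analysis of white-matter fiber bundles:
    reading and writing MRtrix TCK tractograms, length- and waypoint-ROI
    filtering of streamlines, landmark-based clustering of fiber paths
    (start point, end point, two equidistant interior points, and path
    length), centroid trajectories resampled at a fixed arc-length step,
    and multi-session Euclidean-distance reliability statistics (per-session
    maxima, per-subject average maxima, and grand maximum-mean distances).
    Includes a synthetic multi-session fiber-bundle simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'geometry.R'
    'tck-io.R'
    'roi.R'
    'filtering.R'
    'clustering.R'
    'reliability.R'
    'synthetic.R'
    'pipeline.R'
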