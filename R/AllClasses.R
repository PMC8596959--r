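#' @import methods
NULL

## Fixed vocabulary for the six seed-to-target connections analysed by the
## pipeline (nucleus accumbens to medial prefrontal cortex, anterior cingulate
## cortex, hippocampus, amygdala, ventral tegmental area, dorsomedial thalamus).
.CONNECTIONS <- c("mPFC", "ACC", "HPC", "AMY", "VTA", "dmT")
.HEMISPHERES <- c("L", "R")

.validStreamline <- function(p, what = "streamline") {
  if (!is.matrix(p) || !is.numeric(p) || ncol(p) != 3L)
    return(sprintf("%s must be a numeric matrix with 3 columns", what))
  if (nrow(p) < 2L)
    return(sprintf("%s must have at least 2 points", what))
  if (!all(is.finite(p)))
    return(sprintf("%s contains non-finite coordinates", what))
  seg <- diff(p)
  if (any(rowSums(seg * seg) == 0))
    return(sprintf("%s has consecutive identical points", what))
  TRUE
}

#' Tractogram: a collection of streamlines with spatial and study metadata
#'
#' A `Tractogram` holds the streamlines reconstructed for one subject,
#' session, seed-to-target connection and hemisphere. Each streamline is a
#' numeric matrix with one row per point and columns x, y, z in millimetres,
#' in AC-PC-aligned space (anterior commissure at the origin, x left to
#' right, y posterior to anterior, z inferior to superior).
#'
#' @slot streamlines list of numeric n-by-3 matrices (mm), ordered from the
#'   seed end to the target end.
#' @slot spaceId label of the coordinate frame (default `"acpc-mm"`).
#' @slot subject subject identifier (`NA` when unset).
#' @slot session session number, 1-7 (`NA` when unset).
#' @slot connection one of `"mPFC"`, `"ACC"`, `"HPC"`, `"AMY"`, `"VTA"`,
#'   `"dmT"` (`NA` when unset).
#' @slot hemisphere `"L"` or `"R"` (`NA` when unset).
#' @slot header named character vector of key-value pairs carried through
#'   from the on-disk track file header.
#' @export
setClass("Tractogram",
  representation(
    streamlines = "list",
    spaceId     = "character",
    subject     = "character",
    session     = "integer",
    connection  = "character",
    hemisphere  = "character",
    header      = "character"
  ),
  prototype(
    streamlines = list(),
    spaceId     = "acpc-mm",
    subject     = NA_character_,
    session     = NA_integer_,
    connection  = NA_character_,
    hemisphere  = NA_character_,
    header      = character()
  )
)

setValidity("Tractogram", function(object) {
  msgs <- character()
  for (i in seq_along(object@streamlines)) {
    v <- .validStreamline(object@streamlines[[i]], sprintf("streamline %d", i))
    if (!isTRUE(v)) { msgs <- c(msgs, v); break }
  }
  if (!is.na(object@session) &&
      (object@session < 1L || object@session > 7L))
    msgs <- c(msgs, "session must be in 1..7")
  if (!is.na(object@connection) && !(object@connection %in% .CONNECTIONS))
    msgs <- c(msgs, sprintf("connection must be one of %s",
                            paste(.CONNECTIONS, collapse = ", ")))
  if (!is.na(object@hemisphere) && !(object@hemisphere %in% .HEMISPHERES))
    msgs <- c(msgs, "hemisphere must be 'L' or 'R'")
  if (length(msgs)) msgs else TRUE
})

#' Construct a Tractogram
#'
#' @param streamlines list of numeric n-by-3 matrices in mm.
#' @param subject,session,connection,hemisphere study metadata; `NA` when
#'   unknown.
#' @param spaceId coordinate-frame label.
#' @param header named character vector of file header key-value pairs.
#' @return A [Tractogram-class] object.
#' @examples
#' t <- tractogram(list(cbind(0, c(0, 8), 0)), connection = "VTA")
#' nStreamlines(t)
#' @export
tractogram <- function(streamlines, subject = NA_character_,
                       session = NA_integer_, connection = NA_character_,
                       hemisphere = NA_character_, spaceId = "acpc-mm",
                       header = character()) {
  streamlines <- lapply(streamlines, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  new("Tractogram", streamlines = streamlines, spaceId = spaceId,
      subject = as.character(subject), session = as.integer(session),
      connection = as.character(connection),
      hemisphere = as.character(hemisphere), header = header)
}

#' Region of interest for waypoint filtering
#'
#' Virtual parent of [BoxRoi-class] (axis-aligned box in mm) and
#' [MaskRoi-class] (binary voxel mask with a voxel-to-mm affine).
#' @export
setClass("RoiRegion", representation("VIRTUAL"))

#' @rdname RoiRegion-class
#' @slot minCorner,maxCorner numeric(3), opposite corners in mm with
#'   `minCorner` strictly less than `maxCorner` on all axes.
#' @export
setClass("BoxRoi", contains = "RoiRegion",
  representation(minCorner = "numeric", maxCorner = "numeric"))

setValidity("BoxRoi", function(object) {
  if (length(object@minCorner) != 3L || length(object@maxCorner) != 3L)
    return("corners must be numeric vectors of length 3")
  if (!all(is.finite(c(object@minCorner, object@maxCorner))))
    return("corners must be finite")
  if (!all(object@minCorner < object@maxCorner))
    return("minCorner must be strictly less than maxCorner on all axes")
  TRUE
})

#' @rdname RoiRegion-class
#' @slot mask 3D array, nonzero voxels are inside the region.
#' @slot affine 4x4 matrix mapping 0-based voxel indices to mm coordinates.
#' @export
setClass("MaskRoi", contains = "RoiRegion",
  representation(mask = "array", affine = "matrix"))

setValidity("MaskRoi", function(object) {
  if (length(dim(object@mask)) != 3L)
    return("mask must be a 3D array")
  if (!any(object@mask != 0))
    return("ROI contains no voxels")
  if (!all(dim(object@affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (abs(det(object@affine[1:3, 1:3])) < .Machine$double.eps)
    return("affine must be invertible")
  TRUE
})

#' Clustering and comparison parameters
#'
#' Bundles the tunable parameters of the clustering criteria and the
#' trajectory comparison: the landmark distance threshold (10 mm), the
#' maximum relative path-length difference (10%), the arc-length resampling
#' step (0.8 mm), and the per-connection maximum fiber lengths
#' (ACC 55, AMY 40, HPC 65, mPFC 55, dmT 30, VTA 30 mm).
#'
#' @slot distThresh landmark distance threshold in mm.
#' @slot lenThresh maximum relative length difference (fraction, < 1).
#' @slot step arc-length resampling step in mm.
#' @slot maxLength named numeric vector of per-connection maximum fiber
#'   lengths in mm.
#' @export
setClass("TrackParameters",
  representation(distThresh = "numeric", lenThresh = "numeric",
                 step = "numeric", maxLength = "numeric"))

setValidity("TrackParameters", function(object) {
  v <- c(object@distThresh, object@lenThresh, object@step, object@maxLength)
  if (!all(is.finite(v)) || !all(v > 0))
    return("all parameters must be finite and strictly positive")
  if (object@lenThresh >= 1)
    return("lenThresh must be a fraction < 1")
  if (!all(.CONNECTIONS %in% names(object@maxLength)))
    return("maxLength must name all six connections")
  TRUE
})

#' @param distThresh landmark distance threshold in mm (default 10).
#' @param lenThresh maximum relative length difference (default 0.10).
#' @param step resampling step in mm (default 0.8).
#' @param maxLength named per-connection maximum lengths in mm.
#' @return A [TrackParameters-class] object.
#' @rdname TrackParameters-class
#' @examples
#' p <- trackParameters()
#' p@maxLength[["HPC"]]
#' @export
trackParameters <- function(distThresh = 10, lenThresh = 0.10, step = 0.8,
                            maxLength = c(ACC = 55, AMY = 40, HPC = 65,
                                          mPFC = 55, dmT = 30, VTA = 30)) {
  new("TrackParameters", distThresh = distThresh, lenThresh = lenThresh,
      step = step, maxLength = maxLength)
}

#' Result of clustering a tractogram
#'
#' Partition of the streamlines of one tractogram into clusters of mutually
#' compatible paths. Each cluster records its member indices and the index
#' of its founding member, whose landmark signature is the cluster
#' representative.
#'
#' @slot members list of integer vectors, indices into the source tractogram.
#' @slot founders integer vector, founding member of each cluster.
#' @slot mode `"leader"` or `"graph"`.
#' @slot nStreamlines number of streamlines in the clustered tractogram.
#' @export
setClass("StreamlineClusters",
  representation(members = "list", founders = "integer", mode = "character",
                 nStreamlines = "integer"))

setValidity("StreamlineClusters", function(object) {
  if (length(object@members) == 0L)
    return("at least one cluster required")
  all_idx <- unlist(object@members)
  if (anyDuplicated(all_idx))
    return("cluster member sets must be disjoint")
  if (!setequal(all_idx, seq_len(object@nStreamlines)))
    return("clusters must partition all streamline indices")
  if (length(object@founders) != length(object@members))
    return("one founder per cluster required")
  ok <- vapply(seq_along(object@members), function(i)
    object@founders[i] %in% object@members[[i]], logical(1))
  if (!all(ok))
    return("each founder must belong to its cluster")
  TRUE
})

#' Centroid trajectory of a streamline cluster
#'
#' The mean path of a cluster, resampled at a fixed arc-length step
#' (default 0.8 mm). Centroid trajectories are the unit of inter-session
#' comparison.
#'
#' @slot points numeric n-by-3 matrix (mm) with consecutive spacing equal to
#'   `step` except possibly the final segment.
#' @slot step resampling step in mm.
#' @slot subject,session,connection,hemisphere study metadata.
#' @slot nMembers number of streamlines that contributed.
#' @export
setClass("CentroidTrajectory",
  representation(points = "matrix", step = "numeric", subject = "character",
                 session = "integer", connection = "character",
                 hemisphere = "character", nMembers = "integer"))

setValidity("CentroidTrajectory", function(object) {
  v <- .validStreamline(object@points, "centroid")
  if (!isTRUE(v)) return(v)
  if (object@nMembers < 1L) return("nMembers must be >= 1")
  if (object@step <= 0) return("step must be positive")
  ## points are spaced exactly `step` apart along the polyline; the chord
  ## distance checked here is shorter where the path bends, so allow a
  ## small curvature deficit but never an excess
  seg <- sqrt(rowSums(diff(object@points)^2))
  if (length(seg) > 1L) {
    inner <- seg[-length(seg)]
    if (any(inner > object@step + 1e-6) ||
        any(inner < object@step * 0.9))
      return("consecutive spacing must equal step (except final segment)")
  }
  TRUE
})

#' Point-by-point distance profile between two centroid trajectories
#'
#' Euclidean distances between index-paired points of a session's centroid
#' trajectory and the reference (shortest) trajectory, both resampled at the
#' same arc-length step.
#'
#' @slot distances numeric vector of mm distances, one per resampling step.
#' @slot step resampling step in mm.
#' @slot session,referenceSession session ids of the compared trajectories.
#' @slot subject,connection,hemisphere study metadata.
#' @export
setClass("DistanceProfile",
  representation(distances = "numeric", step = "numeric", session = "integer",
                 referenceSession = "integer", subject = "character",
                 connection = "character", hemisphere = "character"))

setValidity("DistanceProfile", function(object) {
  if (any(object@distances < 0)) return("distances must be non-negative")
  TRUE
})

#' Multi-session reliability summary
#'
#' The three-level summary of inter-session trajectory agreement:
#' per-session maximum distances to the shortest trajectory, per-subject
#' average maxima, and the grand maximum-mean distance per connection and
#' hemisphere.
#'
#' @slot sessionMax data.frame with columns subject, session, connection,
#'   hemisphere, isReference, maxDistance (mm).
#' @slot avgMax data.frame with columns subject, connection, hemisphere,
#'   avgMax (mm).
#' @slot maxMean data.frame with columns connection, hemisphere, maxMean (mm).
#' @slot policy `"exclude_ref"` or `"include_ref"`: whether the reference
#'   session's (zero) self-distance enters the averages.
#' @export
setClass("ReliabilitySummary",
  representation(sessionMax = "data.frame", avgMax = "data.frame",
                 maxMean = "data.frame", policy = "character"))

#' Specification of a synthetic fiber bundle
#'
#' Parameters of the synthetic bundle generator: a smooth prototype
#' trajectory through control points, per-streamline perpendicular jitter
#' with a tunable correlation length, symmetric end truncation, and a
#' minority of outlier paths detoured through an offset region.
#'
#' @slot controlPoints numeric matrix (>= 4 rows) of 3D control points (mm).
#' @slot nStreamlines number of streamlines to generate.
#' @slot jitterSd standard deviation of perpendicular jitter (mm).
#' @slot jitterSmoothness correlation length of the jitter along the arc (mm).
#' @slot lengthVarFrac maximum fraction of arc length truncated at each end.
#' @slot outlierFrac fraction of streamlines routed through the detour.
#' @slot outlierOffset 3D displacement (mm) of the detour region.
#' @slot seed RNG seed.
#' @export
setClass("BundleSpec",
  representation(controlPoints = "matrix", nStreamlines = "integer",
                 jitterSd = "numeric", jitterSmoothness = "numeric",
                 lengthVarFrac = "numeric", outlierFrac = "numeric",
                 outlierOffset = "numeric", seed = "integer"))

setValidity("BundleSpec", function(object) {
  if (nrow(object@controlPoints) < 4L || ncol(object@controlPoints) != 3L)
    return("at least 4 three-dimensional control points required")
  if (object@nStreamlines < 1L) return("nStreamlines must be >= 1")
  if (object@jitterSd < 0) return("jitterSd must be >= 0")
  if (object@jitterSmoothness <= 0) return("jitterSmoothness must be > 0")
  if (object@outlierFrac < 0 || object@outlierFrac >= 1)
    return("outlierFrac must be in [0, 1)")
  if (object@lengthVarFrac < 0 || object@lengthVarFrac >= 0.5)
    return("lengthVarFrac must be in [0, 0.5)")
  if (length(object@outlierOffset) != 3L)
    return("outlierOffset must be a 3-vector")
  TRUE
})

#' Specification of repeated measurement sessions
#'
#' Models repeated scan sessions of the same bundle: each session redraws
#' the streamline jitter and applies a small rigid perturbation (random
#' translation plus rotation about the bundle midpoint), emulating
#' positioning and susceptibility differences between scans.
#'
#' @slot nSessions number of sessions (default 7).
#' @slot sessionShiftSd per-axis sd of the rigid session translation (mm).
#' @slot sessionRotSd sd of the session rotation angle (degrees).
#' @slot seed RNG seed for the session transforms.
#' @export
setClass("SessionSpec",
  representation(nSessions = "integer", sessionShiftSd = "numeric",
                 sessionRotSd = "numeric", seed = "integer"))

setValidity("SessionSpec", function(object) {
  if (object@nSessions < 2L) return("nSessions must be >= 2")
  if (object@sessionShiftSd < 0 || object@sessionRotSd < 0)
    return("session perturbation sds must be >= 0")
  TRUE
})
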