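#' @include AllClasses.R
NULL

#' Accessors for tractograms and derived objects
#'
#' @param x,object a package object.
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("streamlines", function(x) standardGeneric("streamlines"))

#' @rdname accessors
#' @export
setGeneric("nStreamlines", function(x) standardGeneric("nStreamlines"))

#' @rdname accessors
#' @export
setGeneric("roiContains", function(roi, points)
  standardGeneric("roiContains"))

#' @rdname accessors
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x, i) standardGeneric("clusterMembers"))

#' @rdname accessors
#' @export
setGeneric("centroidPoints", function(x) standardGeneric("centroidPoints"))

#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname accessors
#' @export
setGeneric("sessionMax", function(x) standardGeneric("sessionMax"))

#' @rdname accessors
#' @export
setGeneric("avgMax", function(x) standardGeneric("avgMax"))

#' @rdname accessors
#' @export
setGeneric("maxMean", function(x) standardGeneric("maxMean"))

#' @rdname accessors
setMethod("streamlines", "Tractogram", function(x) x@streamlines)

#' @rdname accessors
setMethod("nStreamlines", "Tractogram",
          function(x) length(x@streamlines))

#' @rdname accessors
setMethod("clusterSizes", "StreamlineClusters",
          function(x) vapply(x@members, length, integer(1)))

#' @rdname accessors
setMethod("clusterMembers", "StreamlineClusters",
          function(x, i) x@members[[i]])

#' @rdname accessors
setMethod("centroidPoints", "CentroidTrajectory", function(x) x@points)

#' @rdname accessors
setMethod("distances", "DistanceProfile", function(x) x@distances)

#' @rdname accessors
setMethod("sessionMax", "ReliabilitySummary", function(x) x@sessionMax)

#' @rdname accessors
setMethod("avgMax", "ReliabilitySummary", function(x) x@avgMax)

#' @rdname accessors
setMethod("maxMean", "ReliabilitySummary", function(x) x@maxMean)

setMethod("show", "Tractogram", function(object) {
  cat(sprintf("Tractogram with %d streamline(s) [%s]\n",
              length(object@streamlines), object@spaceId))
  meta <- c(subject = object@subject, session = object@session,
            connection = object@connection, hemisphere = object@hemisphere)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = "=", collapse = " "), "\n")
  if (length(object@streamlines)) {
    np <- vapply(object@streamlines, nrow, integer(1))
    cat(sprintf("  points per streamline: %d-%d (median %g)\n",
                min(np), max(np), stats::median(np)))
  }
})

setMethod("show", "BoxRoi", function(object) {
  cat(sprintf("BoxRoi [%g, %g] x [%g, %g] x [%g, %g] mm\n",
              object@minCorner[1], object@maxCorner[1],
              object@minCorner[2], object@maxCorner[2],
              object@minCorner[3], object@maxCorner[3]))
})

setMethod("show", "MaskRoi", function(object) {
  cat(sprintf("MaskRoi %s voxels, %d inside\n",
              paste(dim(object@mask), collapse = "x"),
              sum(object@mask != 0)))
})

setMethod("show", "StreamlineClusters", function(object) {
  sz <- sort(vapply(object@members, length, integer(1)), decreasing = TRUE)
  cat(sprintf("StreamlineClusters: %d cluster(s) over %d streamline(s) [%s mode]\n",
              length(object@members), object@nStreamlines, object@mode))
  cat("  sizes:", paste(utils::head(sz, 10), collapse = ", "),
      if (length(sz) > 10) "..." else "", "\n")
})

setMethod("show", "CentroidTrajectory", function(object) {
  cat(sprintf(
    "CentroidTrajectory: %d points, step %g mm, %d member(s)\n",
    nrow(object@points), object@step, object@nMembers))
  meta <- c(subject = object@subject, session = object@session,
            connection = object@connection, hemisphere = object@hemisphere)
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = "=", collapse = " "), "\n")
})

setMethod("show", "DistanceProfile", function(object) {
  cat(sprintf(
    "DistanceProfile: session %d vs reference %d, %d steps, max %.3g mm\n",
    object@session, object@referenceSession, length(object@distances),
    if (length(object@distances)) max(object@distances) else NA))
})

setMethod("show", "ReliabilitySummary", function(object) {
  cat(sprintf("ReliabilitySummary (%s)\n", object@policy))
  cat(sprintf("  %d session-level maxima, %d subject averages\n",
              nrow(object@sessionMax), nrow(object@avgMax)))
  if (nrow(object@maxMean)) {
    cat("  maximum mean distances (mm):\n")
    m <- object@maxMean
    for (i in seq_len(nrow(m)))
      cat(sprintf("    %s %s: %.3f\n", m$connection[i], m$hemisphere[i],
                  m$maxMean[i]))
  }
})
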