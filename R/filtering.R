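#' @include roi.R
NULL

.filterReport <- function(keep) {
  list(kept = sum(keep), removed = sum(!keep))
}

#' Filter streamlines by maximum fiber length
#'
#' Keeps exactly the streamlines whose polygonal arc length does not exceed
#' `maxLength` (inclusive bound: a fiber at exactly the maximum length is
#' kept), preserving input order. Overlong streamlines are artifacts of
#' tracking past the target (over-sprouting, loops, indirect relays); each
#' seed-target connection has its own maximum (see
#' [trackParameters()]).
#'
#' @param t a [Tractogram-class].
#' @param maxLength maximum fiber length in mm. Defaults to the
#'   per-connection value from `params` when `t` carries a connection id.
#' @param params a [TrackParameters-class] supplying the per-connection
#'   length table.
#' @return List with `tractogram` (the filtered [Tractogram-class]) and
#'   `report` (`kept` / `removed` counts).
#' @export
filterByLength <- function(t, maxLength = NULL, params = trackParameters()) {
  if (is.null(maxLength)) {
    if (is.na(t@connection))
      stop("maxLength not given and tractogram has no connection id")
    maxLength <- params@maxLength[[t@connection]]
  }
  stopifnot(maxLength > 0)
  keep <- streamlineLengths(t) <= maxLength
  t@streamlines <- t@streamlines[keep]
  list(tractogram = t, report = .filterReport(keep))
}

#' Filter streamlines by passage through a waypoint ROI
#'
#' In `"require"` mode keeps the streamlines that pass through the region
#' (a vertex inside it, or a segment crossing it); in `"exclude"` mode
#' keeps those that do not. Requiring passage through a tract-specific
#' waypoint removes inhomogeneous path courses, e.g. detours over
#' contralateral structures; excluding a region expresses the same goal
#' from the other side. Input order is preserved.
#'
#' @param t a [Tractogram-class].
#' @param roi a [RoiRegion-class].
#' @param mode `"require"` (default) or `"exclude"`.
#' @return List with `tractogram` and `report` (`kept` / `removed`).
#' @export
filterByRoi <- function(t, roi, mode = c("require", "exclude")) {
  mode <- match.arg(mode)
  hit <- vapply(t@streamlines, streamlineIntersectsRoi, logical(1),
                roi = roi)
  keep <- if (mode == "require") hit else !hit
  t@streamlines <- t@streamlines[keep]
  list(tractogram = t, report = .filterReport(keep))
}
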