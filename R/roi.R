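#' @include tck-io.R
NULL

#' Construct an axis-aligned box ROI
#'
#' @param minCorner,maxCorner numeric(3) opposite corners in mm;
#'   `minCorner` strictly less than `maxCorner` on all axes.
#' @return A [BoxRoi-class].
#' @examples
#' roi <- boxRoi(c(-2, 20, -4), c(2, 24, 0))
#' roiContains(roi, rbind(c(0, 22, -2), c(0, 30, 0)))
#' @export
boxRoi <- function(minCorner, maxCorner) {
  new("BoxRoi", minCorner = as.numeric(minCorner),
      maxCorner = as.numeric(maxCorner))
}

#' Construct a binary-mask ROI
#'
#' @param mask 3D array; nonzero voxels are inside the region.
#' @param affine 4x4 matrix mapping 0-based voxel indices to mm.
#' @return A [MaskRoi-class].
#' @export
maskRoi <- function(mask, affine) {
  if (!any(mask != 0)) stop("ROI contains no voxels")
  new("MaskRoi", mask = mask, affine = affine)
}

#' Read an ROI from a file or inline box specification
#'
#' Accepts a NIfTI binary mask (`.nii` / `.nii.gz`), a YAML or JSON file
#' with `min` and `max` entries (mm), or an inline list/vector box
#' specification.
#'
#' @param x path to a NIfTI, YAML or JSON file; a list with `min` and `max`
#'   3-vectors; or a numeric vector of 6 values
#'   `(xmin, ymin, zmin, xmax, ymax, zmax)`.
#' @return A [RoiRegion-class].
#' @export
readRoi <- function(x) {
  if (is.numeric(x) && length(x) == 6L)
    return(boxRoi(x[1:3], x[4:6]))
  if (is.list(x)) {
    if (is.null(x$min) || is.null(x$max))
      stop("box specification must have 'min' and 'max' entries")
    return(boxRoi(unlist(x$min), unlist(x$max)))
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (!file.exists(x)) stop("ROI file not found: ", x)
  if (grepl("\\.nii(\\.gz)?$", x)) {
    img <- RNifti::readNifti(x)
    arr <- as.array(img)
    if (length(dim(arr)) > 3L)
      arr <- array(arr, dim = dim(arr)[1:3])
    if (!any(arr != 0)) stop("ROI contains no voxels")
    return(maskRoi(arr != 0, structure(RNifti::xform(img),
                                       dimnames = NULL)))
  }
  spec <- if (grepl("\\.ya?ml$", x)) yaml::read_yaml(x)
          else jsonlite::read_json(x, simplifyVector = TRUE)
  readRoi(spec)
}

#' @describeIn readRoi Membership of mm-space points in a box ROI
#'   (bounds inclusive).
#' @param roi a [RoiRegion-class].
#' @param points numeric n-by-3 matrix of mm coordinates.
#' @export
setMethod("roiContains", "BoxRoi", function(roi, points) {
  points <- rbind(points)
  apply(points, 1, function(p)
    all(p >= roi@minCorner & p <= roi@maxCorner))
})

#' @describeIn readRoi Membership of mm-space points in a mask ROI: the
#'   point's voxel (nearest 0-based index under the inverse affine) must be
#'   nonzero.
#' @export
setMethod("roiContains", "MaskRoi", function(roi, points) {
  points <- rbind(points)
  vox <- solve(roi@affine) %*% rbind(t(points), 1)
  idx <- round(vox[1:3, , drop = FALSE]) + 1   # to 1-based array indices
  d <- dim(roi@mask)
  apply(idx, 2, function(v) {
    if (any(v < 1 | v > d)) FALSE
    else roi@mask[v[1], v[2], v[3]] != 0
  })
})

## Does segment p -> q intersect the axis-aligned box? Slab clipping.
.segmentInBox <- function(p, q, minC, maxC) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    if (d[ax] == 0) {
      if (p[ax] < minC[ax] || p[ax] > maxC[ax]) return(FALSE)
    } else {
      ta <- (minC[ax] - p[ax]) / d[ax]
      tb <- (maxC[ax] - p[ax]) / d[ax]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

#' Does a streamline pass through an ROI?
#'
#' Tests both the vertices and the segments: a thin region (such as a
#' 2x2-voxel coronal waypoint) can be crossed by a segment whose endpoints
#' both lie outside it, so vertex membership alone is not sufficient at
#' coarse point spacing.
#'
#' @param p numeric n-by-3 matrix of streamline points (mm).
#' @param roi a [RoiRegion-class].
#' @return `TRUE` if any vertex lies inside the ROI or any segment crosses
#'   it.
#' @export
streamlineIntersectsRoi <- function(p, roi) {
  if (any(roiContains(roi, p))) return(TRUE)
  if (is(roi, "BoxRoi")) {
    for (i in seq_len(nrow(p) - 1L))
      if (.segmentInBox(p[i, ], p[i + 1L, ], roi@minCorner, roi@maxCorner))
        return(TRUE)
    return(FALSE)
  }
  ## mask ROI: sample each segment at half the smallest voxel dimension
  voxSize <- sqrt(colSums(roi@affine[1:3, 1:3]^2))
  h <- min(voxSize) / 2
  seg <- sqrt(rowSums(diff(p)^2))
  long <- which(seg > h)
  for (i in long) {
    k <- ceiling(seg[i] / h)
    w <- seq(0, 1, length.out = k + 1L)
    pts <- outer(1 - w, p[i, ]) + outer(w, p[i + 1L, ])
    if (any(roiContains(roi, pts))) return(TRUE)
  }
  FALSE
}
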