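#' @include utils.R
NULL

#' Arc length of a streamline
#'
#' Polygonal arc length: the sum of Euclidean segment lengths of the stored
#' points. No smoothing is applied; tractography output is already densely
#' sampled.
#'
#' @param p numeric n-by-3 matrix of points (mm), or a
#'   [CentroidTrajectory-class].
#' @return Length in mm.
#' @examples
#' arcLength(cbind(c(0, 3, 3), c(0, 0, 4), 0))  # 3 + 4 = 7
#' @export
arcLength <- function(p) {
  if (is(p, "CentroidTrajectory")) p <- p@points
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Arc lengths of all streamlines in a tractogram
#'
#' @param t a [Tractogram-class].
#' @return Numeric vector of lengths in mm.
#' @export
streamlineLengths <- function(t) {
  vapply(t@streamlines, arcLength, numeric(1))
}

#' Resample a streamline at equidistant arc-length steps
#'
#' Returns points at arc lengths 0, step, 2*step, ..., k*step with
#' k = floor(L / step), followed by the original endpoint if its arc
#' distance from the last grid point exceeds step / 2. Every returned point
#' lies on the input polyline (linear interpolation); the first point is
#' the input start.
#'
#' @param p numeric n-by-3 matrix of points (mm).
#' @param step step size in mm (default 0.8).
#' @return Resampled n'-by-3 matrix.
#' @examples
#' r <- resampleEquidistant(cbind(0, c(0, 8), 0), 0.8)
#' nrow(r)  # 11 points at y = 0, 0.8, ..., 8
#' @export
resampleEquidistant <- function(p, step = 0.8) {
  stopifnot(step > 0)
  L <- arcLength(p)
  if (L < step) stop("path shorter than one step")
  ## tolerance so that e.g. 8 / 0.8 lands on k = 10 despite binary rounding
  k <- floor(L / step + 1e-9)
  out <- .interpAlong(p, (0:k) * step)
  rem <- L - k * step
  if (rem > step / 2 + 1e-9)
    out <- rbind(out, p[nrow(p), , drop = FALSE])
  out
}

#' Landmark signature of a streamline
#'
#' The four landmarks used by the clustering criteria — start point, end
#' point, and the two interior points dividing the arc length into thirds —
#' plus the arc length itself.
#'
#' @param p numeric n-by-3 matrix of points (mm).
#' @return List with `points` (4-by-3 matrix: start, 1/3, 2/3, end) and
#'   `length` (mm).
#' @examples
#' sig <- landmarkSignature(cbind(0, c(0, 9), 0))
#' sig$points[, 2]  # y = 0, 3, 6, 9
#' @export
landmarkSignature <- function(p) {
  L <- arcLength(p)
  inner <- .interpAlong(p, c(L / 3, 2 * L / 3))
  list(points = rbind(p[1, ], inner, p[nrow(p), ]), length = L)
}

#' Align the orientation of a streamline to a reference
#'
#' Probabilistic tracking is usually seeded from one end, but stored files
#' need not guarantee a consistent direction. Returns `p` or its reversal,
#' whichever minimises the sum of start-to-start and end-to-end distances
#' to `ref`; on a tie the original orientation is kept.
#'
#' @param p,ref numeric n-by-3 matrices of points (mm).
#' @return `p`, possibly reversed.
#' @export
orientAlign <- function(p, ref) {
  n <- nrow(p); m <- nrow(ref)
  dKeep <- .vecnorm(p[1, ] - ref[1, ]) + .vecnorm(p[n, ] - ref[m, ])
  dFlip <- .vecnorm(p[n, ] - ref[1, ]) + .vecnorm(p[1, ] - ref[m, ])
  if (dFlip < dKeep) p[n:1, , drop = FALSE] else p
}

#' Point-by-point Euclidean distances between two resampled streamlines
#'
#' Index-paired distances over the shorter of the two point counts. Both
#' inputs should already be resampled at the same arc-length step.
#'
#' @param a,b numeric n-by-3 matrices of points (mm).
#' @return Numeric vector of distances (mm), length `min(nrow(a), nrow(b))`.
#' @export
pointwiseDistances <- function(a, b) {
  k <- min(nrow(a), nrow(b))
  sqrt(rowSums((a[seq_len(k), , drop = FALSE] -
                b[seq_len(k), , drop = FALSE])^2))
}

#' Apply a rigid transform to points
#'
#' Rotates about `center` and then translates:
#' `(p - center) %*% t(rotation) + center + translation`.
#'
#' @param p numeric n-by-3 matrix (mm).
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric(3) in mm.
#' @param center numeric(3), center of rotation in mm.
#' @return Transformed n-by-3 matrix.
#' @export
rigidTransform <- function(p, rotation = diag(3),
                           translation = c(0, 0, 0),
                           center = c(0, 0, 0)) {
  sweep(sweep(p, 2, center) %*% t(rotation), 2,
        center + translation, "+")
}

#' @rdname rigidTransform
#' @param t a [Tractogram-class].
#' @export
transformTractogram <- function(t, rotation = diag(3),
                                translation = c(0, 0, 0),
                                center = c(0, 0, 0)) {
  t@streamlines <- lapply(t@streamlines, rigidTransform,
                          rotation = rotation, translation = translation,
                          center = center)
  t
}

## Rotation matrix for angle (radians) about unit axis, Rodrigues form.
.rotationMatrix <- function(axis, angle) {
  a <- axis / .vecnorm(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
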