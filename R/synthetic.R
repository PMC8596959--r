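#' @include reliability.R
NULL

#' Construct a bundle specification
#'
#' Defaults describe a realistic single connection bundle: 500 streamlines,
#' 1 mm perpendicular jitter with a 5 mm correlation length, up to 5% of
#' the arc truncated at each end, and 5% outlier paths detoured 12 mm
#' laterally — scales at which the default clustering thresholds separate
#' inliers from outliers.
#'
#' @param controlPoints numeric matrix (>= 4 rows) of 3D control points in
#'   mm; default is the mPFC prototype from [prototypeLibrary()].
#' @param nStreamlines number of streamlines (default 500).
#' @param jitterSd sd of the perpendicular jitter in mm (default 1).
#' @param jitterSmoothness correlation length of the jitter along the arc
#'   in mm (default 5).
#' @param lengthVarFrac maximum fraction of arc length truncated at each
#'   end, drawn uniformly per end (default 0.05).
#' @param outlierFrac fraction of streamlines routed through the detour
#'   (default 0.05).
#' @param outlierOffset 3D displacement of the detour region in mm
#'   (default `c(12, 0, 0)`, a contralateral-style lateral excursion).
#' @param seed RNG seed (default 1).
#' @return A [BundleSpec-class].
#' @export
bundleSpec <- function(controlPoints = prototypeLibrary()[["mPFC"]],
                       nStreamlines = 500, jitterSd = 1,
                       jitterSmoothness = 5, lengthVarFrac = 0.05,
                       outlierFrac = 0.05, outlierOffset = c(12, 0, 0),
                       seed = 1) {
  new("BundleSpec", controlPoints = as.matrix(controlPoints),
      nStreamlines = as.integer(nStreamlines), jitterSd = jitterSd,
      jitterSmoothness = jitterSmoothness, lengthVarFrac = lengthVarFrac,
      outlierFrac = outlierFrac, outlierOffset = as.numeric(outlierOffset),
      seed = as.integer(seed))
}

#' Construct a session specification
#'
#' Repeated sessions of the same bundle differ by a small rigid
#' perturbation (head positioning, susceptibility effects) plus fresh
#' streamline jitter. Defaults: 7 sessions, 0.5 mm per-axis translation sd,
#' 0.5 degree rotation sd about the bundle midpoint.
#'
#' @param nSessions number of sessions (default 7).
#' @param sessionShiftSd per-axis sd of the session translation in mm
#'   (default 0.5).
#' @param sessionRotSd sd of the session rotation angle in degrees
#'   (default 0.5).
#' @param seed RNG seed for the session transforms (default 1).
#' @return A [SessionSpec-class].
#' @export
sessionSpec <- function(nSessions = 7, sessionShiftSd = 0.5,
                        sessionRotSd = 0.5, seed = 1) {
  new("SessionSpec", nSessions = as.integer(nSessions),
      sessionShiftSd = sessionShiftSd, sessionRotSd = sessionRotSd,
      seed = as.integer(seed))
}

#' Prototype trajectories for the six seed-to-target connections
#'
#' Illustrative smooth curves loosely shaped like the six nucleus accumbens
#' connections (right hemisphere, AC-PC mm space), with arc lengths below
#' the per-connection maximum fiber lengths. Mirror `x` for the left
#' hemisphere. Shapes are illustrative only — they carry no anatomical
#' claim beyond plausible scale and direction.
#'
#' @param hemisphere `"R"` (default) or `"L"`.
#' @return Named list of control-point matrices.
#' @export
prototypeLibrary <- function(hemisphere = c("R", "L")) {
  hemisphere <- match.arg(hemisphere)
  lib <- list(
    mPFC = rbind(c(10, 8, -8), c(9, 20, -6), c(8, 32, -2), c(6, 42, 2)),
    ACC  = rbind(c(10, 8, -8), c(9, 16, 0), c(8, 24, 10), c(7, 30, 18)),
    HPC  = rbind(c(10, 8, -8), c(16, 0, -10), c(22, -10, -14),
                 c(26, -20, -16), c(28, -28, -14)),
    AMY  = rbind(c(10, 8, -8), c(14, 4, -12), c(18, -2, -16),
                 c(22, -6, -18)),
    VTA  = rbind(c(10, 8, -8), c(8, 2, -10), c(6, -4, -11), c(5, -8, -12)),
    dmT  = rbind(c(10, 8, -8), c(8, 4, -4), c(7, 0, 0), c(6, -4, 3))
  )
  if (hemisphere == "L")
    lib <- lapply(lib, function(m) { m[, 1] <- -m[, 1]; m })
  lib
}

#' Build a smooth prototype streamline from control points
#'
#' Interpolates a natural cubic spline through the control points
#' (chord-length parameterisation, one spline per coordinate) and samples
#' it at no more than 0.4 mm spacing. The curve passes through every
#' control point; collinear control points yield a straight line.
#'
#' @param spec a [BundleSpec-class], or a control-point matrix.
#' @return Numeric n-by-3 matrix of prototype points (mm).
#' @export
makePrototype <- function(spec) {
  cp <- if (is(spec, "BundleSpec")) spec@controlPoints else as.matrix(spec)
  if (nrow(cp) < 4L) stop("at least 4 control points required")
  seg <- sqrt(rowSums(diff(cp)^2))
  if (any(seg == 0)) stop("duplicate adjacent control points")
  tt <- c(0, cumsum(seg))
  L <- tt[length(tt)]
  nOut <- max(ceiling(L / 0.4) + 1L, nrow(cp))
  xout <- sort(unique(c(seq(0, L, length.out = nOut), tt)))
  pts <- sapply(1:3, function(ax)
    stats::spline(tt, cp[, ax], xout = xout, method = "natural")$y)
  ## collapse numerically coincident consecutive samples
  keep <- c(TRUE, rowSums(diff(pts)^2) > 1e-24)
  pts[keep, , drop = FALSE]
}

## Smoothed unit-variance Gaussian noise along arc positions `s`:
## white noise convolved with a Gaussian kernel of width `corrLen`,
## standardised so every point has marginal sd 1.
.smoothNoise <- function(s, corrLen) {
  m <- length(s)
  W <- exp(-0.5 * (outer(s, s, "-") / corrLen)^2)
  z <- as.numeric(W %*% stats::rnorm(m))
  z / sqrt(rowSums(W^2))
}

## Unit tangents of a polyline by central differences.
.tangents <- function(p) {
  n <- nrow(p)
  d <- rbind(p[2, ] - p[1, ],
             p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE],
             p[n, ] - p[n - 1, ])
  d / sqrt(rowSums(d^2))
}

## Orthonormal frame (e1, e2) perpendicular to each tangent row.
.perpFrame <- function(tg) {
  n <- nrow(tg)
  e1 <- matrix(0, n, 3); e2 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    a <- if (abs(tg[i, 3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    v <- c(tg[i, 2] * a[3] - tg[i, 3] * a[2],
           tg[i, 3] * a[1] - tg[i, 1] * a[3],
           tg[i, 1] * a[2] - tg[i, 2] * a[1])
    e1[i, ] <- v / .vecnorm(v)
    e2[i, ] <- c(tg[i, 2] * e1[i, 3] - tg[i, 3] * e1[i, 2],
                 tg[i, 3] * e1[i, 1] - tg[i, 1] * e1[i, 3],
                 tg[i, 1] * e1[i, 2] - tg[i, 2] * e1[i, 1])
  }
  list(e1 = e1, e2 = e2)
}

#' Simulate a synthetic fiber bundle
#'
#' Generates `nStreamlines` noisy copies of the prototype: each copy is
#' truncated at both ends by an independent uniform fraction of the arc,
#' then displaced perpendicular to the local tangent by smooth zero-mean
#' Gaussian jitter (sd `jitterSd`, correlation length `jitterSmoothness`
#' along the arc). `floor(outlierFrac * n)` streamlines are additionally
#' routed through a detour: the prototype midpoint region is displaced by
#' `outlierOffset` with a smooth bump profile before jitter. Perpendicular
#' (rather than isotropic) jitter keeps streamline lengths comparable, so
#' the length criterion of the clustering is exercised by the explicit
#' truncation parameter, not by noise side-effects. Fully reproducible
#' from the seed.
#'
#' @param spec a [BundleSpec-class].
#' @param session optional session id stored in the tractogram metadata.
#' @param subject,connection,hemisphere optional metadata.
#' @return List with `tractogram` (a [Tractogram-class]) and `groundTruth`
#'   (per-streamline `labels` — `"inlier"` / `"outlier"` — and the
#'   `prototype` polyline).
#' @export
simulateBundle <- function(spec, session = NA_integer_,
                           subject = "sim01", connection = NA_character_,
                           hemisphere = NA_character_) {
  stopifnot(is(spec, "BundleSpec"))
  validObject(spec)
  proto <- makePrototype(spec)
  L <- arcLength(proto)
  n <- spec@nStreamlines
  nOut <- floor(spec@outlierFrac * n)

  .withSeed(spec@seed, {
    isOutlier <- rep(FALSE, n)
    if (nOut > 0) isOutlier[sample.int(n, nOut)] <- TRUE
    streamlines <- vector("list", n)
    for (i in seq_len(n)) {
      p <- proto
      if (isOutlier[i]) {
        s <- .cumArc(p)
        bump <- exp(-0.5 * ((s - L / 2) / (L / 6))^2)
        p <- p + outer(bump, spec@outlierOffset)
      }
      if (spec@lengthVarFrac > 0) {
        Lp <- arcLength(p)  # outlier detours lengthen the path
        u <- stats::runif(2, 0, spec@lengthVarFrac)
        p <- .cropArc(p, u[1] * Lp, Lp - u[2] * Lp)
      }
      if (spec@jitterSd > 0) {
        s <- .cumArc(p)
        fr <- .perpFrame(.tangents(p))
        z1 <- .smoothNoise(s, spec@jitterSmoothness) * spec@jitterSd
        z2 <- .smoothNoise(s, spec@jitterSmoothness) * spec@jitterSd
        p <- p + z1 * fr$e1 + z2 * fr$e2
      }
      streamlines[[i]] <- p
    }
    list(
      tractogram = tractogram(streamlines, subject = subject,
                              session = session, connection = connection,
                              hemisphere = hemisphere),
      groundTruth = list(
        labels = ifelse(isOutlier, "outlier", "inlier"),
        prototype = proto))
  })
}

#' Simulate repeated measurement sessions of one bundle
#'
#' Generates `nSessions` tractograms of the same underlying bundle. Each
#' session redraws the streamline jitter (fresh seed derived from the
#' bundle seed and session number) and applies one rigid transform —
#' translation with per-axis sd `sessionShiftSd`, rotation about the
#' prototype midpoint with angle sd `sessionRotSd` — drawn once per
#' session. Transforms are recorded in the ground truth; session metadata
#' is populated 1..n.
#'
#' @param bspec a [BundleSpec-class].
#' @param sspec a [SessionSpec-class].
#' @param sessionTransforms optional list (length `nSessions`) of
#'   `list(rotation = 3x3, translation = numeric(3))` overriding the drawn
#'   transforms, e.g. to force a known session offset.
#' @param subject,connection,hemisphere metadata stored on each session.
#' @return List with `sessions` (list of per-session
#'   `list(tractogram, groundTruth)`) and `transforms` (the rigid
#'   transforms applied, including the rotation `center`).
#' @export
simulateSessions <- function(bspec, sspec = sessionSpec(),
                             sessionTransforms = NULL,
                             subject = "sim01",
                             connection = NA_character_,
                             hemisphere = NA_character_) {
  stopifnot(is(bspec, "BundleSpec"), is(sspec, "SessionSpec"))
  validObject(bspec); validObject(sspec)
  proto <- makePrototype(bspec)
  center <- .interpAlong(proto, arcLength(proto) / 2)[1, ]

  nS <- sspec@nSessions
  transforms <- .withSeed(sspec@seed, lapply(seq_len(nS), function(k) {
    shift <- stats::rnorm(3, 0, sspec@sessionShiftSd)
    angle <- stats::rnorm(1, 0, sspec@sessionRotSd) * pi / 180
    axis <- stats::rnorm(3)
    rot <- if (sspec@sessionRotSd > 0 && .vecnorm(axis) > 0)
      .rotationMatrix(axis, angle) else diag(3)
    list(rotation = rot, translation = shift, center = center)
  }))
  if (!is.null(sessionTransforms)) {
    stopifnot(length(sessionTransforms) == nS)
    transforms <- lapply(sessionTransforms, function(tr)
      list(rotation = if (is.null(tr$rotation)) diag(3) else tr$rotation,
           translation = if (is.null(tr$translation)) c(0, 0, 0)
                         else tr$translation,
           center = center))
  }

  sessions <- lapply(seq_len(nS), function(k) {
    bs <- bspec
    bs@seed <- as.integer((bspec@seed + 7919L * k) %% .Machine$integer.max)
    sim <- simulateBundle(bs, session = k, subject = subject,
                          connection = connection, hemisphere = hemisphere)
    tr <- transforms[[k]]
    sim$tractogram <- transformTractogram(sim$tractogram, tr$rotation,
                                          tr$translation, tr$center)
    sim$groundTruth$transform <- tr
    sim
  })
  list(sessions = sessions, transforms = transforms)
}
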