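#' @include clustering.R
NULL

#' Centroid trajectory of a cluster
#'
#' Computes the mean path of a cluster: every member is resampled to the
#' same number of points uniformly in normalised arc length
#' (N = floor(median member length / step) + 1), the centroid is the
#' index-wise mean of these, and the mean polyline is finally resampled at
#' `step` so consecutive points are a fixed arc-length apart. The
#' normalised-arc construction is well defined for members of unequal
#' length and reduces to the member's own equidistant resampling when all
#' members are identical.
#'
#' @param t a [Tractogram-class].
#' @param members integer vector of member indices (default: all
#'   streamlines).
#' @param params a [TrackParameters-class] (supplies `step`).
#' @return A [CentroidTrajectory-class] carrying the tractogram's metadata.
#' @export
centroidTrajectory <- function(t, members = seq_along(t@streamlines),
                               params = trackParameters()) {
  stopifnot(length(members) >= 1L)
  sl <- t@streamlines[members]
  lens <- vapply(sl, arcLength, numeric(1))
  if (any(lens < params@step))
    stop("cluster member shorter than one step")
  nPts <- floor(stats::median(lens) / params@step) + 1L
  nPts <- max(nPts, 2L)
  acc <- matrix(0, nPts, 3L)
  for (s in sl) {
    L <- arcLength(s)
    acc <- acc + .interpAlong(s, seq(0, L, length.out = nPts))
  }
  mean_path <- acc / length(sl)
  pts <- resampleEquidistant(mean_path, params@step)
  new("CentroidTrajectory", points = pts, step = params@step,
      subject = t@subject, session = t@session, connection = t@connection,
      hemisphere = t@hemisphere, nMembers = length(members))
}

#' Select the reference trajectory
#'
#' Among the centroid trajectories of one subject, connection and
#' hemisphere (one per session), selects the shortest trajectory as the
#' reference for all point-by-point comparisons. Ties go to the lowest
#' session id.
#'
#' @param trajs list of [CentroidTrajectory-class] with distinct sessions.
#' @return The index of the reference trajectory within `trajs`.
#' @export
selectReference <- function(trajs) {
  if (length(trajs) < 2L)
    stop("at least 2 sessions required to select a reference")
  lens <- vapply(trajs, arcLength, numeric(1))
  sess <- vapply(trajs, function(x) x@session, integer(1))
  best <- which(lens == min(lens))
  best[which.min(sess[best])]
}

#' Point-by-point distance profile to the reference trajectory
#'
#' Euclidean distances between index-paired points of `traj` and the
#' reference, both resampled at the same arc-length step and paired from
#' the streamline start. The reference is the shortest trajectory, so the
#' pairing is total on its point indices. `traj` is orientation-aligned to
#' the reference before pairing.
#'
#' @param traj,ref [CentroidTrajectory-class] objects at the same step.
#' @return A [DistanceProfile-class].
#' @export
distanceProfile <- function(traj, ref) {
  if (abs(traj@step - ref@step) > 1e-12)
    stop("step mismatch between trajectory and reference")
  p <- orientAlign(traj@points, ref@points)
  new("DistanceProfile",
      distances = pointwiseDistances(p, ref@points),
      step = ref@step, session = traj@session,
      referenceSession = ref@session, subject = traj@subject,
      connection = traj@connection, hemisphere = traj@hemisphere)
}

#' Summarise distance profiles into the three reliability statistics
#'
#' Aggregates per-session distance profiles into the three-level summary:
#' \describe{
#'   \item{session max}{the maximum of a profile's point-by-point distances
#'     to the shortest trajectory, per subject, session, connection and
#'     hemisphere; the reference session's self-distance is 0 by
#'     definition.}
#'   \item{average max}{the mean of a subject's session maxima over the
#'     policy-selected sessions.}
#'   \item{maximum mean}{the mean of the session maxima over all subjects
#'     and policy-selected sessions, per connection and hemisphere.}
#' }
#' With `policy = "exclude_ref"` (default) the reference session's zero is
#' left out of the averages as uninformative; `"include_ref"` averages over
#' all sessions literally.
#'
#' @param profiles list of [DistanceProfile-class] objects (including each
#'   reference's all-zero self profile).
#' @param policy `"exclude_ref"` or `"include_ref"`.
#' @return A [ReliabilitySummary-class].
#' @export
summarizeReliability <- function(profiles,
                                 policy = c("exclude_ref", "include_ref")) {
  policy <- match.arg(policy)
  if (!length(profiles)) stop("no profiles to summarise")
  tab <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(subject = p@subject, session = p@session,
               connection = p@connection, hemisphere = p@hemisphere,
               isReference = (p@session == p@referenceSession),
               maxDistance = max(p@distances),
               stringsAsFactors = FALSE)
  }))
  sel <- if (policy == "exclude_ref") !tab$isReference else rep(TRUE, nrow(tab))
  used <- tab[sel, , drop = FALSE]
  if (!nrow(used)) stop("policy selected no sessions")
  avg <- stats::aggregate(maxDistance ~ subject + connection + hemisphere,
                          data = used, FUN = mean)
  names(avg)[names(avg) == "maxDistance"] <- "avgMax"
  grand <- stats::aggregate(maxDistance ~ connection + hemisphere,
                            data = used, FUN = mean)
  names(grand)[names(grand) == "maxDistance"] <- "maxMean"
  ord <- order(tab$connection, tab$hemisphere, tab$subject, tab$session)
  new("ReliabilitySummary", sessionMax = tab[ord, , drop = FALSE],
      avgMax = avg[order(avg$connection, avg$hemisphere, avg$subject), ,
                   drop = FALSE],
      maxMean = grand[order(grand$connection, grand$hemisphere), ,
                      drop = FALSE],
      policy = policy)
}

#' Export a reliability summary as CSV
#'
#' Writes one `session_max` row per (subject, session, connection,
#' hemisphere) followed by `avg_max` aggregate rows per subject and
#' `max_mean` rows per connection and hemisphere. The output is plain CSV
#' and deterministic: re-exporting the same summary yields a byte-identical
#' file.
#'
#' @param s a [ReliabilitySummary-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportSummary <- function(s, path) {
  detail <- data.frame(
    subject = s@sessionMax$subject, session = s@sessionMax$session,
    connection = s@sessionMax$connection,
    hemisphere = s@sessionMax$hemisphere,
    statistic = "session_max", value_mm = s@sessionMax$maxDistance,
    is_reference = s@sessionMax$isReference, stringsAsFactors = FALSE)
  avg <- data.frame(
    subject = s@avgMax$subject, session = NA_integer_,
    connection = s@avgMax$connection, hemisphere = s@avgMax$hemisphere,
    statistic = "avg_max", value_mm = s@avgMax$avgMax,
    is_reference = NA, stringsAsFactors = FALSE)
  grand <- data.frame(
    subject = NA_character_, session = NA_integer_,
    connection = s@maxMean$connection, hemisphere = s@maxMean$hemisphere,
    statistic = "max_mean", value_mm = s@maxMean$maxMean,
    is_reference = NA, stringsAsFactors = FALSE)
  utils::write.csv(rbind(detail, avg, grand), path, row.names = FALSE)
  invisible(path)
}

#' Export distance profiles as CSV
#'
#' One row per resampling step with the step index, the arc position along
#' the reference in mm, and the distance in mm, plus the identifying
#' metadata.
#'
#' @param profiles list of [DistanceProfile-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportProfiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    k <- seq_along(p@distances)
    data.frame(subject = p@subject, session = p@session,
               connection = p@connection, hemisphere = p@hemisphere,
               reference_session = p@referenceSession,
               step_index = k - 1L, arc_position_mm = (k - 1L) * p@step,
               distance_mm = p@distances, stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
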