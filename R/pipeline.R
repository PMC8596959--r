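#' @include synthetic.R
NULL

#' Analyse the sessions of one subject, connection and hemisphere
#'
#' Runs the full per-connection workflow on a list of session tractograms:
#' length filtering (per-connection maximum), optional waypoint-ROI
#' filtering, global orientation alignment, clustering, main-pathway
#' selection, centroid trajectories, reference (shortest trajectory)
#' selection, and point-by-point distance profiles of every session's
#' centroid to the reference.
#'
#' @param sessionTractograms list of [Tractogram-class], one per session,
#'   with distinct session ids.
#' @param params a [TrackParameters-class].
#' @param mode clustering mode, `"leader"` or `"graph"`.
#' @param roi optional [RoiRegion-class] waypoint filter.
#' @param roiMode `"require"` or `"exclude"`.
#' @param maxLength maximum fiber length in mm; default looks up the
#'   connection id in `params`, or skips length filtering when no
#'   connection id is set.
#' @return List with `centroids` (per-session [CentroidTrajectory-class]),
#'   `reference` (index of the reference session), `profiles` (per-session
#'   [DistanceProfile-class], including the reference's all-zero self
#'   profile), `clusters` (per-session [StreamlineClusters-class]) and
#'   `counts` (per-stage streamline bookkeeping).
#' @export
analyzeConnection <- function(sessionTractograms,
                              params = trackParameters(),
                              mode = c("leader", "graph"),
                              roi = NULL, roiMode = "require",
                              maxLength = NULL) {
  mode <- match.arg(mode)
  if (length(sessionTractograms) < 2L)
    stop("at least 2 sessions required")
  sess <- vapply(sessionTractograms, function(t) t@session, integer(1))
  if (anyDuplicated(sess[!is.na(sess)]))
    stop("session ids must be distinct")

  counts <- data.frame(session = sess,
                       input = vapply(sessionTractograms, nStreamlines,
                                      integer(1)),
                       afterLength = NA_integer_, afterRoi = NA_integer_,
                       mainCluster = NA_integer_)

  ## one global orientation reference so centroids are comparable
  globalRef <- NULL
  clusters <- vector("list", length(sessionTractograms))
  centroids <- vector("list", length(sessionTractograms))
  for (k in seq_along(sessionTractograms)) {
    t <- sessionTractograms[[k]]
    ml <- maxLength
    if (is.null(ml) && !is.na(t@connection))
      ml <- params@maxLength[[t@connection]]
    if (!is.null(ml)) t <- filterByLength(t, ml)$tractogram
    counts$afterLength[k] <- nStreamlines(t)
    if (!is.null(roi)) t <- filterByRoi(t, roi, roiMode)$tractogram
    counts$afterRoi[k] <- nStreamlines(t)
    if (nStreamlines(t) == 0L)
      stop("no streamlines left after filtering in session ", sess[k])
    if (is.null(globalRef)) globalRef <- t@streamlines[[1]]
    t@streamlines <- lapply(t@streamlines, orientAlign, ref = globalRef)
    cl <- clusterStreamlines(t, params, mode, align = FALSE)
    clusters[[k]] <- cl
    main <- clusterMembers(cl, mainCluster(cl))
    counts$mainCluster[k] <- length(main)
    centroids[[k]] <- centroidTrajectory(t, main, params)
  }

  refIdx <- selectReference(centroids)
  profiles <- lapply(centroids, distanceProfile, ref = centroids[[refIdx]])
  list(centroids = centroids, reference = refIdx, profiles = profiles,
       clusters = clusters, counts = counts)
}

.readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config
}

#' Run the full multi-subject pipeline from a configuration
#'
#' Executes filter, cluster, main-pathway, centroid, reference selection,
#' distance profiles and the reliability summary for every (subject,
#' connection, hemisphere) group found in the inputs, and writes the
#' artifacts: `clusters.json`, per-group centroid `.tck` files,
#' `profiles.csv`, `summary.csv` and `pipeline.log` (per-stage streamline
#' counts and the resolved parameter set).
#'
#' The configuration (YAML file or list) has the entries:
#' \describe{
#'   \item{input_dir / inputs}{directory scanned for
#'     `<subject>_<session>_<connection>_<hemi>.tck` files, or an explicit
#'     vector of such paths.}
#'   \item{simulate}{alternative to inputs: a list with `connections`
#'     (subset of the six ids), `subjects`, `sessions`, `seed` and
#'     optionally `n_streamlines`, `jitter_sd`, `jitter_smoothness`,
#'     `length_var_frac`, `outlier_frac`, `session_shift_sd`,
#'     `session_rot_sd` — the synthetic stand-in for a full study.}
#'   \item{parameters}{optional `dist_thresh`, `len_thresh`, `step`
#'     overrides.}
#'   \item{roi}{optional box ROI (`min` / `max`) applied to every group,
#'     with `roi_mode` `"require"` or `"exclude"`.}
#'   \item{mode}{clustering mode, `"leader"` (default) or `"graph"`.}
#'   \item{policy}{`"exclude_ref"` (default) or `"include_ref"`.}
#'   \item{output_dir}{where artifacts are written.}
#' }
#'
#' @param config path to a YAML file, or an equivalent list.
#' @return The [ReliabilitySummary-class], invisibly.
#' @export
runPipeline <- function(config) {
  cfg <- .readPipelineConfig(config)
  if (is.null(cfg$output_dir)) stop("config must set output_dir")
  outDir <- cfg$output_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  mode <- if (is.null(cfg$mode)) "leader" else cfg$mode
  policy <- if (is.null(cfg$policy)) "exclude_ref" else cfg$policy
  stopifnot(mode %in% c("leader", "graph"),
            policy %in% c("exclude_ref", "include_ref"))

  params <- trackParameters()
  if (!is.null(cfg$parameters)) {
    pp <- cfg$parameters
    params <- trackParameters(
      distThresh = if (is.null(pp$dist_thresh)) 10 else pp$dist_thresh,
      lenThresh = if (is.null(pp$len_thresh)) 0.10 else pp$len_thresh,
      step = if (is.null(pp$step)) 0.8 else pp$step)
  }
  roi <- if (!is.null(cfg$roi)) readRoi(cfg$roi) else NULL
  roiMode <- if (is.null(cfg$roi_mode)) "require" else cfg$roi_mode

  log <- c(sprintf("tractrel pipeline  %s", format(Sys.time(), "%Y-%m-%d")),
           sprintf("mode=%s policy=%s dist_thresh=%g len_thresh=%g step=%g",
                   mode, policy, params@distThresh, params@lenThresh,
                   params@step))

  ## ---- gather input tractograms, grouped by subject/connection/hemi ----
  groups <- list()
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    conns <- if (is.null(sim$connections)) .CONNECTIONS else sim$connections
    bad <- setdiff(conns, .CONNECTIONS)
    if (length(bad))
      stop("unknown connection id(s): ", paste(bad, collapse = ", "))
    subjects <- if (is.null(sim$subjects)) "sim01"
                else sprintf("sim%02d", seq_len(sim$subjects))
    hemis <- if (is.null(sim$hemispheres)) "R" else sim$hemispheres
    seed0 <- if (is.null(sim$seed)) 1L else as.integer(sim$seed)
    gi <- 0L
    for (subj in subjects) for (conn in conns) for (h in hemis) {
      gi <- gi + 1L
      bs <- bundleSpec(
        controlPoints = prototypeLibrary(h)[[conn]],
        nStreamlines = if (is.null(sim$n_streamlines)) 500
                       else sim$n_streamlines,
        jitterSd = if (is.null(sim$jitter_sd)) 1 else sim$jitter_sd,
        jitterSmoothness = if (is.null(sim$jitter_smoothness)) 5
                           else sim$jitter_smoothness,
        lengthVarFrac = if (is.null(sim$length_var_frac)) 0.05
                        else sim$length_var_frac,
        outlierFrac = if (is.null(sim$outlier_frac)) 0.05
                      else sim$outlier_frac,
        seed = (seed0 + 104729L * gi) %% .Machine$integer.max)
      ss <- sessionSpec(
        nSessions = if (is.null(sim$sessions)) 7 else sim$sessions,
        sessionShiftSd = if (is.null(sim$session_shift_sd)) 0.5
                         else sim$session_shift_sd,
        sessionRotSd = if (is.null(sim$session_rot_sd)) 0.5
                       else sim$session_rot_sd,
        seed = (seed0 + 7L * gi) %% .Machine$integer.max)
      sims <- simulateSessions(bs, ss, subject = subj, connection = conn,
                               hemisphere = h)
      groups[[.metaLabel(subj, "all", conn, h)]] <-
        lapply(sims$sessions, `[[`, "tractogram")
    }
  } else {
    paths <- cfg$inputs
    if (is.null(paths) && !is.null(cfg$input_dir))
      paths <- list.files(cfg$input_dir, "\\.tck$", full.names = TRUE)
    if (!length(paths)) stop("no input tractograms configured")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    tgs <- lapply(paths, readTck)
    key <- vapply(tgs, function(t)
      .metaLabel(t@subject, "all", t@connection, t@hemisphere), character(1))
    groups <- split(tgs, key)
  }

  ## ---- run each group, skipping those with < 2 sessions ----
  allProfiles <- list()
  clustersOut <- list()
  for (g in names(groups)) {
    tgs <- groups[[g]]
    if (length(tgs) < 2L) {
      msg <- sprintf("group %s skipped: fewer than 2 sessions", g)
      warning(msg); log <- c(log, msg)
      next
    }
    res <- analyzeConnection(tgs, params, mode, roi, roiMode)
    allProfiles <- c(allProfiles, res$profiles)
    t0 <- tgs[[1]]
    clustersOut[[g]] <- list(
      parameters = list(dist_thresh = params@distThresh,
                        len_thresh = params@lenThresh, mode = mode),
      sessions = lapply(res$clusters, function(cl) unname(cl@members)))
    cent <- tractogram(lapply(res$centroids, centroidPoints),
                       subject = t0@subject, connection = t0@connection,
                       hemisphere = t0@hemisphere)
    writeTck(cent, file.path(outDir, sprintf("centroids_%s.tck", g)))
    for (k in seq_len(nrow(res$counts)))
      log <- c(log, sprintf(
        "%s session %s: input=%d afterLength=%d afterRoi=%d main=%d%s",
        g, res$counts$session[k], res$counts$input[k],
        res$counts$afterLength[k], res$counts$afterRoi[k],
        res$counts$mainCluster[k],
        if (k == res$reference) " [reference]" else ""))
  }
  if (!length(allProfiles)) stop("no group produced profiles")

  summary <- summarizeReliability(allProfiles, policy)
  jsonlite::write_json(clustersOut, file.path(outDir, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  exportProfiles(allProfiles, file.path(outDir, "profiles.csv"))
  exportSummary(summary, file.path(outDir, "summary.csv"))
  writeLines(log, file.path(outDir, "pipeline.log"))
  invisible(summary)
}
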