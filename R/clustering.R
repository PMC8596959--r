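#' @include filtering.R
NULL

#' Compatibility of two landmark signatures
#'
#' Two streamlines belong to the same cluster when (1) each of the four
#' landmark pairs — start to start, first third to first third, second
#' third to second third, end to end — lies within the spatial distance
#' threshold (default 10 mm, inclusive), and (2) the difference in path
#' lengths relative to the shorter path does not exceed the length
#' threshold (default 10%, inclusive).
#'
#' @param a,b landmark signatures from [landmarkSignature()]; `b` is
#'   assumed orientation-aligned to `a` upstream.
#' @param params a [TrackParameters-class].
#' @return `TRUE` or `FALSE`.
#' @examples
#' s <- landmarkSignature(cbind(0, c(0, 50), 0))
#' compatibleSignatures(s, s)  # TRUE
#' @export
compatibleSignatures <- function(a, b, params = trackParameters()) {
  d <- sqrt(rowSums((a$points - b$points)^2))
  all(d <= params@distThresh) &&
    abs(a$length - b$length) / min(a$length, b$length) <= params@lenThresh
}

## Signatures of all streamlines as a 3D array (n x 4 x 3) plus lengths,
## vectorised for the pairwise computations below.
.signatureArray <- function(streamlines) {
  n <- length(streamlines)
  pts <- array(NA_real_, c(n, 4L, 3L))
  len <- numeric(n)
  for (i in seq_len(n)) {
    s <- landmarkSignature(streamlines[[i]])
    pts[i, , ] <- s$points
    len[i] <- s$length
  }
  list(points = pts, length = len)
}

## n x n logical compatibility matrix from a signature array.
.compatMatrix <- function(sig, params) {
  n <- length(sig$length)
  ok <- matrix(TRUE, n, n)
  if (n == 1L) return(ok)
  for (l in 1:4) {
    D <- as.matrix(stats::dist(matrix(sig$points[, l, ], ncol = 3L)))
    ok <- ok & (D <= params@distThresh)
  }
  lenDiff <- abs(outer(sig$length, sig$length, "-")) /
    outer(sig$length, sig$length, pmin)
  ok & (lenDiff <= params@lenThresh)
}

#' Cluster streamlines by trajectory and length similarity
#'
#' Groups the streamlines of a tractogram into clusters of paths with
#' similar trajectories and lengths, judged by the landmark criteria of
#' [compatibleSignatures()]. Two algorithms are provided over the same
#' criteria:
#' \describe{
#'   \item{leader}{single pass in input order; each streamline joins the
#'     first existing cluster whose founding member's signature is
#'     compatible, else founds a new cluster. O(n k) and deterministic for
#'     a fixed input order.}
#'   \item{graph}{clusters are the connected components of the pairwise
#'     compatibility graph; invariant under input permutation and the
#'     reference semantics for the leader mode.}
#' }
#'
#' @param t a [Tractogram-class] with at least one streamline.
#' @param params a [TrackParameters-class].
#' @param mode `"leader"` (default) or `"graph"`.
#' @param align orientation-align every streamline to the first before
#'   computing signatures (default `TRUE`).
#' @return A [StreamlineClusters-class]; clusters are ordered by founding
#'   member index.
#' @export
clusterStreamlines <- function(t, params = trackParameters(),
                               mode = c("leader", "graph"), align = TRUE) {
  mode <- match.arg(mode)
  sl <- t@streamlines
  n <- length(sl)
  if (n == 0L) stop("cannot cluster an empty tractogram")
  if (align && n > 1L)
    sl[-1] <- lapply(sl[-1], orientAlign, ref = sl[[1]])
  sig <- .signatureArray(sl)

  if (mode == "leader") {
    founders <- integer(0)
    members <- list()
    for (i in seq_len(n)) {
      assigned <- FALSE
      if (length(founders)) {
        ## distance of streamline i to every founder, per landmark
        ok <- rep(TRUE, length(founders))
        for (l in 1:4) {
          F <- matrix(sig$points[founders, l, ], ncol = 3L)
          delta <- F - matrix(sig$points[i, l, ], nrow(F), 3L, byrow = TRUE)
          ok <- ok & (sqrt(rowSums(delta^2)) <= params@distThresh)
        }
        lf <- sig$length[founders]
        ok <- ok & (abs(lf - sig$length[i]) /
                      pmin(lf, sig$length[i]) <= params@lenThresh)
        j <- which(ok)
        if (length(j)) {
          j <- j[1]
          members[[j]] <- c(members[[j]], i)
          assigned <- TRUE
        }
      }
      if (!assigned) {
        founders <- c(founders, i)
        members[[length(founders)]] <- i
      }
    }
  } else {
    adj <- .compatMatrix(sig, params)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    members <- unname(split(seq_len(n), comp))
    founders <- vapply(members, min, integer(1))
    ord <- order(founders)
    members <- members[ord]
    founders <- founders[ord]
  }
  new("StreamlineClusters",
      members = lapply(members, as.integer),
      founders = as.integer(founders), mode = mode,
      nStreamlines = as.integer(n))
}

#' Select the main pathway
#'
#' The main pathway of a connection is the cluster containing the most
#' streamlines. Ties are broken in favour of the cluster whose founding
#' member has the lowest input index.
#'
#' @param clusters a [StreamlineClusters-class].
#' @return The index of the main cluster (use [clusterMembers()] to get
#'   its member indices).
#' @export
mainCluster <- function(clusters) {
  sz <- clusterSizes(clusters)
  best <- which(sz == max(sz))
  best[which.min(clusters@founders[best])]
}
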