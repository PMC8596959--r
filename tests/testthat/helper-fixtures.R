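# Fixture generators and the independent clustering oracle used by the
# tests. Everything is built in code; no data files.

# Straight streamline from `from` towards unit direction `dir`, given length
# and point count.
straightLine <- function(from = c(0, 0, 0), dir = c(0, 1, 0), length = 40,
                         nPoints = 5) {
  dir <- dir / sqrt(sum(dir^2))
  s <- seq(0, length, length.out = nPoints)
  outer(s, dir) + matrix(from, nPoints, 3, byrow = TRUE)
}

# Smooth-ish random streamline: a random walk with strictly positive step
# lengths (always a valid streamline).
randomStreamline <- function(nPoints = 10, scale = 1) {
  steps <- matrix(rnorm(3 * (nPoints - 1), sd = scale), ncol = 3)
  norms <- sqrt(rowSums(steps^2))
  steps[norms < 1e-3, ] <- 1e-3  # no zero-length segments
  apply(rbind(rnorm(3, sd = 5 * scale), steps), 2, cumsum)
}

randomTractogram <- function(nStreamlines = 5, ...) {
  tractogram(lapply(seq_len(nStreamlines),
                    function(i) randomStreamline(...)))
}

# Brute-force clustering oracle: scalar pairwise compatibility plus a
# hand-rolled union-find, fully independent of the package's vectorised
# compatibility matrix and of igraph.
oracleClusters <- function(streamlines, params = trackParameters()) {
  n <- length(streamlines)
  if (n > 1)
    streamlines[-1] <- lapply(streamlines[-1], orientAlign,
                              ref = streamlines[[1]])
  sigs <- lapply(streamlines, landmarkSignature)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (compatibleSignatures(sigs[[i]], sigs[[j]], params)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# Rodrigues rotation matrix, written out independently of the package.
.rotForTest <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Canonical form of a partition for set-of-sets comparison.
canonicalPartition <- function(members) {
  parts <- lapply(members, function(m) sort(as.integer(m)))
  parts[order(vapply(parts, min, integer(1)))]
}

# A small multi-session synthetic study analysed end to end; returns the
# ReliabilitySummary and the intermediate results.
runSyntheticStudy <- function(bspec, sspec, sessionTransforms = NULL,
                              connection = "mPFC", hemisphere = "R",
                              policy = "exclude_ref", mode = "leader") {
  sims <- simulateSessions(bspec, sspec,
                           sessionTransforms = sessionTransforms,
                           connection = connection, hemisphere = hemisphere)
  res <- analyzeConnection(lapply(sims$sessions, `[[`, "tractogram"),
                           mode = mode)
  list(summary = summarizeReliability(res$profiles, policy), result = res,
       sims = sims)
}
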