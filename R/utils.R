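#' @include AllGenerics.R
NULL

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

.vecnorm <- function(v) sqrt(sum(v * v))

## Cumulative arc length of a polyline: length nrow(p), starting at 0.
.cumArc <- function(p) {
  c(0, cumsum(sqrt(rowSums(diff(p)^2))))
}

## Interpolate points on the polyline `p` at arc-length positions `s`
## (clamped to [0, total length]); linear interpolation between vertices.
.interpAlong <- function(p, s) {
  cl <- .cumArc(p)
  L <- cl[length(cl)]
  s <- pmin(pmax(s, 0), L)
  idx <- findInterval(s, cl, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(p) - 1L)
  seg <- cl[idx + 1L] - cl[idx]
  w <- ifelse(seg > 0, (s - cl[idx]) / seg, 0)
  p[idx, , drop = FALSE] * (1 - w) + p[idx + 1L, , drop = FALSE] * w
}

## Extract the sub-polyline between arc positions s0 < s1, keeping original
## vertices strictly inside the range and interpolated endpoints.
.cropArc <- function(p, s0, s1) {
  cl <- .cumArc(p)
  L <- cl[length(cl)]
  s0 <- max(0, s0); s1 <- min(L, s1)
  stopifnot(s1 > s0)
  inside <- which(cl > s0 + 1e-12 & cl < s1 - 1e-12)
  out <- rbind(.interpAlong(p, s0), p[inside, , drop = FALSE],
               .interpAlong(p, s1))
  ## drop any zero-length segment created by coincident interpolated ends
  keep <- c(TRUE, rowSums(diff(out)^2) > 1e-24)
  out[keep, , drop = FALSE]
}

.metaLabel <- function(subject, session, connection, hemisphere) {
  paste(subject, session, connection, hemisphere, sep = "_")
}
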