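test_that("prototypes interpolate their control points smoothly", {
  # collinear control points give a straight line
  cp <- cbind(0, seq(0, 30, length.out = 5), 0)
  p <- makePrototype(cp)
  expect_lt(max(abs(p[, c(1, 3)])), 1e-9)
  expect_equal(arcLength(p), 30, tolerance = 1e-9)

  # an arc passes through all its control points
  theta <- seq(0, pi / 2, length.out = 6)
  cp2 <- cbind(20 * cos(theta), 20 * sin(theta), 0)
  p2 <- makePrototype(cp2)
  for (i in seq_len(nrow(cp2)))
    expect_lt(min(sqrt(rowSums(sweep(p2, 2, cp2[i, ])^2))), 1e-9)
  # sampling is at most 0.4 mm apart
  expect_lte(max(sqrt(rowSums(diff(p2)^2))), 0.4 + 1e-9)

  expect_identical(makePrototype(cp2), makePrototype(cp2))
  expect_error(makePrototype(rbind(cp2[1, ], cp2[1, ], cp2[3:4, ])),
               "duplicate adjacent")
  expect_error(makePrototype(cp2[1:3, ]), "at least 4")
})

test_that("the prototype library respects the per-connection length caps", {
  params <- trackParameters()
  for (h in c("R", "L")) {
    lib <- prototypeLibrary(h)
    expect_named(lib, c("mPFC", "ACC", "HPC", "AMY", "VTA", "dmT"))
    for (conn in names(lib))
      expect_lte(arcLength(makePrototype(lib[[conn]])),
                 params@maxLength[[conn]])
  }
})

test_that("the noiseless bundle is the prototype repeated", {
  spec <- bundleSpec(nStreamlines = 5, jitterSd = 0, lengthVarFrac = 0,
                     outlierFrac = 0, seed = 1)
  sim <- simulateBundle(spec)
  expect_equal(nStreamlines(sim$tractogram), 5L)
  for (s in streamlines(sim$tractogram))
    expect_identical(s, sim$groundTruth$prototype)
  expect_true(all(sim$groundTruth$labels == "inlier"))
})

test_that("outlier labels follow the floor rule and detours are distant", {
  spec <- bundleSpec(nStreamlines = 100, outlierFrac = 0.1, jitterSd = 0.5,
                     outlierOffset = c(15, 0, 0), seed = 2)
  sim <- simulateBundle(spec)
  expect_equal(sum(sim$groundTruth$labels == "outlier"), 10L)
  expect_equal(length(sim$groundTruth$labels), 100L)
  # outliers pass near the offset midpoint, inliers do not
  proto <- sim$groundTruth$prototype
  cumArc <- c(0, cumsum(sqrt(rowSums(diff(proto)^2))))
  mid <- proto[which.min(abs(cumArc - arcLength(proto) / 2)), ]
  detour <- mid + c(15, 0, 0)
  minDist <- vapply(streamlines(sim$tractogram), function(s)
    min(sqrt(rowSums(sweep(s, 2, detour)^2))), numeric(1))
  expect_true(all(minDist[sim$groundTruth$labels == "outlier"] < 5))
  expect_true(all(minDist[sim$groundTruth$labels == "inlier"] > 10))
})

test_that("jitter is zero-mean perpendicular noise at the requested scale", {
  spec <- bundleSpec(nStreamlines = 500, jitterSd = 1, lengthVarFrac = 0,
                     outlierFrac = 0, seed = 3)
  sim <- simulateBundle(spec)
  proto <- sim$groundTruth$prototype
  midIdx <- round(nrow(proto) / 2)
  disp <- t(vapply(streamlines(sim$tractogram),
                   function(s) s[midIdx, ] - proto[midIdx, ], numeric(3)))
  # mean displacement at mid-arc ~ N(0, sd/sqrt(n)) per axis
  expect_lt(max(abs(colMeans(disp))), 3 / sqrt(500))
  # total perpendicular sd across the two normal directions is sqrt(2)*sd
  expect_equal(mean(sqrt(rowSums(disp^2))), sqrt(pi / 2),
               tolerance = 0.15)
  # lengths stay comparable: perpendicular jitter, no truncation
  lens <- streamlineLengths(sim$tractogram)
  expect_lt(diff(range(lens)) / min(lens), 0.1)
})

test_that("sessions are deterministic and carry their rigid transforms", {
  bs <- bundleSpec(nStreamlines = 10, seed = 4)
  ss <- sessionSpec(nSessions = 3, seed = 4)
  a <- simulateSessions(bs, ss)
  b <- simulateSessions(bs, ss)
  d <- withr::local_tempdir()
  for (k in 1:3) {
    fa <- file.path(d, sprintf("a%d.tck", k))
    fb <- file.path(d, sprintf("b%d.tck", k))
    writeTck(a$sessions[[k]]$tractogram, fa)
    writeTck(b$sessions[[k]]$tractogram, fb)
    expect_identical(readBin(fa, "raw", file.size(fa)),
                     readBin(fb, "raw", file.size(fb)))
    expect_equal(a$sessions[[k]]$tractogram@session, k)
  }
  expect_length(a$transforms, 3L)
  expect_equal(dim(a$transforms[[1]]$rotation), c(3L, 3L))

  # the forced-transform hook overrides the drawn perturbations
  forced <- simulateSessions(bs, ss, sessionTransforms = list(
    list(), list(translation = c(0, 0, 2)), list()))
  expect_equal(forced$transforms[[2]]$translation, c(0, 0, 2))
  expect_equal(forced$transforms[[1]]$rotation, diag(3))
})
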