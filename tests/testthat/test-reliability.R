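test_that("centroid of identical members is the member's resampling", {
  A <- straightLine(length = 40)
  t <- tractogram(replicate(6, A, simplify = FALSE), session = 1L)
  ct <- centroidTrajectory(t)
  expect_equal(centroidPoints(ct), resampleEquidistant(A, 0.8))
  expect_equal(ct@nMembers, 6L)

  # two parallel lines: the centroid is the midline
  B <- sweep(A, 2, c(2, 0, 0), "+")
  t2 <- tractogram(list(A, B), session = 1L)
  mid <- centroidPoints(centroidTrajectory(t2))
  expect_equal(mid, resampleEquidistant(sweep(A, 2, c(1, 0, 0), "+"), 0.8))

  expect_error(
    centroidTrajectory(tractogram(list(cbind(0, c(0, 0.5), 0)))),
    "shorter than one step")
})

test_that("centroid converges to the prototype as members average out", {
  sim <- simulateBundle(bundleSpec(nStreamlines = 200, jitterSd = 1,
                                   lengthVarFrac = 0, outlierFrac = 0,
                                   seed = 21))
  ct <- centroidTrajectory(sim$tractogram)
  proto <- resampleEquidistant(sim$groundTruth$prototype, 0.8)
  d <- pointwiseDistances(centroidPoints(ct), proto)
  # pointwise error of a mean of 200 jitters: well within 3 sd/sqrt(n)
  expect_lt(max(d), 3 * 1 / sqrt(200) + 0.05)
})

test_that("the reference is the shortest trajectory, ties to low session", {
  mk <- function(L, sess) {
    t <- tractogram(list(straightLine(length = L)), session = sess)
    centroidTrajectory(t)
  }
  trajs <- list(mk(42, 1L), mk(40.1, 2L), mk(44.7, 3L))
  expect_equal(selectReference(trajs), 2L)
  ties <- list(mk(40, 5L), mk(40, 2L))
  expect_equal(selectReference(ties), 2L)
  expect_error(selectReference(trajs[1]), "at least 2")
})

test_that("distance profiles measure rigid offsets exactly", {
  A <- straightLine(length = 40)
  ref <- centroidTrajectory(tractogram(list(A), session = 1L))
  same <- centroidTrajectory(tractogram(list(A), session = 2L))
  expect_equal(distances(distanceProfile(same, ref)),
               rep(0, nrow(centroidPoints(ref))))

  shifted <- centroidTrajectory(
    tractogram(list(sweep(A, 2, c(0, 3, 0), "+")), session = 3L))
  expect_equal(distances(distanceProfile(shifted, ref)),
               rep(3, nrow(centroidPoints(ref))), tolerance = 1e-12)

  # bent tail: zeros then a strictly growing tail
  bent <- A
  bent[4:5, 1] <- bent[4:5, 1] + c(2, 5)
  bt <- centroidTrajectory(tractogram(list(bent), session = 4L))
  prof <- distances(distanceProfile(bt, ref))
  expect_equal(prof[1:10], rep(0, 10))
  tail <- prof[prof > 1e-9]
  expect_true(all(diff(tail) > 0))

  # step mismatch is refused
  coarse <- centroidTrajectory(tractogram(list(A), session = 5L),
                               params = trackParameters(step = 1.6))
  expect_error(distanceProfile(coarse, ref), "step mismatch")
})

test_that("summaries aggregate session maxima at three levels", {
  mkProfile <- function(maxd, sess, refSess = 1L, subj = "s1") {
    new("DistanceProfile", distances = c(0, maxd / 2, maxd), step = 0.8,
        session = as.integer(sess), referenceSession = as.integer(refSess),
        subject = subj, connection = "ACC", hemisphere = "L")
  }
  profs <- list(mkProfile(0, 1), mkProfile(1, 2), mkProfile(2, 3),
                mkProfile(3, 4))
  s <- summarizeReliability(profs, "exclude_ref")
  expect_equal(avgMax(s)$avgMax, 2)
  expect_equal(maxMean(s)$maxMean, 2)
  expect_equal(sessionMax(s)$maxDistance[sessionMax(s)$isReference], 0)

  # include_ref averages the reference's zero in
  sInc <- summarizeReliability(profs, "include_ref")
  expect_equal(avgMax(sInc)$avgMax, 6 / 4)

  # two subjects: grand mean over all policy sessions
  profs2 <- c(profs[1:2],
              list(mkProfile(0, 1, subj = "s2"), mkProfile(4, 2, subj = "s2")))
  s2 <- summarizeReliability(profs2, "exclude_ref")
  expect_equal(maxMean(s2)$maxMean, mean(c(1, 4)))
  expect_equal(sort(avgMax(s2)$avgMax), c(1, 4))

  # all-zero profiles give all-zero statistics
  zeros <- list(mkProfile(0, 1), mkProfile(0, 2))
  s0 <- summarizeReliability(zeros)
  expect_equal(maxMean(s0)$maxMean, 0)

  # mean bounds: maxMean between min and max session maxima
  expect_gte(maxMean(s2)$maxMean, min(c(1, 4)))
  expect_lte(maxMean(s2)$maxMean, max(c(1, 4)))

  expect_error(summarizeReliability(list()), "no profiles")
})

test_that("adding a session identical to the reference never raises avgMax", {
  set.seed(31)
  for (i in 1:5) {
    maxima <- runif(3, 0.5, 4)
    mk <- function(maxd, sess) new("DistanceProfile",
      distances = c(0, maxd), step = 0.8, session = as.integer(sess),
      referenceSession = 1L, subject = "s1", connection = "VTA",
      hemisphere = "R")
    base <- c(list(mk(0, 1)), lapply(seq_along(maxima), function(k)
      mk(maxima[k], k + 1)))
    extra <- c(base, list(mk(0, 9)))  # a duplicate of the reference
    for (pol in c("exclude_ref", "include_ref")) {
      a0 <- avgMax(summarizeReliability(base, pol))$avgMax
      a1 <- avgMax(summarizeReliability(extra, pol))$avgMax
      expect_lte(a1, a0 + 1e-12)
    }
  }
})

test_that("summary and profile exports are deterministic CSV", {
  study <- runSyntheticStudy(
    bundleSpec(nStreamlines = 30, seed = 41),
    sessionSpec(nSessions = 3, seed = 41))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  exportSummary(study$summary, f1)
  exportSummary(study$summary, f2)
  expect_identical(readLines(f1), readLines(f2))
  tab <- read.csv(f1)
  # one detail row per session plus one avg_max and one max_mean row
  expect_equal(sum(tab$statistic == "session_max"), 3)
  expect_equal(sum(tab$statistic == "avg_max"), 1)
  expect_equal(sum(tab$statistic == "max_mean"), 1)

  fp <- withr::local_tempfile(fileext = ".csv")
  exportProfiles(study$result$profiles, fp)
  prof <- read.csv(fp)
  expect_named(prof, c("subject", "session", "connection", "hemisphere",
                       "reference_session", "step_index",
                       "arc_position_mm", "distance_mm"))
  expect_equal(prof$arc_position_mm, prof$step_index * 0.8)
})
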