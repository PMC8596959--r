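test_that("signature compatibility applies both criteria symmetrically", {
  s <- landmarkSignature(straightLine(length = 50))
  expect_true(compatibleSignatures(s, s))

  # 11 mm translation exceeds the 10 mm landmark threshold everywhere
  far <- landmarkSignature(sweep(straightLine(length = 50), 2,
                                 c(0, 0, 11), "+"))
  expect_false(compatibleSignatures(s, far))
  expect_false(compatibleSignatures(far, s))

  # same geometry, lengths 100 vs 111: 11% relative difference
  a <- list(points = s$points, length = 100)
  b <- list(points = s$points, length = 111)
  expect_false(compatibleSignatures(a, b))
  expect_true(compatibleSignatures(a, list(points = s$points, length = 105)))
})

test_that("far-separated groups cluster identically in both modes", {
  A <- straightLine(length = 40)
  B <- sweep(A, 2, c(0, 0, 50), "+")
  t <- tractogram(c(replicate(3, A, simplify = FALSE),
                    replicate(2, B, simplify = FALSE)))
  for (mode in c("leader", "graph")) {
    cl <- clusterStreamlines(t, mode = mode)
    expect_equal(sort(clusterSizes(cl), decreasing = TRUE), c(3L, 2L))
    expect_equal(canonicalPartition(cl@members),
                 list(1:3, 4:5))
  }
  # five copies of one streamline form a single cluster
  t1 <- tractogram(replicate(5, A, simplify = FALSE))
  expect_equal(clusterSizes(clusterStreamlines(t1)), 5L)
})

test_that("graph mode matches the brute-force union-find oracle", {
  set.seed(10)
  for (i in 1:40) {
    k <- sample(1:3, 1)
    protos <- lapply(seq_len(k), function(j)
      straightLine(from = c(runif(1, -15, 15), 0, runif(1, -15, 15)),
                   length = runif(1, 30, 45), nPoints = 8))
    sl <- lapply(seq_len(sample(5:25, 1)), function(j) {
      p <- protos[[sample(k, 1)]]
      p + matrix(rnorm(length(p), sd = runif(1, 0.5, 6)), nrow(p))
    })
    t <- tractogram(sl)
    got <- clusterStreamlines(t, mode = "graph")
    want <- oracleClusters(streamlines(t))
    expect_equal(canonicalPartition(got@members), canonicalPartition(want))
  }
})

test_that("clustering yields a partition; graph mode ignores input order", {
  set.seed(11)
  sl <- lapply(1:15, function(j)
    straightLine(from = rnorm(3, sd = 8), length = runif(1, 30, 40)))
  t <- tractogram(sl)
  for (mode in c("leader", "graph")) {
    cl <- clusterStreamlines(t, mode = mode)
    expect_setequal(unlist(cl@members), seq_len(nStreamlines(t)))
    expect_false(anyDuplicated(unlist(cl@members)) > 0)
  }
  perm <- sample(15)
  clP <- clusterStreamlines(tractogram(sl[perm]), mode = "graph")
  back <- lapply(clP@members, function(m) perm[m])
  expect_equal(canonicalPartition(back),
               canonicalPartition(clusterStreamlines(t,
                                                     mode = "graph")@members))
})

test_that("leader mode refines the graph components", {
  set.seed(12)
  for (i in 1:10) {
    sl <- lapply(1:20, function(j)
      straightLine(from = rnorm(3, sd = 6), length = runif(1, 30, 42)))
    t <- tractogram(sl)
    leader <- clusterStreamlines(t, mode = "leader")@members
    graph <- clusterStreamlines(t, mode = "graph")@members
    # every leader cluster lies inside exactly one graph component
    compOf <- integer(20)
    for (g in seq_along(graph)) compOf[graph[[g]]] <- g
    for (m in leader) expect_length(unique(compOf[m]), 1L)
  }
})

test_that("the main pathway is the largest cluster, ties to lowest founder", {
  A <- straightLine(length = 40)
  B <- sweep(A, 2, c(0, 0, 50), "+")
  t <- tractogram(c(replicate(4, A, simplify = FALSE),
                    replicate(2, B, simplify = FALSE)))
  cl <- clusterStreamlines(t)
  expect_equal(sort(clusterMembers(cl, mainCluster(cl))), 1:4)

  # tie: interleave so both clusters have size 3; founder 1 wins
  t2 <- tractogram(list(A, B, A, B, A, B))
  cl2 <- clusterStreamlines(t2)
  expect_equal(sort(clusterMembers(cl2, mainCluster(cl2))), c(1L, 3L, 5L))

  t3 <- tractogram(replicate(3, A, simplify = FALSE))
  cl3 <- clusterStreamlines(t3)
  expect_equal(mainCluster(cl3), 1L)
})

test_that("clustering an empty tractogram is an error", {
  expect_error(clusterStreamlines(tractogram(list())), "empty")
})
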