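test_that("closestDistance handles nested sets and path-graph arithmetic", {
  g <- cliqueGraph(letters[1:4])
  # every target is itself a disease gene: minimum distance 0
  res <- closestDistance(g, V = letters[1:4], T_ = c("a", "b"))
  expect_equal(res$dc, 0)
  expect_equal(res$nDroppedTargets, 0L)

  p <- pathGraph(c("a", "b", "c", "d", "e"))
  res2 <- closestDistance(p, V = "a", T_ = c("d", "e"))
  expect_equal(res2$dc, 3.5)  # (3 + 4) / 2
})

test_that("closestDistance equals the brute-force double loop on scale-free graphs", {
  g <- generateInteractome(200, attachM = 3, seed = 5)
  dm <- allPairsDistances(g)
  set.seed(5)
  for (i in 1:10) {
    V <- sample(nodeIds(g), 20)
    T_ <- sample(nodeIds(g), 10)
    got <- closestDistance(g, V, T_, dist = dm)
    oracle <- bruteClosestDistance(g, V, T_)
    expect_identical(got$dc, oracle$dc)
    # with and without the precomputed matrix
    expect_identical(closestDistance(g, V, T_)$dc, oracle$dc)
  }
})

test_that("closestDistance drops absent members with a warning and counts unreachable targets", {
  p <- pathGraph(c("a", "b", "c"))
  expect_warning(res <- closestDistance(p, V = c("a", "zz"), T_ = "c"),
                 "absent from the graph")
  expect_equal(res$dc, 2)
  expect_error(suppressWarnings(closestDistance(p, V = "zz", T_ = "c")),
               "must both intersect")

  two <- interactomeFromEdges(data.frame(node1 = c("a", "x"),
                                         node2 = c("b", "y")))
  res2 <- closestDistance(two, V = "a", T_ = c("b", "x"))
  expect_equal(res2$dc, 1)              # only the reachable target contributes
  expect_equal(res2$nDroppedTargets, 1L)
})

test_that("degree bins partition the nodes with the promised occupancy", {
  g <- generateInteractome(1000, attachM = 3, seed = 2)
  b <- degreeBins(g)
  expect_setequal(unlist(b$bins), nodeIds(g))
  expect_equal(sum(lengths(b$bins)), numNodes(g))
  expect_true(all(lengths(b$bins) >= 100))
  # nodes sharing a degree value always share a bin
  deg <- igraph::degree(asIgraph(g))
  for (v in unique(deg))
    expect_length(unique(b$binOfNode[names(deg)[deg == v]]), 1L)

  small <- generateInteractome(100, attachM = 2, seed = 3)
  expect_true(all(lengths(degreeBins(small)$bins) >= 10))
})

test_that("degreeMatchedSample matches size always and degree bins in distribution", {
  # regular graph: a single degree value, so any k-subset is admissible
  cyc <- interactomeFromEdges(data.frame(node1 = sprintf("n%d", 1:6),
                                         node2 = sprintf("n%d", c(2:6, 1))))
  set.seed(1)
  s <- degreeMatchedSample(cyc, sprintf("n%d", 1:3))
  expect_length(s, 3L)
  expect_false(anyDuplicated(s) > 0)

  # reference exhausting the graph leaves only one admissible sample
  expect_setequal(degreeMatchedSample(cyc, nodeIds(cyc)), nodeIds(cyc))

  g <- generateInteractome(1000, attachM = 3, seed = 8)
  bins <- degreeBins(g)
  deg <- igraph::degree(asIgraph(g))
  hubs <- names(sort(deg, decreasing = TRUE))[1:30]
  refCounts <- table(bins$binOfNode[hubs])
  set.seed(9)
  for (i in 1:100) {
    s <- degreeMatchedSample(g, hubs, bins)
    expect_length(s, 30L)
    expect_identical(table(bins$binOfNode[s]), refCounts)
  }
  expect_error(degreeMatchedSample(g, "NOT_A_NODE"), "absent")
})

test_that("proximityZ reports a degenerate null instead of a bogus z", {
  k <- cliqueGraph(letters[1:8])
  # complete graph: every disjoint pair of sets is at distance 1 always
  expect_error(proximityZ(k, V = c("a", "b"), T_ = c("c", "d"),
                          nRandom = 20, seed = 1),
               class = "degenerateNullError")
  cond <- tryCatch(proximityZ(k, V = c("a", "b"), T_ = c("c", "d"),
                              nRandom = 20, seed = 1),
                   degenerateNullError = function(e) e)
  expect_equal(cond$dc, 1)
  expect_equal(cond$mu, 1)

  # forcing every replicate to the observed sets (sampler hook) degenerates too
  g <- generateInteractome(300, attachM = 3, seed = 4)
  sc <- plantPair(g, 15, 8, q = 0.5, seed = 6)
  expect_error(
    proximityZ(g, sc@diseaseSet, sc@targetSet, nRandom = 10, seed = 2,
               sampler = function(g, reference, bins, exclude) reference),
    class = "degenerateNullError")
})

test_that("planted-proximal targets score negative z and seeds reproduce bit-identically", {
  g <- generateInteractome(800, attachM = 4, seed = 10)
  dm <- allPairsDistances(g)
  sc <- plantPair(g, 20, 10, q = 1, seed = 12)
  r1 <- proximityZ(g, sc@diseaseSet, sc@targetSet, nRandom = 100, seed = 33,
                   dist = dm)
  expect_lt(r1@z, 0)
  r2 <- proximityZ(g, sc@diseaseSet, sc@targetSet, nRandom = 100, seed = 33,
                   dist = dm)
  expect_identical(r1@dc, r2@dc)
  expect_identical(r1@nullDistances, r2@nullDistances)
  expect_identical(r1@z, r2@z)
  # z consistency and population-sd definition
  expect_equal(r1@z, (r1@dc - r1@mu) / r1@sigma)
  expect_equal(r1@sigma, sqrt(mean((r1@nullDistances - r1@mu)^2)))
  expect_error(proximityZ(g, sc@diseaseSet, sc@targetSet, nRandom = 1),
               "nRandom")
})
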