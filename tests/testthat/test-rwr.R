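test_that("transition matrices are column-normalized adjacency", {
  g <- interactomeFromEdges(data.frame(node1 = "A", node2 = "B"))
  m <- buildTransition(g)
  expect_equal(as.matrix(m@M),
               matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B"))))

  star <- interactomeFromEdges(data.frame(node1 = "c", node2 = c("x", "y", "z")))
  M <- as.matrix(buildTransition(star)@M)
  expect_equal(M["c", "x"], 1)               # a leaf always walks to the centre
  expect_equal(unname(M[c("x", "y", "z"), "c"]), rep(1 / 3, 3))

  set.seed(14)
  rg <- interactomeFromEdges(randomEdgeTable(40, 0.15))
  cs <- Matrix::colSums(buildTransition(rg)@M)
  expect_true(all(abs(cs - 1) < 1e-12))

  iso <- interactomeFromEdges(data.frame(node1 = "A", node2 = "B"), nodes = "L")
  mi <- buildTransition(iso)
  expect_identical(mi@isolated, "L")
  expect_equal(Matrix::colSums(mi@M)[["L"]], 0)
})

test_that("a pure restart walk returns the seed distribution", {
  g <- pathGraph(letters[1:4])
  res <- rwr(g, GeneSet(c("a", "b")), r = 1)
  expect_equal(affinityScores(res),
               c(a = 0.5, b = 0.5, c = 0, d = 0))
  expect_true(res@converged)
})

test_that("iterative scores match the closed-form linear solve", {
  p <- pathGraph(c("a", "b", "c", "d"))
  res <- rwr(p, GeneSet("a"), r = 0.75)
  oracle <- rwrLinearOracle(p, "a", 0.75)
  expect_lt(max(abs(affinityScores(res)[names(oracle)] - oracle)), 1e-8)

  set.seed(20)
  for (i in 1:10) {
    g <- randomConnectedGraph(sample(10:60, 1), 0.15)
    seeds <- sample(nodeIds(g), sample(1:3, 1))
    res <- rwr(g, GeneSet(seeds), r = 0.75)
    oracle <- rwrLinearOracle(g, seeds, 0.75)
    expect_lt(max(abs(affinityScores(res)[names(oracle)] - oracle)), 1e-8)
    expect_true(res@converged)
  }
})

test_that("walk scores respect graph automorphisms", {
  cyc <- interactomeFromEdges(data.frame(node1 = sprintf("n%d", 1:5),
                                         node2 = sprintf("n%d", c(2:5, 1))))
  s <- affinityScores(rwr(cyc, GeneSet("n1")))
  expect_equal(s[["n2"]], s[["n5"]])   # hop-1 pair
  expect_equal(s[["n3"]], s[["n4"]])   # hop-2 pair
})

test_that("seed handling warns on missing seeds and errors when none remain", {
  p <- pathGraph(letters[1:3])
  expect_warning(res <- rwr(p, GeneSet(c("a", "zz"))), "dropped")
  expect_setequal(geneIds(res@seeds), "a")
  expect_error(rwr(p, GeneSet("zz")), "no seed gene")
  expect_error(rwr(p, GeneSet("a"), r = 0), "'r'")
  expect_error(rwr(p, GeneSet("a"), r = 1.2), "'r'")
})

test_that("restart dominance concentrates mass on the seeds as r grows", {
  g <- generateInteractome(150, attachM = 3, seed = 16)
  seeds <- GeneSet(nodeIds(g)[1:5])
  seedMass <- vapply(c(0.2, 0.5, 0.75, 0.95, 0.999), function(r) {
    s <- affinityScores(rwr(g, seeds, r = r))
    sum(s[geneIds(seeds)])
  }, 0)
  expect_true(all(diff(seedMass) > 0))
  expect_gt(seedMass[length(seedMass)], 0.99)
})

test_that("non-convergence under a tiny iteration cap is flagged", {
  g <- generateInteractome(100, attachM = 3, seed = 17)
  expect_warning(res <- rwr(g, GeneSet(nodeIds(g)[1]), maxIter = 2L),
                 "did not converge")
  expect_false(res@converged)
  expect_equal(res@iterations, 2L)
})

test_that("the iteration is deterministic", {
  g <- generateInteractome(200, attachM = 3, seed = 18)
  a <- rwr(g, GeneSet(nodeIds(g)[1:4]))
  b <- rwr(g, GeneSet(nodeIds(g)[1:4]))
  expect_identical(affinityScores(a), affinityScores(b))
})

test_that("rankTop orders by score with id tie-breaks and optional seed exclusion", {
  g <- pathGraph(c("B", "A"))  # symmetric pair: equal scores
  res <- rwr(g, GeneSet(c("A", "B")))
  top <- rankTop(res, 2)
  expect_identical(top$gene, c("A", "B"))

  expect_equal(nrow(rankTop(res, 100)), 2L)  # k clamps to the node count
  expect_error(rankTop(res, 0), "'k'")

  # a planted hub adjacent to every seed outranks all other non-seeds
  sg <- generateInteractome(150, attachM = 3, seed = 19)
  sc <- plantPair(sg, 10, 6, q = 0.5, seed = 20, plantHub = TRUE)
  sub <- largestComponent(inducedSubgraph(
    sc@graph, c(geneIds(sc@diseaseSet), geneIds(sc@targetSet), sc@plantedHub)))
  res2 <- rwr(sub, GeneSet(intersect(geneIds(sc@targetSet), nodeIds(sub))))
  nonSeed <- rankTop(res2, 1, excludeSeeds = TRUE)
  expect_identical(nonSeed$gene, sc@plantedHub)
})
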