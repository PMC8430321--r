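test_that("loadEdgeList keeps exactly the edges at or above the confidence cut", {
  f <- writeTempLines(c("# interactome fixture",
                        "A\tB\t0.95", "B\tC\t0.91", "C\tD\t0.90",
                        "D\tE\t0.89", "E\tA\t0.40"))
  g <- loadEdgeList(f, minConfidence = 0.9)
  expect_equal(numEdges(g), 3L)
  et <- edgeTable(g)
  expect_setequal(paste(et$node1, et$node2), c("A B", "B C", "C D"))
  expect_true(all(et$confidence >= 0.9))

  # STRING-style 0-999 integer scores rescale on load
  f2 <- writeTempLines(c("A B 950", "B C 910", "C D 900", "D E 899"))
  expect_equal(numEdges(loadEdgeList(f2, 0.9, scoreScale = "string999")), 3L)
})

test_that("loadEdgeList handles empty files, self-loops and unscored edges", {
  empty <- writeTempLines(character())
  g <- loadEdgeList(empty)
  expect_equal(numNodes(g), 0L)
  expect_equal(numEdges(g), 0L)

  loop <- writeTempLines("A A 0.99")
  g2 <- loadEdgeList(loop, minConfidence = 0)
  expect_equal(nodeIds(g2), "A")
  expect_equal(numEdges(g2), 0L)

  # unscored edges pass only a zero threshold
  noscore <- writeTempLines(c("A B", "B C"))
  expect_equal(numEdges(loadEdgeList(noscore, 0)), 2L)
  expect_equal(numEdges(loadEdgeList(noscore, 0.5)), 0L)

  # duplicate unordered pairs collapse
  dup <- writeTempLines(c("A B 0.9", "B A 0.8", "A B 0.95"))
  expect_equal(numEdges(loadEdgeList(dup, 0)), 1L)
})

test_that("loadEdgeList rejects malformed input with the line number", {
  f <- writeTempLines(c("A B 0.9", "C"))
  expect_error(loadEdgeList(f), "line 2")
  f2 <- writeTempLines(c("# c", "A B 0.9", "C D x"))
  expect_error(loadEdgeList(f2), "line 3.*non-numeric")
  f3 <- writeTempLines("A B 0.9")
  expect_error(loadEdgeList(f3, minConfidence = 1.5), "minConfidence")
  expect_error(loadEdgeList(f3, minConfidence = -0.1), "minConfidence")
})

test_that("edge lists round-trip through write and load", {
  set.seed(42)
  et <- randomEdgeTable(20, 0.2)
  et$confidence <- round(runif(nrow(et)), 3)
  g <- interactomeFromEdges(et, nodes = "ISOLATED")
  f <- tempfile()
  writeEdgeList(g, f)
  g2 <- loadEdgeList(f, minConfidence = 0)
  expect_setequal(nodeIds(g2), nodeIds(g))
  key <- function(x) { e <- edgeTable(x); sort(paste(pmin(e$node1, e$node2),
                                                     pmax(e$node1, e$node2))) }
  expect_identical(key(g2), key(g))
})

test_that("bfsDistances returns exact hop counts", {
  p <- pathGraph(c("a", "b", "c"))
  expect_equal(bfsDistances(p, "a"), c(a = 0L, b = 1L, c = 2L))

  k5 <- cliqueGraph(letters[1:5])
  d <- bfsDistances(k5, "c")
  expect_equal(d[["c"]], 0L)
  expect_true(all(d[setdiff(names(d), "c")] == 1L))

  expect_error(bfsDistances(p, "zz"), "not in the graph")
})

test_that("bfsDistances agrees with the Floyd-Warshall oracle on random graphs", {
  set.seed(7)
  for (i in 1:10) {
    g <- interactomeFromEdges(randomEdgeTable(30, 0.1))
    D <- fwDistances(edgeTable(g), nodeIds(g))
    src <- sample(nodeIds(g), 1)
    got <- bfsDistances(g, src)
    row <- D[src, ]
    row <- row[is.finite(row)]
    expect_equal(got[order(names(got))],
                 setNames(as.integer(row), names(row))[order(names(row))])
  }
})

test_that("unreachable nodes are absent from distance maps", {
  g <- interactomeFromEdges(data.frame(node1 = c("a", "x"), node2 = c("b", "y")))
  d <- bfsDistances(g, "a")
  expect_false(any(c("x", "y") %in% names(d)))
})

test_that("inducedSubgraph restricts nodes and edges and reports missing genes", {
  tri <- cliqueGraph(c("A", "B", "C"))
  sub <- inducedSubgraph(tri, c("A", "B"))
  expect_setequal(nodeIds(sub), c("A", "B"))
  expect_equal(numEdges(sub), 1L)

  off <- inducedSubgraph(tri, c("X", "Y"))
  expect_equal(numNodes(off), 0L)
  expect_setequal(off@metadata$missingGenes, c("X", "Y"))
})

test_that("inducedSubgraph matches a brute-force edge filter and is idempotent", {
  set.seed(11)
  g <- interactomeFromEdges(randomEdgeTable(50, 0.08))
  genes <- sample(nodeIds(g), 20)
  sub <- inducedSubgraph(g, genes)
  et <- edgeTable(g)
  expected <- et[et$node1 %in% genes & et$node2 %in% genes, ]
  expect_equal(numEdges(sub), nrow(expected))
  sub2 <- inducedSubgraph(sub, genes)
  expect_setequal(nodeIds(sub2), nodeIds(sub))
  expect_equal(numEdges(sub2), numEdges(sub))
})

test_that("largestComponent picks the biggest component with a lexicographic tie rule", {
  g <- interactomeFromEdges(data.frame(node1 = c("a", "b", "x"),
                                       node2 = c("b", "c", "y")))
  expect_setequal(nodeIds(largestComponent(g)), c("a", "b", "c"))

  conn <- pathGraph(letters[1:4])
  expect_setequal(nodeIds(largestComponent(conn)), letters[1:4])

  tie <- interactomeFromEdges(data.frame(node1 = c("C", "A"), node2 = c("D", "B")))
  expect_setequal(nodeIds(largestComponent(tie)), c("A", "B"))

  empty <- interactomeFromEdges(data.frame(node1 = character(), node2 = character()))
  expect_error(largestComponent(empty), "empty")
})

test_that("gene lists read and write with comments and trimming", {
  f <- writeTempLines(c("# disease genes", "  STAT3 ", "MAPK1", "", "STAT3"))
  gs <- readGeneList(f, label = "dz")
  expect_identical(geneIds(gs), c("STAT3", "MAPK1"))
  f2 <- tempfile()
  writeGeneList(gs, f2)
  expect_identical(geneIds(readGeneList(f2)), geneIds(gs))
})

test_that("Interactome validity rejects bad confidence values", {
  expect_error(
    interactomeFromEdges(data.frame(node1 = "A", node2 = "B", confidence = 1.5)),
    "confidence")
})
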