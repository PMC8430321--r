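test_that("preferential-attachment graphs have the promised size and connectivity", {
  tree <- generateInteractome(5, attachM = 1, seed = 1)
  expect_equal(numEdges(tree), 4L)
  expect_true(igraph::is_connected(asIgraph(tree)))

  g <- generateInteractome(2000, attachM = 5, seed = 2)
  expect_equal(numEdges(g), (2000 - 5) * 5)
  expect_equal(numNodes(g), 2000L)
  expect_true(igraph::is_connected(asIgraph(g)))

  # heavy-tailed degrees: the top hub dwarfs the median degree
  deg <- igraph::degree(asIgraph(g))
  expect_gt(max(deg), 10 * stats::median(deg))

  expect_error(generateInteractome(3, attachM = 3), "n > attachM")
  expect_error(generateInteractome(10, attachM = 0), "n > attachM")
})

test_that("generators reproduce bit-identically from (parameters, seed)", {
  key <- function(g) { e <- edgeTable(g); paste(e$node1, e$node2) }
  expect_identical(key(generateInteractome(300, 3, seed = 5)),
                   key(generateInteractome(300, 3, seed = 5)))

  g <- generateInteractome(400, 3, seed = 6)
  s1 <- plantPair(g, 15, 8, q = 0.5, seed = 7)
  s2 <- plantPair(g, 15, 8, q = 0.5, seed = 7)
  expect_identical(geneIds(s1@diseaseSet), geneIds(s2@diseaseSet))
  expect_identical(geneIds(s1@targetSet), geneIds(s2@targetSet))

  t1 <- generateCompoundTable(50, passFraction = 0.4, seed = 8)
  t2 <- generateCompoundTable(50, passFraction = 0.4, seed = 8)
  expect_identical(t1$records, t2$records)
  expect_identical(t1$pairs, t2$pairs)

  uni <- sprintf("g%03d", 1:200)
  c1 <- generateTermCollection(uni, 10, c(5, 20), uni[1:30], 10, seed = 9)
  c2 <- generateTermCollection(uni, 10, c(5, 20), uni[1:30], 10, seed = 9)
  expect_identical(termGenes(c1$collection), termGenes(c2$collection))
})

test_that("planted pairs respect the proximity level q", {
  g <- generateInteractome(600, 4, seed = 10)
  dm <- allPairsDistances(g)

  scClose <- plantPair(g, 20, 10, q = 1, seed = 11)
  expect_lte(closestDistance(g, scClose@diseaseSet, scClose@targetSet,
                             dist = dm)$dc, 1)
  expect_length(intersect(geneIds(scClose@diseaseSet),
                          geneIds(scClose@targetSet)), 0L)

  scFar <- plantPair(g, 20, 10, q = 0, seed = 12)
  # q = 0: every target lies outside the module's closed neighbourhood
  mins <- closestDistance(g, scFar@diseaseSet, scFar@targetSet,
                          dist = dm)$perTarget
  expect_true(all(mins >= 2))

  # ground truth recomputes: close targets all sit at hop 1
  gtClose <- scClose@groundTruth$closeTargets
  expect_length(gtClose, 10L)
  expect_true(all(closestDistance(g, scClose@diseaseSet, gtClose,
                                  dist = dm)$perTarget == 1))
})

test_that("planted disease modules are connected neighbourhoods", {
  g <- generateInteractome(500, 3, seed = 13)
  sc <- plantPair(g, 25, 10, q = 0.5, seed = 14)
  sub <- inducedSubgraph(g, sc@diseaseSet)
  expect_true(igraph::is_connected(asIgraph(sub)))
  expect_equal(numNodes(sub), 25L)
})

test_that("compound tables plant an exact pass composition with boundary records", {
  none <- generateCompoundTable(30, passFraction = 0, seed = 15)
  expect_equal(nrow(filterCompounds(none$records)), 0L)

  tab <- generateCompoundTable(100, passFraction = 0.37, seed = 16)
  expect_equal(tab$groundTruth$nPass, 37L)
  kept <- filterCompounds(tab$records)
  expect_setequal(unique(kept$mol_id), tab$groundTruth$passIds)
  # the planted boundary compound sits exactly on both thresholds
  boundary <- tab$records[tab$records$ob == 30 & tab$records$dl == 0.18, ]
  expect_gte(nrow(boundary), 1L)
  expect_true(all(unique(boundary$mol_id) %in% tab$groundTruth$passIds))
})

test_that("planted term collections respect feasibility limits", {
  uni <- sprintf("g%03d", 1:100)
  # overlap equal to both term and query size: the minimal possible p
  tc <- generateTermCollection(uni, 5, c(5, 10), uni[1:10], 10,
                               plantedSize = 10, seed = 17)
  rows <- enrich(uni[1:10], tc$collection, correction = "none")
  expect_equal(rows$p[rows$term_id == "TERM_PLANTED"],
               1 / choose(100, 10), tolerance = 1e-12)
  expect_error(
    generateTermCollection(uni, 5, c(5, 10), uni[1:10], 12, plantedSize = 12),
    "infeasible")
})

test_that("scenarios write the formats the pipeline reads", {
  g <- generateInteractome(200, 3, seed = 18)
  sc <- plantPair(g, 10, 5, q = 1, seed = 19)
  dir <- tempfile()
  paths <- writeScenario(sc, dir)
  expect_true(all(file.exists(paths)))
  g2 <- loadEdgeList(paths[["graph"]])
  expect_equal(numEdges(g2), numEdges(g))
  expect_setequal(geneIds(readGeneList(paths[["disease"]])),
                  geneIds(sc@diseaseSet))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$q, 1)
})
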