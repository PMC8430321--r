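## Synthetic fixtures with recorded ground truth: a scale-free interactome,
## planted disease/target gene-set pairs with controllable topological
## proximity, ADME compound tables with a known pass composition, and term
## collections with one planted enriched term. Gene ids are synthetic
## ("G0001"-style): the fixtures emulate the *structure* of curated
## interactome/annotation snapshots, not their content.

#' Generate a scale-free interactome by preferential attachment
#'
#' Barabasi-Albert-style growth: \code{attachM} initially isolated nodes,
#' then each new node attaches \code{attachM} edges to distinct existing
#' nodes chosen with probability proportional to degree + 1. The result is
#' connected by construction, has exactly \code{(n - attachM) * attachM}
#' edges, and reproduces the heavy-tailed degree distribution of curated
#' human interactomes at desk scale.
#'
#' @param n number of nodes (> attachM)
#' @param attachM edges attached per new node (>= 1); default 5
#' @param seed optional integer seed; identical (parameters, seed) give
#'   bit-identical graphs
#' @return an [Interactome] with node ids \code{"G0001"}, ...
#' @export
#' @examples
#' g <- generateInteractome(200, attachM = 3, seed = 1)
#' numEdges(g)  # (200 - 3) * 3
generateInteractome <- function(n, attachM = 5L, seed = NULL) {
  if (!is.numeric(n) || !is.numeric(attachM) || attachM < 1 || n <= attachM)
    stop("need n > attachM >= 1")
  n <- as.integer(n); m <- as.integer(attachM)
  if (!is.null(seed)) set.seed(seed)
  width <- max(4L, nchar(as.character(n)))
  ids <- sprintf(paste0("G%0", width, "d"), seq_len(n))
  deg <- integer(n)
  nEdges <- (n - m) * m
  from <- integer(nEdges); to <- integer(nEdges)
  e <- 0L
  for (v in (m + 1L):n) {
    existing <- v - 1L
    tgt <- sample.int(existing, m, prob = deg[seq_len(existing)] + 1)
    from[e + seq_len(m)] <- v
    to[e + seq_len(m)] <- tgt
    e <- e + m
    deg[tgt] <- deg[tgt] + 1L
    deg[v] <- deg[v] + m
  }
  interactomeFromEdges(
    data.frame(node1 = ids[from], node2 = ids[to], stringsAsFactors = FALSE))
}

#' Plant a disease module and a drug-target set of tunable proximity
#'
#' Emulates the structure that the proximity analysis assumes: disease genes
#' forming a connected neighbourhood in the interactome, and drug targets
#' whose closeness to that module is controlled. The disease set is grown as
#' a random BFS ball of \code{diseaseSize} nodes; \code{ceiling(q *
#' targetSize)} targets are drawn from the module's first neighbourhood
#' (hop <= 1 from the disease set, excluding it), and the remainder
#' uniformly from nodes outside the module's closed neighbourhood. Targets
#' are always disjoint from the disease set. At q = 1 every target is within
#' one hop of the module, so d_c <= 1 by construction.
#'
#' @param g an [Interactome]
#' @param diseaseSize,targetSize sizes of the planted sets
#' @param q fraction of targets drawn from the disease neighbourhood, in
#'   [0, 1]
#' @param seed optional integer seed
#' @param plantHub also add a hub node (\code{"HUB0001"}) adjacent to every
#'   planted target? Used to test seed-adjacency ranking. Default FALSE
#' @return a [SyntheticScenario]
#' @export
plantPair <- function(g, diseaseSize, targetSize, q, seed = NULL,
                      plantHub = FALSE) {
  stopifnot(is(g, "Interactome"))
  if (q < 0 || q > 1) stop("'q' must be in [0, 1]")
  if (diseaseSize < 1 || targetSize < 1) stop("set sizes must be >= 1")
  if (diseaseSize + targetSize >= numNodes(g))
    stop("set sizes infeasible for this graph")
  if (!is.null(seed)) set.seed(seed)
  ig <- g@graph
  nd <- nodeIds(g)
  ## random BFS ball of diseaseSize nodes
  start <- nd[sample.int(length(nd), 1L)]
  module <- start
  frontier <- start
  while (length(module) < diseaseSize) {
    av <- igraph::adjacent_vertices(ig, frontier)
    nb <- unique(unlist(lapply(av, names)))
    nb <- setdiff(nb, module)
    if (!length(nb))
      stop("disease module exhausted its component before reaching the requested size")
    nb <- nb[sample.int(length(nb))]
    take <- head(nb, diseaseSize - length(module))
    module <- c(module, take)
    frontier <- take
  }
  ## first neighbourhood of the module
  n1 <- unique(unlist(lapply(igraph::adjacent_vertices(ig, module), names)))
  n1 <- setdiff(n1, module)
  nClose <- as.integer(ceiling(q * targetSize))
  nFar <- targetSize - nClose
  farPool <- setdiff(nd, c(module, n1))
  if (length(n1) < nClose)
    stop("not enough first-neighbourhood nodes to plant the requested close targets")
  if (length(farPool) < nFar)
    stop("not enough distant nodes to plant the requested far targets")
  closeT <- if (nClose) n1[sample.int(length(n1), nClose)] else character()
  farT <- if (nFar) farPool[sample.int(length(farPool), nFar)] else character()
  targets <- c(closeT, farT)
  hub <- character()
  if (plantHub) {
    hub <- "HUB0001"
    et <- edgeTable(g)[c("node1", "node2")]
    et <- rbind(et, data.frame(node1 = hub, node2 = targets))
    g <- interactomeFromEdges(et)
  }
  new("SyntheticScenario",
      graph = g,
      diseaseSet = GeneSet(module, label = "disease"),
      targetSet = GeneSet(targets, label = "targets"),
      q = q, plantedHub = hub,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      groundTruth = list(
        diseaseSize = diseaseSize, targetSize = targetSize, q = q,
        nClose = nClose, closeTargets = closeT, farTargets = farT,
        moduleStart = start, plantedHub = hub))
}

setMethod("show", "SyntheticScenario", function(object) {
  cat(sprintf("SyntheticScenario: %d-node graph, |disease| = %d, |targets| = %d, q = %.2f\n",
              numNodes(object@graph), length(object@diseaseSet),
              length(object@targetSet), object@q))
  if (length(object@plantedHub))
    cat("  planted hub:", object@plantedHub, "\n")
})

#' Generate an ADME compound table with a known pass composition
#'
#' Builds a compound table in which exactly \code{round(passFraction *
#' nCompounds)} records satisfy both screening thresholds (OB >= 30, DL >=
#' 0.18); the first passing compound sits exactly on the boundary (OB = 30,
#' DL = 0.18) to exercise the inclusive comparison, and failing compounds
#' miss on OB, DL, or both. Each compound is assigned 1-2 herbs (a row per
#' herb) and each passing compound 1-30 targets from a synthetic target
#' pool. The ground-truth record carries the pass list and the per-herb
#' compound/target tallies recomputed directly from the construction.
#'
#' @param nCompounds number of distinct compounds
#' @param herbs character vector of herb labels; default four herbs, as in a
#'   classic four-herb formula
#' @param passFraction fraction of compounds passing both thresholds
#' @param nTargetPool size of the synthetic target pool; default 40
#' @param seed optional integer seed
#' @return list with \code{records} (screening table, one row per
#'   compound-herb), \code{pairs} (compound-target pairs of passing
#'   compounds) and \code{groundTruth}
#' @export
generateCompoundTable <- function(nCompounds,
                                  herbs = c("herbA", "herbB", "herbC", "herbD"),
                                  passFraction = 0.3, nTargetPool = 40L,
                                  seed = NULL) {
  if (passFraction < 0 || passFraction > 1)
    stop("'passFraction' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(nCompounds)
  nPass <- as.integer(round(passFraction * n))
  ids <- sprintf("MOL%04d", seq_len(n))
  passIdx <- if (nPass) sort(sample.int(n, nPass)) else integer()
  ob <- numeric(n); dl <- numeric(n)
  ob[passIdx] <- runif(nPass, 30, 100)
  dl[passIdx] <- runif(nPass, 0.18, 1)
  if (nPass) { ob[passIdx[1]] <- 30; dl[passIdx[1]] <- 0.18 }
  failIdx <- setdiff(seq_len(n), passIdx)
  failMode <- sample(c("ob", "dl", "both"), length(failIdx), replace = TRUE)
  for (j in seq_along(failIdx)) {
    i <- failIdx[j]
    ob[i] <- if (failMode[j] %in% c("ob", "both")) runif(1, 1, 29.9) else runif(1, 30, 100)
    dl[i] <- if (failMode[j] %in% c("dl", "both")) runif(1, 0.01, 0.17) else runif(1, 0.18, 1)
  }
  herbOf <- lapply(seq_len(n), function(i) {
    k <- sample.int(min(2L, length(herbs)), 1L)
    herbs[sample.int(length(herbs), k)]
  })
  records <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(mol_id = ids[i], name = paste0("compound_", i),
               herb = herbOf[[i]], ob = ob[i], dl = dl[i],
               stringsAsFactors = FALSE)))
  pool <- sprintf("TG%03d", seq_len(as.integer(nTargetPool)))
  pairList <- lapply(passIdx, function(i) {
    k <- sample.int(min(30L, length(pool)), 1L)
    data.frame(mol_id = ids[i], target = pool[sample.int(length(pool), k)],
               stringsAsFactors = FALSE)
  })
  pairs <- if (length(pairList)) do.call(rbind, pairList) else
    data.frame(mol_id = character(), target = character())
  passIds <- ids[passIdx]
  perHerb <- do.call(rbind, lapply(sort(unique(unlist(herbOf))), function(h) {
    cpds <- ids[vapply(herbOf, function(hh) h %in% hh, TRUE)]
    passCpds <- intersect(cpds, passIds)
    tg <- unique(pairs$target[pairs$mol_id %in% passCpds])
    data.frame(herb = h, n_compounds_pass = length(passCpds),
               n_targets = length(tg), stringsAsFactors = FALSE)
  }))
  list(records = records, pairs = pairs,
       groundTruth = list(nPass = nPass, passIds = passIds,
                          perHerb = perHerb,
                          allTargets = sort(unique(pairs$target)),
                          seed = seed))
}

#' Generate a term collection with one planted enriched term
#'
#' Builds \code{nTerms} random terms over the universe plus one planted term
#' (\code{"TERM_PLANTED"}) sharing exactly \code{plantedOverlap} genes with
#' the given query set; the remaining members of the planted term come from
#' outside the query. Used to check that over-representation analysis
#' recovers a known signal and stays calibrated when the overlap is at
#' chance level.
#'
#' @param universe character vector of gene ids
#' @param nTerms number of random (non-planted) terms
#' @param termSizeRange integer range \code{c(lo, hi)} of term sizes;
#'   default c(10, 40)
#' @param plantedQuery [GeneSet] or character vector the planted term is
#'   tied to
#' @param plantedOverlap exact number of query genes inside the planted term
#' @param plantedSize size of the planted term; default the overlap plus 5
#'   background genes
#' @param seed optional integer seed
#' @return list with \code{collection} (a [TermCollection]) and
#'   \code{groundTruth} (names the planted term and overlap)
#' @export
generateTermCollection <- function(universe, nTerms, termSizeRange = c(10L, 40L),
                                   plantedQuery, plantedOverlap,
                                   plantedSize = plantedOverlap + 5L,
                                   seed = NULL) {
  q <- unique(if (is(plantedQuery, "GeneSet")) geneIds(plantedQuery)
              else as.character(plantedQuery))
  universe <- unique(as.character(universe))
  if (!all(q %in% universe)) stop("planted query must lie inside the universe")
  if (plantedOverlap > min(plantedSize, length(q)))
    stop("infeasible planted overlap: exceeds the term or query size")
  if (plantedSize - plantedOverlap > length(setdiff(universe, q)))
    stop("infeasible planted term: not enough non-query genes in the universe")
  if (!is.null(seed)) set.seed(seed)
  lo <- max(1L, as.integer(termSizeRange[1]))
  hi <- min(length(universe), as.integer(termSizeRange[2]))
  genes <- lapply(seq_len(nTerms), function(i) {
    sz <- sample(lo:hi, 1L)
    universe[sample.int(length(universe), sz)]
  })
  names(genes) <- sprintf("TERM%03d", seq_len(nTerms))
  inQ <- if (plantedOverlap) q[sample.int(length(q), plantedOverlap)] else character()
  outPool <- setdiff(universe, q)
  outQ <- if (plantedSize > plantedOverlap)
    outPool[sample.int(length(outPool), plantedSize - plantedOverlap)] else character()
  genes[["TERM_PLANTED"]] <- c(inQ, outQ)
  coll <- TermCollection(genes, universe = universe)
  list(collection = coll,
       groundTruth = list(plantedTerm = "TERM_PLANTED",
                          plantedOverlap = plantedOverlap,
                          plantedSize = plantedSize, seed = seed))
}

#' Write a synthetic scenario to disk
#'
#' Writes the formats the pipeline reads: the edge list, the disease and
#' target gene lists, and a ground-truth JSON sidecar.
#'
#' @param scenario a [SyntheticScenario]
#' @param dir output directory (created if needed)
#' @return named character vector of the paths written, invisibly
#' @export
writeScenario <- function(scenario, dir) {
  stopifnot(is(scenario, "SyntheticScenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(graph = file.path(dir, "interactome.tsv"),
             disease = file.path(dir, "disease_genes.txt"),
             targets = file.path(dir, "target_genes.txt"),
             truth = file.path(dir, "ground_truth.json"))
  writeEdgeList(scenario@graph, paths[["graph"]])
  writeGeneList(scenario@diseaseSet, paths[["disease"]])
  writeGeneList(scenario@targetSet, paths[["targets"]])
  jsonlite::write_json(scenario@groundTruth, paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
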