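#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom stats setNames phyper p.adjust runif
#' @importFrom utils head read.table write.table
NULL

setOldClass("igraph")

#' Interactome: an undirected protein-protein interaction graph
#'
#' Wraps an undirected \pkg{igraph} graph whose vertices are gene identifiers
#' and whose edges optionally carry a confidence score in [0, 1] (STRING-style
#' integer scores on the 0-999 scale are rescaled at load time). The graph is
#' simple: no self-loops, no duplicated unordered pairs. Distances are always
#' hop counts; confidence is used only for filtering when the graph is loaded.
#'
#' @slot graph an undirected simple \code{igraph} object; vertex attribute
#'   \code{name} holds gene identifiers, optional edge attribute
#'   \code{confidence} holds scores in [0, 1]
#' @slot metadata list of free-form annotations (e.g. genes that were requested
#'   but missing when a subgraph was induced)
#'
#' @seealso [loadEdgeList()], [inducedSubgraph()], [largestComponent()]
#' @export
setClass("Interactome",
  representation(graph = "igraph", metadata = "list"),
  prototype(metadata = list())
)

setValidity("Interactome", function(object) {
  g <- object@graph
  msg <- character()
  if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
  if (any(igraph::which_loop(g))) msg <- c(msg, "graph must not contain self-loops")
  if (any(igraph::which_multiple(g))) msg <- c(msg, "graph must not contain duplicate edges")
  if (igraph::vcount(g) > 0 && is.null(igraph::V(g)$name))
    msg <- c(msg, "vertices must be named")
  conf <- igraph::edge_attr(g, "confidence")
  if (!is.null(conf) && length(conf) &&
      (anyNA(conf) || any(conf < 0) || any(conf > 1)))
    msg <- c(msg, "edge confidences must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' GeneSet: a labelled set of gene identifiers
#'
#' A plain named set of gene identifiers (strings, case preserved, surrounding
#' whitespace trimmed on construction). Used for disease-gene sets, drug-target
#' sets, random-walk seed sets and enrichment queries.
#'
#' @slot label a single descriptive string
#' @slot members unique character vector of gene identifiers
#' @export
setClass("GeneSet",
  representation(label = "character", members = "character"),
  prototype(label = "", members = character())
)

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@label) != 1) msg <- c(msg, "label must be a single string")
  if (anyDuplicated(object@members)) msg <- c(msg, "members must be unique")
  if (any(!nzchar(object@members))) msg <- c(msg, "members must be non-empty strings")
  if (length(msg)) msg else TRUE
})

#' BipartiteNetwork: compound-target network with herb attribution
#'
#' @slot compounds character vector of compound ids (deduplicated)
#' @slot targets character vector of target gene ids (deduplicated)
#' @slot edges data.frame with columns \code{mol_id}, \code{target};
#'   unordered-duplicate-free
#' @slot herbs named list: compound id -> character vector of herbs it belongs
#'   to (a compound may belong to several herbs)
#' @slot herbSummary data.frame with columns \code{herb},
#'   \code{n_compounds}, \code{n_targets}; compounds shared between herbs are
#'   counted once per herb
#' @export
setClass("BipartiteNetwork",
  representation(compounds = "character", targets = "character",
                 edges = "data.frame", herbs = "list",
                 herbSummary = "data.frame")
)

setValidity("BipartiteNetwork", function(object) {
  msg <- character()
  if (nrow(object@edges) &&
      !all(object@edges$mol_id %in% object@compounds))
    msg <- c(msg, "every edge must reference a known compound")
  if (nrow(object@edges) && !all(object@edges$target %in% object@targets))
    msg <- c(msg, "every edge must reference a known target")
  if (anyDuplicated(paste(object@edges$mol_id, object@edges$target)))
    msg <- c(msg, "duplicate compound-target edges are not allowed")
  if (length(msg)) msg else TRUE
})

#' ProximityResult: closest-distance proximity and its degree-matched z-score
#'
#' Holds the closest distance d_c between a disease-gene set V and a
#' drug-target set T, together with the mean and population standard deviation
#' of d_c over random gene-set pairs matched to V and T in size and degree,
#' and the standardized distance z = (d_c - mu) / sigma. A strongly negative z
#' indicates that the drug's targets sit unusually close to the disease module.
#'
#' @slot dc observed closest distance (mean over targets of the minimum hop
#'   distance to the disease set)
#' @slot mu,sigma mean and population standard deviation of the null d_c
#' @slot z standardized distance
#' @slot nRandom number of random replicates behind mu and sigma
#' @slot nDroppedTargets number of retained targets with no path to any
#'   disease gene (excluded from the d_c mean)
#' @slot seed integer seed used for the null draws (NA if none supplied)
#' @slot nullDistances the replicate d_c values (diagnostics)
#' @export
setClass("ProximityResult",
  representation(dc = "numeric", mu = "numeric", sigma = "numeric",
                 z = "numeric", nRandom = "integer",
                 nDroppedTargets = "integer", seed = "integer",
                 nullDistances = "numeric")
)

setValidity("ProximityResult", function(object) {
  msg <- character()
  if (object@sigma < 0) msg <- c(msg, "sigma must be non-negative")
  if (object@nRandom < 1L) msg <- c(msg, "nRandom must be >= 1")
  if (object@sigma > 0 &&
      abs(object@z - (object@dc - object@mu) / object@sigma) > 1e-8)
    msg <- c(msg, "z inconsistent with (dc - mu) / sigma")
  if (length(msg)) msg else TRUE
})

#' TransitionModel: column-stochastic walk matrix of an interactome
#'
#' The transition matrix M of the random walk, with entry (i, j) equal to
#' A(i, j) / degree(j): each column spreads a walker at node j uniformly over
#' its neighbours. Columns of degree-0 (isolated) nodes are all-zero and the
#' corresponding nodes are flagged.
#'
#' @slot nodes node ordering (gene ids) indexing rows/columns of M
#' @slot M sparse column-stochastic matrix (\code{dgCMatrix})
#' @slot isolated ids of degree-0 nodes whose columns are all-zero
#' @export
setClass("TransitionModel",
  representation(nodes = "character", M = "Matrix", isolated = "character")
)

setValidity("TransitionModel", function(object) {
  msg <- character()
  if (nrow(object@M) != length(object@nodes) ||
      ncol(object@M) != length(object@nodes))
    msg <- c(msg, "M must be square over the node ordering")
  cs <- Matrix::colSums(object@M)
  live <- !(object@nodes %in% object@isolated)
  if (any(live) && any(abs(cs[live] - 1) > 1e-12))
    msg <- c(msg, "columns of non-isolated nodes must sum to 1 (tol 1e-12)")
  if (any(object@M@x < 0)) msg <- c(msg, "entries must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RWRResult: stationary affinities of a random walk with restart
#'
#' @slot scores named numeric vector of stationary affinity scores, one per
#'   node, summing to 1
#' @slot seeds the seed [GeneSet] (restart distribution support)
#' @slot r restart probability in (0, 1]
#' @slot tol L1 convergence threshold
#' @slot iterations number of iterations performed
#' @slot converged whether the last L1 step change fell below \code{tol}
#' @export
setClass("RWRResult",
  representation(scores = "numeric", seeds = "GeneSet", r = "numeric",
                 tol = "numeric", iterations = "integer",
                 converged = "logical")
)

setValidity("RWRResult", function(object) {
  msg <- character()
  if (any(object@scores < -1e-12)) msg <- c(msg, "scores must be non-negative")
  if (abs(sum(object@scores) - 1) > 1e-8)
    msg <- c(msg, "scores must sum to 1 (tol 1e-8)")
  if (object@r <= 0 || object@r > 1) msg <- c(msg, "r must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' CommunityPartition: modularity-based clustering of a graph
#'
#' Assignment of every node to a community, labelled 0-based and contiguous,
#' ordered by decreasing community size (ties broken by the lexicographically
#' smallest member). Communities smaller than \code{minSize} are kept in the
#' assignment but their nodes are additionally reported as unclustered, since
#' singleton or pair "clusters" carry no enrichment signal.
#'
#' @slot assignment named integer vector node -> community index (0-based)
#' @slot modularity Newman-Girvan modularity Q of the assignment
#' @slot minSize reporting threshold used to flag small communities
#' @slot unclustered node ids belonging to communities smaller than minSize
#' @export
setClass("CommunityPartition",
  representation(assignment = "integer", modularity = "numeric",
                 minSize = "integer", unclustered = "character")
)

setValidity("CommunityPartition", function(object) {
  msg <- character()
  a <- object@assignment
  if (length(a) && is.null(names(a))) msg <- c(msg, "assignment must be named")
  if (length(a)) {
    idx <- sort(unique(a))
    if (!identical(idx, seq_along(idx) - 1L))
      msg <- c(msg, "community indices must be contiguous from 0")
  }
  if (length(msg)) msg else TRUE
})

#' TermCollection: named gene-set terms over a declared universe
#'
#' GMT-style collection: each term has an id, a human-readable name and a
#' non-empty member gene set contained in the declared universe.
#'
#' @slot termIds character vector of term identifiers
#' @slot termNames character vector of term descriptions (same length)
#' @slot termGenes list of character vectors, one member set per term
#' @slot universe character vector of all genes the terms draw from
#' @export
setClass("TermCollection",
  representation(termIds = "character", termNames = "character",
                 termGenes = "list", universe = "character")
)

setValidity("TermCollection", function(object) {
  msg <- character()
  k <- length(object@termIds)
  if (length(object@termNames) != k || length(object@termGenes) != k)
    msg <- c(msg, "termIds, termNames and termGenes must have equal length")
  if (anyDuplicated(object@termIds)) msg <- c(msg, "term ids must be unique")
  if (k && any(vapply(object@termGenes, length, 0L) == 0))
    msg <- c(msg, "term member sets must be non-empty")
  if (k && !all(unlist(object@termGenes) %in% object@universe))
    msg <- c(msg, "every term member must belong to the universe")
  if (length(msg)) msg else TRUE
})

#' SyntheticScenario: a planted drug-disease instance with ground truth
#'
#' Bundles a synthetic interactome with a planted disease module (a connected
#' gene neighbourhood), a drug-target set whose topological proximity to the
#' disease module is controlled by the fraction \code{q} of targets drawn from
#' the disease set's first neighbourhood, an optional planted hub adjacent to
#' every target, and a ground-truth record sufficient to recompute every
#' planted quantity.
#'
#' @slot graph the synthetic [Interactome]
#' @slot diseaseSet,targetSet the planted [GeneSet]s
#' @slot q fraction of targets drawn from the disease neighbourhood
#' @slot plantedHub id of the planted hub node, or character(0)
#' @slot seed integer seed the scenario was generated with (NA if none)
#' @slot groundTruth list recording all planted memberships and counts
#' @export
setClass("SyntheticScenario",
  representation(graph = "Interactome", diseaseSet = "GeneSet",
                 targetSet = "GeneSet", q = "numeric",
                 plantedHub = "character", seed = "integer",
                 groundTruth = "list")
)

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  nd <- nodeIds(object@graph)
  if (!all(object@diseaseSet@members %in% nd))
    msg <- c(msg, "disease set must be contained in the graph")
  if (!all(object@targetSet@members %in% nd))
    msg <- c(msg, "target set must be contained in the graph")
  if (object@q < 0 || object@q > 1) msg <- c(msg, "q must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
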