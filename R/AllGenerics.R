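#' Node identifiers of a graph-like object
#' @param x an [Interactome] or [TransitionModel]
#' @return character vector of node ids
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Number of nodes
#' @param x an [Interactome]
#' @return integer
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' Number of edges
#' @param x an [Interactome] or [BipartiteNetwork]
#' @return integer
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Edge table of a graph
#' @param x an [Interactome]
#' @return data.frame with columns \code{node1}, \code{node2} and, when
#'   present, \code{confidence}
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Underlying igraph object
#' @param x an [Interactome]
#' @return the wrapped \code{igraph} graph
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Member gene identifiers
#' @param x a [GeneSet]
#' @return character vector
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Label of a gene set
#' @param x a [GeneSet]
#' @return character scalar
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))

#' Affinity scores of a random walk result
#' @param x an [RWRResult]
#' @return named numeric vector summing to 1
#' @export
setGeneric("affinityScores", function(x) standardGeneric("affinityScores"))

#' Community membership of a partition
#' @param x a [CommunityPartition]
#' @return named integer vector (0-based community indices)
#' @export
setGeneric("communityAssignment",
           function(x) standardGeneric("communityAssignment"))

#' Term identifiers of a collection
#' @param x a [TermCollection]
#' @return character vector
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))

#' Universe of a term collection
#' @param x a [TermCollection]
#' @return character vector of all genes the terms draw from
#' @export
setGeneric("termUniverse", function(x) standardGeneric("termUniverse"))

#' Member genes of each term
#' @param x a [TermCollection]
#' @return named list of character vectors
#' @export
setGeneric("termGenes", function(x) standardGeneric("termGenes"))
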