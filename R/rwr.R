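## Random walk with restart over an interactome:
##   p_{t+1} = (1 - r) * M %*% p_t + r * p_0
## with M the column-normalized adjacency (entry (i,j) = A(i,j)/deg(j)),
## p_0 uniform over the seed genes, restart probability r (default 0.75) and
## L1 convergence threshold 1e-10. The stationary vector scores every node's
## affinity to the seed set; the top-ranked genes are the hub candidates.

#' Build the column-stochastic transition matrix of a graph
#'
#' M(i, j) = A(i, j) / degree(j): each column spreads a walker at node j
#' uniformly over its neighbours. Isolated (degree-0) nodes get an all-zero
#' column and are flagged in the model; a walk touching them would leak
#' probability mass, so walks are normally run on a connected component.
#'
#' @param g a non-empty [Interactome]
#' @return a [TransitionModel]
#' @export
buildTransition <- function(g) {
  stopifnot(is(g, "Interactome"))
  if (numNodes(g) == 0) stop("cannot build a transition model on an empty graph")
  nodes <- nodeIds(g)
  A <- igraph::as_adjacency_matrix(g@graph, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::colSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  M <- A %*% Matrix::Diagonal(x = inv)
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  dimnames(M) <- list(nodes, nodes)
  new("TransitionModel", nodes = nodes, M = M,
      isolated = nodes[deg == 0])
}

#' @describeIn nodeIds node ordering of a transition model
#' @export
setMethod("nodeIds", "TransitionModel", function(x) x@nodes)

setMethod("show", "TransitionModel", function(object) {
  cat("TransitionModel over", length(object@nodes), "nodes")
  if (length(object@isolated))
    cat(" (", length(object@isolated), " isolated)", sep = "")
  cat("\n")
})

#' Random walk with restart from a seed gene set
#'
#' Iterates p_{t+1} = (1 - r) M p_t + r p_0 from the uniform seed
#' distribution p_0 (only seed genes have non-zero initial mass) until the
#' L1 change between successive vectors falls below \code{tol}, or
#' \code{maxIter} is reached. With r = 1 the walk returns the seed
#' distribution exactly. Seeds absent from the graph are dropped with a
#' warning; at least one seed must be present.
#'
#' @param model a [TransitionModel], or an [Interactome] (the model is built
#'   on the fly)
#' @param seeds seed [GeneSet] or character vector
#' @param r restart probability in (0, 1]; default 0.75
#' @param tol L1 convergence threshold; default 1e-10
#' @param maxIter iteration cap; default 10000 (non-convergence returns a
#'   result flagged \code{converged = FALSE} with a warning)
#' @return an [RWRResult]
#' @export
#' @examples
#' g <- interactomeFromEdges(data.frame(node1 = c("a", "b", "c"),
#'                                      node2 = c("b", "c", "d")))
#' res <- rwr(g, GeneSet("a"))
#' head(rankTop(res, 4))
rwr <- function(model, seeds, r = 0.75, tol = 1e-10, maxIter = 10000L) {
  if (is(model, "Interactome")) model <- buildTransition(model)
  stopifnot(is(model, "TransitionModel"))
  if (!is.numeric(r) || length(r) != 1 || r <= 0 || r > 1)
    stop("'r' must be a single number in (0, 1]")
  seedSet <- if (is(seeds, "GeneSet")) seeds else GeneSet(seeds, label = "seeds")
  present <- intersect(geneIds(seedSet), model@nodes)
  if (!length(present))
    stop("no seed gene is present in the graph")
  if (length(present) < length(seedSet))
    warning(sprintf("%d seed(s) absent from the graph were dropped",
                    length(seedSet) - length(present)))
  n <- length(model@nodes)
  p0 <- numeric(n)
  p0[match(present, model@nodes)] <- 1 / length(present)
  p <- p0
  it <- 0L
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    pNew <- as.numeric((1 - r) * (model@M %*% p)) + r * p0
    delta <- sum(abs(pNew - p))
    p <- pNew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("random walk did not converge in %d iterations (last L1 change %.3g)",
                    maxIter, delta))
  new("RWRResult",
      scores = setNames(p, model@nodes),
      seeds = GeneSet(present, label = setLabel(seedSet)),
      r = r, tol = tol, iterations = it, converged = converged)
}

#' @describeIn affinityScores stationary scores of a walk
#' @export
setMethod("affinityScores", "RWRResult", function(x) x@scores)

setMethod("show", "RWRResult", function(object) {
  cat(sprintf("RWRResult over %d nodes (r = %.2f, %d seeds)\n",
              length(object@scores), object@r, length(object@seeds)))
  cat(sprintf("  %s after %d iterations (tol %.1g)\n",
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@tol))
})

#' Top-ranked genes by random-walk affinity
#'
#' Sorts nodes by descending affinity score; ties are broken by ascending
#' node id so the ranking is deterministic. Seed genes can optionally be
#' removed before ranking.
#'
#' @param result an [RWRResult]
#' @param k number of genes to return (clamped to the number available)
#' @param excludeSeeds drop seed genes before ranking? Default FALSE: the
#'   hub table may legitimately contain seed genes
#' @return data.frame with columns \code{rank}, \code{gene}, \code{score}
#' @export
rankTop <- function(result, k = 10L, excludeSeeds = FALSE) {
  stopifnot(is(result, "RWRResult"))
  if (!is.numeric(k) || k < 1) stop("'k' must be at least 1")
  s <- result@scores
  if (excludeSeeds) s <- s[!(names(s) %in% geneIds(result@seeds))]
  ord <- order(-s, names(s))
  s <- s[ord]
  k <- min(as.integer(k), length(s))
  data.frame(rank = seq_len(k), gene = names(s)[seq_len(k)],
             score = as.numeric(s[seq_len(k)]),
             stringsAsFactors = FALSE)
}
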